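tempfile_gff <- function(sim) {
  path <- tempfile(fileext = ".gff3")
  introtrace:::write_gff3(sim$features, path)
  path
}

test_that("a fixed seed gives byte-identical simulation output", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_species = 8, seed = 42,
                           loss_prob_per_branch = 0.2,
                           annotation_dropout_prob = 0.1)
  s1 <- simulate_family(cfg, file.path(dir, "a"))
  s2 <- simulate_family(cfg, file.path(dir, "b"))
  for (f in c("genome.fa", "annotation.gff3", "tree.nwk", "truth.json")) {
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)), info = f)
  }
  s3 <- simulate_family(simulation_config(n_species = 8, seed = 43,
                                          loss_prob_per_branch = 0.2))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("the no-loss limit keeps the variant in every descendant species", {
  cfg <- simulation_config(n_species = 10, seed = 5,
                           loss_prob_per_branch = 0,
                           annotation_dropout_prob = 0)
  sim <- simulate_family(cfg)
  tr <- sim$tree
  birth <- introtrace:::node_by_label(tr, sim$truth$birth_node)
  under <- tr$tip.label[introtrace:::descendant_tips(tr)[[birth]]]
  expect_setequal(names(sim$truth$presence)[sim$truth$presence == "present"],
                  under)
  expect_equal(nrow(sim$truth$loss_edges), 0L)
  expect_equal(sim$truth$realized_origin, sim$truth$birth_node)
})

test_that("certain loss on every branch leaves an all-absent character", {
  cfg <- simulation_config(n_species = 10, seed = 6,
                           loss_prob_per_branch = 1)
  sim <- simulate_family(cfg)
  expect_true(all(sim$truth$presence == "absent"))
  # the reconstruction path must refuse an all-absent pattern
  expect_error(dollo_reconstruct(sim$tree, sim$truth$presence), "all-absent")
})

test_that("substitution counts match the Jukes-Cantor expectation", {
  n_sites <- 10002L
  cds <- withr::with_seed(9, introtrace:::random_cds(n_sites %/% 3L))
  d <- 0.1
  out <- withr::with_seed(10, evolve_cds(cds, d))
  expect_equal(nchar(out), n_sites)
  frac <- mean(strsplit(cds, "")[[1]] != strsplit(out, "")[[1]])
  p_expect <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(p_expect * (1 - p_expect) / n_sites)
  expect_lt(abs(frac - p_expect), 3 * se)
  expect_identical(evolve_cds(cds, 0), cds)
  # evolution never introduces an internal stop
  expect_no_error(translate_cds(out))
})

test_that("emitted files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_species = 6, seed = 11,
                           loss_prob_per_branch = 0.1)
  sim <- simulate_family(cfg, dir)
  genome <- Biostrings::readDNAStringSet(sim$paths$genome)
  expect_setequal(names(genome), names(sim$genome))
  models <- parse_gff3(sim$paths$gff3, genome)
  prot <- annotate_proteins(models, genome)
  # every annotated variant carries exactly the configured intron offset
  vars <- prot[grepl("_VAR$", names(prot))]
  for (v in vars)
    expect_equal(v$introns$coding_offset, sim$truth$intron_offsets)
  # canonical genes are intronless and present for every species
  canon <- prot[grepl("_H2A$", names(prot))]
  expect_length(canon, 6L)
  for (cn in canon) expect_equal(nrow(cn$introns), 0L)
  # species attribute flows through the GFF3 round trip
  expect_setequal(unique(vapply(prot, `[[`, character(1), "species_id")),
                  sim$tree$tip.label)
  tr <- read_species_tree(sim$paths$tree)
  expect_setequal(tr$tip.label, sim$tree$tip.label)
})

test_that("annotation dropouts leave the genome but not the GFF3", {
  cfg <- simulation_config(n_species = 12, seed = 13,
                           loss_prob_per_branch = 0,
                           annotation_dropout_prob = 0.5)
  sim <- simulate_family(cfg)
  expect_gt(length(sim$truth$dropouts), 0L)
  for (sp in sim$truth$dropouts) {
    vid <- paste0(sp, "_VAR")
    expect_true(paste0(vid, "_ctg") %in% names(sim$genome))
    expect_false(vid %in% sim$features$ID)
  }
  # the rescue scan recovers a dropout from its genome at low divergence
  sp <- sim$truth$dropouts[1]
  prot <- annotate_proteins(parse_gff3(tempfile_gff(sim), sim$genome),
                            sim$genome)
  canon_pep <- prot[[paste0(sp, "_H2A")]]$aa
  exon1_pep <- substr(canon_pep, 1, sim$truth$intron_offsets[1] %/% 3L)
  hits <- rescue_scan(exon1_pep, sim$genome[paste0(sp, "_VAR_ctg")],
                      min_score = 60)
  expect_gt(nrow(hits), 0L)
})

test_that("the second intron and protosplice planting are honoured", {
  cfg <- simulation_config(n_species = 6, seed = 17,
                           loss_prob_per_branch = 0,
                           intron_offset = 150L,
                           second_intron_offset = 331L,
                           protosplice_bias = TRUE)
  sim <- simulate_family(cfg)
  expect_equal(sim$truth$intron_offsets, c(150L, 331L))
  genome <- sim$genome
  models <- parse_gff3(tempfile_gff(sim), genome)
  prot <- annotate_proteins(models, genome)
  v <- prot[grepl("_VAR$", names(prot))][[1]]
  expect_equal(v$introns$coding_offset, c(150L, 331L))
  expect_equal(v$introns$phase, c(0L, 1L))
})

test_that("the worked-example fixture reproduces its published coordinates", {
  dir <- withr::local_tempdir()
  fx <- make_fig1_fixture(dir)
  genome <- Biostrings::readDNAStringSet(fx$paths$genome)
  models <- parse_gff3(fx$paths$gff3, genome)
  # variant with offset 78: first CDS segment (transcript order) is 78 nt
  m <- models$var_htas1
  seg_len <- m$cds_segments$end - m$cds_segments$start
  expect_equal(seg_len[1], 78L)
  expect_equal(m$strand, "-")
  prot <- annotate_proteins(models, genome)
  expect_equal(prot$var_htz1$introns$phase, 2L)
  expect_equal(prot$var_htz1$introns$codon_index, 57L)
  expect_equal(nrow(prot$core_H2A$introns), 0L)
})
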