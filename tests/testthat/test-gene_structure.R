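test_that("coding offset maps to the documented codon index and phase", {
  cases <- list(
    list(off = 78L, codon = 26L, phase = 0L, boundary = TRUE),
    list(off = 170L, codon = 57L, phase = 2L, boundary = FALSE),
    list(off = 150L, codon = 50L, phase = 0L, boundary = TRUE),
    list(off = 331L, codon = 111L, phase = 1L, boundary = FALSE),
    list(off = 1L, codon = 1L, phase = 1L, boundary = FALSE))
  for (cs in cases) {
    ann <- intron_codon_phase(cs$off)
    expect_equal(ann$codon_index, cs$codon, info = cs$off)
    expect_equal(ann$phase, cs$phase, info = cs$off)
    expect_equal(ann$boundary, cs$boundary, info = cs$off)
    expect_equal(ann$phase, cs$off %% 3L)
  }
  expect_error(intron_codon_phase(0), ">= 1")
  expect_error(intron_codon_phase(-3), ">= 1")
})

test_that("GFF3 parsing converts coordinates, orders segments, drops broken genes", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  gff <- file.path(dir, "g.gff3")
  withr::with_seed(11, {
    contig <- paste0(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                     collapse = "")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(c(ctg1 = contig)), fa)
  })
  writeLines(c(
    "##gff-version 3",
    "ctg1\tsrc\tgene\t101\t178\t.\t+\t.\tID=gplus",
    "ctg1\tsrc\tmRNA\t101\t178\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "ctg1\tsrc\tCDS\t101\t178\t.\t+\t0\tID=c1;Parent=gplus.t1",
    "ctg1\tsrc\tgene\t10\t95\t.\t-\t.\tID=gminus",
    "ctg1\tsrc\tmRNA\t10\t95\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "ctg1\tsrc\tCDS\t10\t39\t.\t-\t0\tID=c2;Parent=gminus.t1",
    "ctg1\tsrc\tCDS\t60\t95\t.\t-\t0\tID=c3;Parent=gminus.t1",
    "ctg1\tsrc\tgene\t201\t280\t.\t+\t.\tID=gbad",
    "ctg1\tsrc\tmRNA\t201\t280\t.\t+\t.\tID=gbad.t1;Parent=gbad",
    "ctg1\tsrc\tCDS\t201\t280\t.\t+\t0\tID=c4;Parent=gbad.t1"), gff)

  expect_warning(models <- parse_gff3(gff, fa), "gbad")
  expect_setequal(names(models), c("gplus", "gminus"))

  expect_equal(models$gplus$cds_length, 78L)  # 178 - 101 + 1
  expect_equal(models$gplus$cds_segments$start, 100L)  # 0-based half-open
  expect_equal(models$gplus$cds_segments$end, 178L)

  # minus strand: transcript orientation = descending genomic start
  expect_equal(models$gminus$cds_segments$start, c(59L, 9L))
  expect_equal(models$gminus$cds_segments$end, c(95L, 39L))
})

test_that("contig missing from the genome is an error naming the contig", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(other = "ACGTACGTACGT")), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3",
               "ghost\tsrc\tCDS\t1\t12\t.\t+\t0\tID=c;Parent=t1"), gff)
  expect_error(parse_gff3(gff, fa), "ghost")
})

test_that("assembled CDS junction offsets reproduce the worked coordinates", {
  dir <- withr::local_tempdir()
  for (cs in list(list(first = 78L, second = 312L, exp = 78L),
                  list(first = 170L, second = 220L, exp = 170L))) {
    fx <- make_two_exon_fixture(file.path(dir, paste0("f", cs$first)),
                                cs$first, cs$second, strand = "+",
                                seed = cs$first)
    g <- Biostrings::readDNAStringSet(fx$paths$genome)
    m <- parse_gff3(fx$paths$gff3, g)[[1]]
    asm <- assemble_cds(m, g)
    expect_equal(asm$offsets, cs$exp)
    expect_equal(asm$cds, fx$cds)
    expect_equal(nchar(asm$cds), cs$first + cs$second)
  }
})

test_that("identical exon content on plus and minus strands gives one answer", {
  dir <- withr::local_tempdir()
  for (seed in c(3L, 4L)) {
    fp <- make_two_exon_fixture(file.path(dir, paste0("p", seed)), 150L, 240L,
                                strand = "+", seed = seed)
    fm <- make_two_exon_fixture(file.path(dir, paste0("m", seed)), 150L, 240L,
                                strand = "-", seed = seed)
    gp <- Biostrings::readDNAStringSet(fp$paths$genome)
    gm <- Biostrings::readDNAStringSet(fm$paths$genome)
    ap <- assemble_cds(parse_gff3(fp$paths$gff3, gp)[[1]], gp)
    am <- assemble_cds(parse_gff3(fm$paths$gff3, gm)[[1]], gm)
    expect_identical(ap$cds, am$cds)
    expect_identical(ap$offsets, am$offsets)
  }
})

test_that("translation follows the standard code and flags internal stops", {
  expect_equal(translate_cds("ATGGGTTAA"), "MG")
  expect_error(translate_cds("ATGTAAGGT"), "codon 2")
  expect_equal(translate_cds("ATGNNNTAA"), "MX")
  expect_equal(translate_cds("ATGGGT"), "MG")  # no terminal stop required
  expect_error(translate_cds("ATGGG"), "divisible by 3")
})

test_that("round trip: annotation agrees with brute-force codon walking", {
  # brute-force oracle: walk the CDS base by base, counting complete codons
  walk_codon <- function(offset) {
    in_codon <- 0L; complete <- 0L
    for (i in seq_len(offset)) {
      in_codon <- in_codon + 1L
      if (in_codon == 3L) { complete <- complete + 1L; in_codon <- 0L }
    }
    list(codon_index = if (in_codon == 0L) complete else complete + 1L,
         phase = in_codon)
  }
  dir <- withr::local_tempdir()
  for (seed in 1:12) {
    n_codons <- withr::with_seed(seed, sample(40:120, 1))
    total <- 3L * n_codons
    n_intr <- withr::with_seed(seed + 100, sample(0:3, 1))
    offsets <- withr::with_seed(seed + 200,
                                sort(sample(seq_len(total - 1L), n_intr)))
    strand <- if (seed %% 2L) "+" else "-"
    sim <- withr::with_seed(seed + 300, {
      cds <- introtrace:::random_cds(n_codons)
      introns <- vapply(seq_along(offsets), function(i)
        introtrace:::random_intron(50L), character(1))
      introtrace:::emit_gene("sp", "g1", cds, as.integer(offsets), introns,
                             200L, strand = strand)
    })
    dir_i <- file.path(dir, paste0("rt", seed))
    dir.create(dir_i)
    fa <- file.path(dir_i, "g.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(sim$seq, sim$contig)), fa)
    gff <- file.path(dir_i, "g.gff3")
    introtrace:::write_gff3(sim$rows, gff)
    genome <- Biostrings::readDNAStringSet(fa)
    prot <- annotate_proteins(parse_gff3(gff, genome), genome)[[1]]
    expect_equal(prot$introns$coding_offset, as.integer(offsets))
    expect_equal(nchar(prot$aa), n_codons - 1L)  # stop stripped
    for (k in seq_along(offsets)) {
      wk <- walk_codon(offsets[k])
      expect_equal(prot$introns$codon_index[k], wk$codon_index)
      expect_equal(prot$introns$phase[k], wk$phase)
    }
  }
})

test_that("annotated FASTA headers round-trip through the reader", {
  dir <- withr::local_tempdir()
  prots <- list(
    make_protein("gA", "MKVLAT", c(3L, 10L), species = "sp1",
                 cds = "ATGAAAGTTCTTGCCACCTAA"),
    make_protein("gB", "MKVLAT", species = "sp2",
                 cds = "ATGAAAGTACTTGCCACCTAA"))
  aa <- file.path(dir, "p.faa"); nt <- file.path(dir, "p.fna")
  write_annotated_fasta(prots, aa)
  write_annotated_fasta(prots, nt, what = "cds")
  back <- read_annotated_fasta(aa, nt)
  expect_equal(back$gA$introns$coding_offset, c(3L, 10L))
  expect_equal(back$gA$introns$phase, c(0L, 1L))
  expect_equal(back$gA$species_id, "sp1")
  expect_equal(back$gA$cds, prots[[1]]$cds)
  expect_equal(nrow(back$gB$introns), 0L)
})
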