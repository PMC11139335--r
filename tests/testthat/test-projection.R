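aa_n <- function(n) paste(rep("L", n), collapse = "")

test_that("introns project to the column of their codon residue", {
  # 30-residue gene, intron at offset 78 -> codon 26 phase 0
  p <- make_protein("g1", aa_n(30), 78L)
  fam <- aligned_family(c(g1 = aa_n(30)))
  pr <- project_introns(fam, list(p))
  expect_equal(pr$column, 26L)
  expect_equal(pr$phase, 0L)

  # same gene behind 4 leading gap columns -> column 30
  fam2 <- aligned_family(c(g1 = paste0("----", aa_n(30)),
                           g2 = aa_n(34)))
  pr2 <- project_introns(fam2, list(p))
  expect_equal(pr2$column, 30L)

  # two genes, same column, phases 0 and 2 -> distinct projections
  pa <- make_protein("gA", aa_n(30), 78L)   # codon 26 phase 0
  pb <- make_protein("gB", aa_n(30), 77L)   # codon 26 phase 2
  fam3 <- aligned_family(c(gA = aa_n(30), gB = aa_n(30)))
  pr3 <- project_introns(fam3, list(pa, pb))
  expect_equal(pr3$column, c(26L, 26L))
  expect_setequal(pr3$phase, c(0L, 2L))
})

test_that("a stale alignment is rejected naming the gene", {
  p <- make_protein("g1", aa_n(30), 78L)
  fam <- aligned_family(c(g1 = aa_n(29)))
  expect_error(project_introns(fam, list(p)), "g1")
})

test_that("classes partition by exact column and phase", {
  genes <- sprintf("g%02d", 1:16)
  projected <- data.frame(gene_id = genes, column = 26L, phase = 0L,
                          coding_offset = 78L)
  cls <- build_classes(projected)
  expect_equal(nrow(cls), 1L)
  expect_equal(cls$n_members, 16L)
  expect_equal(cls$class_id, "26.0")
  expect_setequal(attr(cls, "members")[["26.0"]], genes)

  near <- data.frame(gene_id = c("a", "b"), column = c(50L, 51L),
                     phase = c(0L, 2L), coding_offset = c(150L, 152L))
  expect_equal(nrow(build_classes(near)), 2L)

  empty <- build_classes(project_introns(aligned_family(c(x = "AAA")),
                                         list(make_protein("x", "AAA"))))
  expect_equal(nrow(empty), 0L)
})

test_that("ortholog assignment flags members missing one reference intron", {
  # reference with introns at columns 57 (phase 2) and 111 (phase 1)
  ref <- make_protein("ref", aa_n(120), c(170L, 331L))
  partial <- make_protein("p1", aa_n(120), 170L)   # lost the second intron
  full <- make_protein("p2", aa_n(120), c(170L, 331L))
  fam <- aligned_family(vapply(list(ref, partial, full),
                               function(p) aa_n(120), character(1)) |>
                          stats::setNames(c("ref", "p1", "p2")))
  cls <- build_classes(project_introns(fam, list(ref, partial, full)))
  orth <- assign_orthologs(cls, "ref")
  expect_setequal(orth$reference_classes, c("57.2", "111.1"))
  o <- orth$orthologs
  expect_true(o$partial[o$gene_id == "p1"])
  expect_match(o$flag[o$gene_id == "p1"], "111\\.1")
  expect_false(o$partial[o$gene_id == "p2"])

  # singleton class and intronless reference error
  single <- assign_orthologs(
    build_classes(data.frame(gene_id = "ref", column = 5L, phase = 0L,
                             coding_offset = 15L)), "ref")
  expect_equal(single$orthologs$gene_id, "ref")
  expect_error(assign_orthologs(cls, "absent_gene"), "absent_gene")
})

test_that("homologous offsets shift with alignment gaps and refuse gapped columns", {
  donor <- make_protein("d", aa_n(30), 78L)
  # gap-free pair: offset carries over unchanged
  fam <- aligned_family(c(d = aa_n(30), t = aa_n(30)))
  m <- homologous_offset(fam, "d", 78L, "t")
  expect_equal(m$status, "ok"); expect_equal(m$offset, 78L)

  # target with a 2-residue insertion upstream of the column
  fam2 <- aligned_family(c(d = paste0("--", aa_n(30)),
                           t = aa_n(32)))
  m2 <- homologous_offset(fam2, "d", 78L, "t")
  expect_equal(m2$offset, 78L + 6L)

  # phase is preserved through the mapping
  m3 <- homologous_offset(fam2, "d", 77L, "t")
  expect_equal(m3$offset %% 3L, 77L %% 3L)

  # target gapped at the column -> unmappable, not a guess
  fam3 <- aligned_family(c(d = aa_n(30),
                           t = paste0(aa_n(20), "----------")))
  m4 <- homologous_offset(fam3, "d", 78L, "t")
  expect_equal(m4$status, "unmappable")
  expect_true(is.na(m4$offset))
})

test_that("protosplice scoring reproduces the qualitative site calls", {
  # perfect site, the two signal sites, and the no-signal site
  mk <- function(four) paste0("ATGGCT", four, "GCTGCTTAA")
  cases <- list(list(f = "AGGT", n = 4L, sig = TRUE),
                list(f = "CAGT", n = 2L, sig = TRUE),
                list(f = "AGGC", n = 3L, sig = TRUE),
                list(f = "CTGG", n = 1L, sig = FALSE))
  for (cs in cases) {
    sc <- flanking_site_score(mk(cs$f), 8L)
    expect_equal(sc$n_matches, cs$n, info = cs$f)
    expect_equal(sc$signal, cs$sig, info = cs$f)
    expect_equal(sc$four_mer, paste0(substr(cs$f, 1, 2), "|",
                                     substr(cs$f, 3, 4)))
  }
  expect_error(flanking_site_score("ATGGCT", 1L), "too close")
  expect_error(flanking_site_score("ATGGCT", 5L), "too close")
})

test_that("gap-column insertion shifts projections uniformly, never reclassifies", {
  for (seed in 1:60) {
    withr::with_seed(seed, {
      n_genes <- sample(3:8, 1)
      width <- sample(30:60, 1)
      rows <- vapply(seq_len(n_genes), function(i)
        paste0(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
                      width, TRUE), collapse = ""), character(1))
      names(rows) <- sprintf("g%d", seq_len(n_genes))
      prots <- lapply(names(rows), function(g) {
        aa <- rows[[g]]
        n_int <- sample(0:3, 1)
        offs <- if (n_int) sort(sample(seq_len(3L * nchar(aa) - 1L), n_int))
                else integer(0)
        make_protein(g, aa, offs)
      })
      fam <- aligned_family(rows)
      cls <- build_classes(project_introns(fam, prots))

      at <- sample(0:width, 1)  # insert an all-gap column after position `at`
      rows2 <- vapply(rows, function(r)
        paste0(substr(r, 1, at), "-", substr(r, at + 1, width)),
        character(1))
      fam2 <- aligned_family(rows2)
      cls2 <- build_classes(project_introns(fam2, prots))

      expect_equal(nrow(cls2), nrow(cls))
      expect_equal(cls2$n_members, cls$n_members)
      expect_equal(cls2$phase, cls$phase)
      expect_equal(cls2$column, cls$column + ifelse(cls$column > at, 1L, 0L))
      expect_identical(unname(attr(cls2, "members")),
                       unname(attr(cls, "members")))
      # phase separation: class ids are unique, and same-column classes
      # with different phases stay distinct
      expect_false(any(duplicated(cls2$class_id)))
      pr2 <- project_introns(fam2, prots)
      for (id in cls2$class_id) {
        rowsc <- pr2[sprintf("%d.%d", pr2$column, pr2$phase) == id, ]
        expect_length(unique(rowsc$phase), 1L)
      }
    })
  }
})

test_that("progressive alignment rows degap to the input proteins", {
  prots <- list(make_protein("a", "MKVLATGHERW"),
                make_protein("b", "MKVLGHERW"),
                make_protein("c", "MKVLATGHW"))
  fam <- align_family(prots)
  expect_equal(fam$source, "progressive-nw")
  expect_true(validate_alignment(fam, prots))
  widths <- unique(nchar(fam$rows))
  expect_length(widths, 1L)
  expect_gte(widths, 11L)
  # equal-length family takes the ungapped fast path
  eq <- align_family(list(make_protein("a", "MKVLA"),
                          make_protein("b", "MKVLG")))
  expect_equal(eq$source, "ungapped")
})
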