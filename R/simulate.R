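#' Configuration for the gene-family simulator
#'
#' Describes the evolutionary scenario the simulator emulates: an ancestral
#' intronless canonical gene evolves along a species tree; at `birth_node` a
#' variant copy is born carrying a novel intron at `intron_offset`; each
#' branch below the birth node loses the variant with probability
#' `loss_prob_per_branch`; the variant lineage evolves
#' `variant_rate_multiplier` times faster; annotation dropouts remove genes
#' from the GFF3 but not from the genome.
#'
#' @param tree an [ape::phylo] species tree, or `NULL` to generate a Yule
#'   tree with `n_species` leaves from the seed.
#' @param n_species leaves of the generated tree when `tree` is `NULL`.
#' @param seed integer; fully determines all output.
#' @param birth_node label of the node where the variant is born; default
#'   is the root child subtending more leaves (a deep origin, as for a
#'   variant arising in the ancestor of most of the genus).
#' @param intron_offset coding offset of the variant-defining intron.
#' @param second_intron_offset optional second intron offset.
#' @param loss_prob_per_branch probability in `[0,1]` of variant loss on
#'   each branch below the birth node.
#' @param substitution_rate expected substitutions/site on a branch of
#'   average length (generated trees are rescaled to mean branch length 1).
#' @param variant_rate_multiplier rate multiplier (>= 1) for the variant
#'   lineage.
#' @param annotation_dropout_prob probability that a present variant is
#'   missing from the emitted annotation.
#' @param protosplice_bias plant an AG|GT protosplice site at the insertion
#'   point in the ancestral gene.
#' @param n_codons ancestral CDS length in codons, including the terminal
#'   stop.
#' @param intron_length intron length in nt (GT...AG bounded).
#' @param flank random flanking sequence per side of each gene's contig.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(tree = NULL, n_species = 32L, seed = 1L,
                              birth_node = NULL, intron_offset = 150L,
                              second_intron_offset = NULL,
                              loss_prob_per_branch = 0.1,
                              substitution_rate = 0.02,
                              variant_rate_multiplier = 3,
                              annotation_dropout_prob = 0,
                              protosplice_bias = TRUE,
                              n_codons = 130L, intron_length = 68L,
                              flank = 500L) {
  probs <- c(loss_prob_per_branch, annotation_dropout_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (variant_rate_multiplier < 1) stop("variant_rate_multiplier must be >= 1")
  offs <- c(intron_offset, second_intron_offset)
  if (any(offs < 1L | offs > 3L * n_codons - 1L))
    stop("intron offsets outside ancestral CDS")
  structure(list(tree = tree, n_species = as.integer(n_species),
                 seed = as.integer(seed), birth_node = birth_node,
                 intron_offset = as.integer(intron_offset),
                 second_intron_offset = if (is.null(second_intron_offset))
                   NULL else as.integer(second_intron_offset),
                 loss_prob_per_branch = loss_prob_per_branch,
                 substitution_rate = substitution_rate,
                 variant_rate_multiplier = variant_rate_multiplier,
                 annotation_dropout_prob = annotation_dropout_prob,
                 protosplice_bias = isTRUE(protosplice_bias),
                 n_codons = as.integer(n_codons),
                 intron_length = as.integer(intron_length),
                 flank = as.integer(flank)),
            class = "simulation_config")
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

# random CDS of n_codons codons (terminal stop TAA), no internal stops;
# sampled codon-wise from the 61 sense codons
random_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOPS)
  paste0(paste0(sample(sense, n_codons - 1L, replace = TRUE), collapse = ""),
         "TAA")
}

has_internal_stop <- function(cds) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1L, n - 3L, 3L), seq(3L, n - 3L, 3L))
  any(codons %in% STOPS)
}

set_nt <- function(cds, pos, base) {
  substr(cds, pos, pos) <- base
  cds
}

# plant a four-mer around a coding offset, then repair any stop it creates
# by resampling the non-planted bases of the affected codons
plant_four_mer <- function(cds, offset, four_mer = "AGGT") {
  for (k in 0:3)
    cds <- set_nt(cds, offset - 1L + k, substr(four_mer, k + 1L, k + 1L))
  planted <- (offset - 1L):(offset + 2L)
  guard <- 0L
  while (has_internal_stop(cds)) {
    guard <- guard + 1L
    if (guard > 200L) stop("could not plant four-mer without a stop codon")
    n <- nchar(cds)
    starts <- seq(1L, n - 3L, 3L)
    bad <- starts[substring(cds, starts, starts + 2L) %in% STOPS]
    for (s in bad) {
      free <- setdiff(s:(s + 2L), planted)
      if (!length(free)) stop("planted four-mer forces a stop codon")
      for (p in free) cds <- set_nt(cds, p, sample(BASES, 1L))
    }
  }
  cds
}

#' Evolve a coding sequence by Jukes-Cantor substitutions
#'
#' Independent-site substitutions with expected substitutions/site `d`
#' (each site differs from its ancestor with probability
#' `3/4 (1 - exp(-4 d / 3))`). Substitutions creating an internal stop
#' codon are resampled so the CDS stays translatable; a terminal stop
#' codon is kept fixed. Intron offsets embedded in the gene are untouched
#' (substitutions only, no indels).
#'
#' @param sequence nucleotide string, length divisible by 3.
#' @param d expected substitutions per site (branch length x rate).
#' @return evolved sequence of identical length.
#' @export
evolve_cds <- function(sequence, d) {
  if (d <= 0) return(sequence)
  n <- nchar(sequence)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  p <- 0.75 * (1 - exp(-4 * d / 3))
  chars <- strsplit(sequence, "")[[1L]]
  mutable <- seq_len(n)
  if (substring(sequence, n - 2L, n) %in% STOPS)
    mutable <- seq_len(n - 3L)
  hit <- mutable[stats::runif(length(mutable)) < p]
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  out <- paste0(chars, collapse = "")
  guard <- 0L
  while (has_internal_stop(out)) {
    guard <- guard + 1L
    if (guard > 200L) { # give up: revert offending codons to the ancestor
      starts <- seq(1L, n - 3L, 3L)
      bad <- starts[substring(out, starts, starts + 2L) %in% STOPS]
      for (s in bad)
        substr(out, s, s + 2L) <- substring(sequence, s, s + 2L)
      break
    }
    starts <- seq(1L, n - 3L, 3L)
    bad <- starts[substring(out, starts, starts + 2L) %in% STOPS]
    for (s in bad) {
      resite <- intersect(s:(s + 2L), hit)
      if (!length(resite)) resite <- s:(s + 2L)
      for (i in resite)
        out <- set_nt(out, i, sample(setdiff(BASES, substr(out, i, i)), 1L))
    }
  }
  out
}

# unconstrained JC evolution (introns, flanks)
evolve_dna <- function(sequence, d) {
  if (d <= 0) return(sequence)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  chars <- strsplit(sequence, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  paste0(chars, collapse = "")
}

random_intron <- function(len) {
  paste0("GT", paste0(sample(BASES, len - 4L, replace = TRUE), collapse = ""),
         "AG")
}

#' Simulate a gene family on a species tree
#'
#' Runs the scenario described by [simulation_config()] and returns the
#' per-species genome (one contig per gene with random flanks), the GFF3
#' annotation, the species tree, and a truth record. All randomness flows
#' from the config seed; a fixed seed gives byte-identical output files.
#'
#' The truth record stores both the `birth_node` and the `realized_origin`
#' (the most recent common ancestor of the species that actually retain
#' the variant) — the latter is what any presence-based reconstruction can
#' recover, and differs from the birth node exactly when an entire child
#' lineage of the birth node lost the variant.
#'
#' @param config a [simulation_config].
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `tree.nwk` and `truth.json`.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `features`
#'   (data.frame of GFF3 rows), `tree`, `truth`, and `paths` (when `dir`
#'   was given).
#' @export
simulate_family <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- if (is.null(config$tree)) yule_tree(config$n_species, config$seed)
          else label_nodes(config$tree)
  withr::with_seed(config$seed + 1L, {
    sim_family_body(config, tree, dir)
  })
}

sim_family_body <- function(config, tree, dir) {
  n <- length(tree$tip.label)
  ch <- children_list(tree)
  tips <- descendant_tips(tree)
  root <- n + 1L

  birth <- if (is.null(config$birth_node)) {
    kids <- ch[[root]]
    sizes <- vapply(kids, function(k) length(tips[[k]]), integer(1))
    kids[order(-sizes, kids)][1L]
  } else node_by_label(tree, config$birth_node)

  offsets <- sort(c(config$intron_offset, config$second_intron_offset))
  anc <- random_cds(config$n_codons)
  if (config$protosplice_bias)
    for (o in offsets) anc <- plant_four_mer(anc, o, "AGGT")

  bl <- function(v) {
    e <- which(tree$edge[, 2L] == v)
    if (length(e)) tree$edge.length[e] else 0
  }

  leaf_state <- vector("list", n)
  loss_edges <- list()
  rate <- config$substitution_rate
  mult <- config$variant_rate_multiplier

  rec <- function(v, canon, var_cds, var_introns, var_present) {
    if (v == birth && !var_present) {
      var_present <- TRUE
      var_cds <- canon
      var_introns <- vapply(offsets, function(o)
        random_intron(config$intron_length), character(1))
    }
    if (v <= n) {
      leaf_state[[v]] <<- list(canon = canon, var_cds = var_cds,
                               var_introns = var_introns,
                               var_present = var_present)
      return(invisible())
    }
    for (w in ch[[v]]) {
      d <- bl(w) * rate
      c2 <- evolve_cds(canon, d)
      present2 <- var_present
      vcds2 <- var_cds; vint2 <- var_introns
      if (var_present) {
        if (stats::runif(1L) < config$loss_prob_per_branch) {
          present2 <- FALSE; vcds2 <- NULL; vint2 <- NULL
          loss_edges[[length(loss_edges) + 1L]] <<- data.frame(
            parent = node_label(tree, v), child = node_label(tree, w))
        } else {
          vcds2 <- evolve_cds(var_cds, d * mult)
          vint2 <- vapply(var_introns, evolve_dna, character(1), d * mult)
        }
      }
      rec(w, c2, vcds2, vint2, present2)
    }
  }
  rec(root, anc, NULL, NULL, FALSE)

  # emit genomes and features
  contigs <- character(0)
  feat <- list()
  dropouts <- character(0)
  presence <- stats::setNames(rep("absent", n), tree$tip.label)
  for (v in seq_len(n)) {
    sp <- tree$tip.label[v]
    st <- leaf_state[[v]]
    g <- emit_gene(sp, paste0(sp, "_H2A"), st$canon, integer(0), character(0),
                   config$flank)
    contigs[g$contig] <- g$seq
    feat[[length(feat) + 1L]] <- g$rows
    if (st$var_present) {
      presence[sp] <- "present"
      gv <- emit_gene(sp, paste0(sp, "_VAR"), st$var_cds, offsets,
                      st$var_introns, config$flank)
      contigs[gv$contig] <- gv$seq
      drop <- stats::runif(1L) < config$annotation_dropout_prob
      if (drop) dropouts <- c(dropouts, sp)
      else feat[[length(feat) + 1L]] <- gv$rows
    }
  }
  features <- do.call(rbind, feat)

  present_sp <- names(presence)[presence == "present"]
  realized <- if (length(present_sp) == 0L) NA_character_
              else if (length(present_sp) == 1L) present_sp
              else node_label(tree, ape::getMRCA(tree, present_sp))
  truth <- list(
    birth_node = node_label(tree, birth),
    realized_origin = realized,
    presence = presence,
    loss_edges = if (length(loss_edges)) do.call(rbind, loss_edges)
                 else data.frame(parent = character(0), child = character(0)),
    intron_offsets = offsets,
    dropouts = dropouts,
    seed = config$seed)

  genome <- Biostrings::DNAStringSet(contigs)
  out <- list(genome = genome, features = features, tree = tree, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  gff3 = file.path(dir, "annotation.gff3"),
                  tree = file.path(dir, "tree.nwk"),
                  truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(genome, paths$genome)
    write_gff3(features, paths$gff3)
    ape::write.tree(tree, paths$tree)
    jsonlite::write_json(
      list(birth_node = truth$birth_node,
           realized_origin = truth$realized_origin,
           presence = as.list(truth$presence),
           loss_edges = truth$loss_edges,
           intron_offsets = truth$intron_offsets,
           dropouts = truth$dropouts, seed = truth$seed),
      paths$truth, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- paths
  }
  out
}

# one gene on its own contig with random flanks; returns contig sequence
# and its GFF3 feature rows (1-based inclusive coordinates)
emit_gene <- function(species, gene_id, cds, intron_offsets, intron_seqs,
                      flank, strand = NULL) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  up <- paste0(sample(BASES, flank, replace = TRUE), collapse = "")
  down <- paste0(sample(BASES, flank, replace = TRUE), collapse = "")
  # genomic gene sequence in transcript orientation: exons + introns
  bounds <- c(0L, intron_offsets, nchar(cds))
  exons <- substring(cds, utils::head(bounds, -1L) + 1L, bounds[-1L])
  parts <- character(0)
  for (i in seq_along(exons)) {
    parts <- c(parts, exons[i])
    if (i <= length(intron_seqs)) parts <- c(parts, intron_seqs[i])
  }
  gene_seq <- paste0(parts, collapse = "")
  contig <- paste0(gene_id, "_ctg")
  placed <- if (strand == "-") revcomp(gene_seq) else gene_seq
  seq <- paste0(up, placed, down)

  # CDS segment coordinates within the gene sequence (transcript orientation)
  exon_starts <- integer(length(exons)); pos <- 0L
  for (i in seq_along(exons)) {
    exon_starts[i] <- pos
    pos <- pos + nchar(exons[i])
    if (i <= length(intron_seqs)) pos <- pos + nchar(intron_seqs[i])
  }
  glen <- nchar(gene_seq)
  seg <- data.frame(start = exon_starts, end = exon_starts + nchar(exons))
  if (strand == "-") {
    seg <- data.frame(start = glen - seg$end, end = glen - seg$start)
  }
  seg$start <- seg$start + flank + 1L  # to 1-based contig coordinates
  seg$end <- seg$end + flank
  gene_lo <- flank + 1L; gene_hi <- flank + glen
  phase <- c(0L, (3L - cumsum(nchar(exons)) %% 3L) %% 3L)[seq_along(exons)]
  if (strand == "-") { seg <- seg[rev(seq_len(nrow(seg))), ]; phase <- rev(phase) }
  tx <- paste0(gene_id, ".t1")
  rows <- rbind(
    data.frame(seqid = contig, type = "gene", start = gene_lo, end = gene_hi,
               strand = strand, phase = NA_integer_, ID = gene_id,
               Parent = NA_character_, species = species),
    data.frame(seqid = contig, type = "mRNA", start = gene_lo, end = gene_hi,
               strand = strand, phase = NA_integer_, ID = tx,
               Parent = gene_id, species = species),
    data.frame(seqid = contig, type = "CDS", start = seg$start, end = seg$end,
               strand = strand, phase = phase,
               ID = paste0(tx, ".cds", seq_len(nrow(seg))),
               Parent = tx, species = species))
  list(contig = contig, seq = seq, rows = rows)
}

# write feature rows through rtracklayer so output is standard GFF3
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  gr$type <- features$type
  gr$ID <- features$ID
  parents <- as.list(features$Parent)
  parents[is.na(features$Parent)] <- list(character(0))
  gr$Parent <- IRanges::CharacterList(parents)
  gr$phase <- features$phase
  gr$species <- features$species
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Deterministic worked-example fixture: three variant genes + core gene
#'
#' Builds a four-gene fixture mirroring the canonical worked example: an
#' intronless core histone gene and three variant genes with introns at
#' coding offsets 78 (phase 0, between codons 26 and 27; placed on the
#' minus strand), 170 (phase 2, splitting codon 57) and 150 (phase 0,
#' between codons 50 and 51). The core gene carries the flanking
#' dinucleotide contexts AG|GC at offset 78, CA|GT at offset 150 and CT|GG
#' at offset 170, so protosplice scoring on the fixture reproduces the
#' three qualitative calls (signal, signal, no signal).
#'
#' @param dir output directory for `genome.fa` and `annotation.gff3`.
#' @return list with `paths`, `core_cds`, and a data.frame `genes`
#'   (`gene_id`, `intron_offset`, `strand`).
#' @export
make_fig1_fixture <- function(dir) {
  withr::with_seed(424243L, {
    n_codons <- 130L
    core <- random_cds(n_codons)
    core <- plant_four_mer(core, 78L, "AGGC")
    core <- plant_four_mer(core, 150L, "CAGT")
    core <- plant_four_mer(core, 170L, "CTGG")
    spec <- data.frame(
      gene_id = c("core_H2A", "var_htas1", "var_htz1", "var_his35"),
      intron_offset = c(NA, 78L, 170L, 150L),
      strand = c("+", "-", "+", "+"))
    contigs <- character(0); feat <- list()
    for (i in seq_len(nrow(spec))) {
      offs <- if (is.na(spec$intron_offset[i])) integer(0)
              else spec$intron_offset[i]
      introns <- if (length(offs)) random_intron(68L) else character(0)
      cds <- if (spec$gene_id[i] == "core_H2A") core
             else evolve_cds(core, 0.02)
      g <- emit_gene(spec$gene_id[i], spec$gene_id[i], cds, offs,
                     introns, 500L, strand = spec$strand[i])
      contigs[g$contig] <- g$seq
      feat[[i]] <- g$rows
    }
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  gff3 = file.path(dir, "annotation.gff3"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs),
                                paths$genome)
    write_gff3(do.call(rbind, feat), paths$gff3)
    list(paths = paths, core_cds = core, genes = spec)
  })
}

#' Deterministic two-exon single-gene fixture
#'
#' Emits a GFF3+FASTA pair holding one gene whose first CDS segment (in
#' transcript orientation) has `first_len` coding nucleotides and whose
#' second has `second_len`, separated by an intron, with random flanking
#' sequence; useful for exercising coordinate handling (including on the
#' minus strand).
#'
#' @param dir output directory.
#' @param first_len,second_len CDS segment lengths in nt (sum divisible
#'   by 3).
#' @param strand `"+"` or `"-"`.
#' @param seed integer seed.
#' @param flank flanking length per side.
#' @return list with `paths` (`genome`, `gff3`) and `gene_id`.
#' @export
make_two_exon_fixture <- function(dir, first_len, second_len, strand = "+",
                                  seed = 99L, flank = 500L) {
  stopifnot((first_len + second_len) %% 3L == 0L)
  withr::with_seed(as.integer(seed), {
    cds <- random_cds((first_len + second_len) %/% 3L)
    g <- emit_gene("fixture", "two_exon_gene", cds, as.integer(first_len),
                   random_intron(68L), as.integer(flank), strand = strand)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  gff3 = file.path(dir, "annotation.gff3"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(g$seq, g$contig)),
      paths$genome)
    write_gff3(g$rows, paths$gff3)
    list(paths = paths, gene_id = "two_exon_gene", cds = cds)
  })
}
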