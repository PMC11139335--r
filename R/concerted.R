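#' Per-species paralog monophyly test for concerted evolution
#'
#' Gene conversion between co-resident paralogs homogenizes their
#' sequences, so interconverting partners group together on a gene tree.
#' For each species, the two paralogs are called `"together"` iff they form
#' a cherry (are each other's closest leaves, sharing an immediate parent)
#' in the gene tree, `"apart"` otherwise, and `"undetermined"` when either
#' gene is missing from the tree. Support values are ignored: the call is
#' purely topological.
#'
#' @param gene_tree [ape::phylo] gene tree (rooted or unrooted).
#' @param paralog_pairs data.frame with columns `species`, `gene1`,
#'   `gene2`.
#' @return named character vector over species with values
#'   `together`/`apart`/`undetermined`.
#' @export
paralog_monophyly_test <- function(gene_tree, paralog_pairs) {
  tips <- gene_tree$tip.label
  parent_of_tip <- integer(length(tips))
  for (k in seq_len(nrow(gene_tree$edge)))
    if (gene_tree$edge[k, 2L] <= length(tips))
      parent_of_tip[gene_tree$edge[k, 2L]] <- gene_tree$edge[k, 1L]
  tips_per_node <- table(parent_of_tip)
  out <- character(nrow(paralog_pairs))
  for (i in seq_len(nrow(paralog_pairs))) {
    a <- match(paralog_pairs$gene1[i], tips)
    b <- match(paralog_pairs$gene2[i], tips)
    if (is.na(a) || is.na(b)) { out[i] <- "undetermined"; next }
    pa <- parent_of_tip[a]
    # cherry: same parent and no third leaf hanging off that parent
    out[i] <- if (pa == parent_of_tip[b] &&
                  tips_per_node[as.character(pa)] == 2L) "together" else "apart"
  }
  stats::setNames(out, paralog_pairs$species)
}

#' Split a family alignment at an intron class into per-exon alignments
#'
#' Columns up to and including the class column form exon 1, the rest
#' exon 2. A phase-0 boundary is exact (the class column is the last
#' codon fully upstream); for phase 1/2 the interrupted codon's column is
#' assigned to exon 1.
#'
#' @param family an [aligned_family].
#' @param intron_class one row of a [build_classes()] data.frame (or any
#'   list with `column` and `phase`).
#' @return list of two [aligned_family] objects, `exon1` and `exon2`.
#' @export
split_alignment_by_exon <- function(family, intron_class) {
  b <- intron_class$column
  width <- nchar(family$rows[[1L]])
  if (b < 1L || b > width) stop("class column outside alignment")
  e1 <- vapply(family$rows, substr, character(1), 1L, b)
  e2 <- vapply(family$rows, substr, character(1), b + 1L, width)
  list(exon1 = aligned_family(e1, source = family$source),
       exon2 = aligned_family(e2, source = family$source))
}

#' p-distance matrix between alignment rows
#'
#' Proportion of differing aligned non-gap sites per sequence pair; feeds
#' [nj_tree()] for the per-exon gene trees.
#'
#' @param family an [aligned_family].
#' @return symmetric numeric matrix.
#' @export
p_distance <- function(family) {
  ids <- names(family$rows)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pd <- pairwise_differences(family$rows[[i]], family$rows[[j]])
      d[i, j] <- d[j, i] <- 1 - pd$pct_identity / 100
    }
  }
  d
}
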