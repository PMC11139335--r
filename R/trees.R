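#' Read a rooted species tree from Newick
#'
#' Leaf labels are species ids and must be unique; internal nodes without
#' labels are given stable generated labels (`n<number>`), so every
#' reconstruction result can name its origin node.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick tree from ", path)
  label_nodes(tr)
}

# ensure unique tip labels and fill in missing internal-node labels
label_nodes <- function(tr) {
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  n <- length(tr$tip.label)
  if (is.null(tr$node.label) || !length(tr$node.label))
    tr$node.label <- rep("", tr$Nnode)
  blank <- is.na(tr$node.label) | tr$node.label == ""
  tr$node.label[blank] <- paste0("n", which(blank) + n)
  tr
}

# children of each node, as a list indexed by node number
children_list <- function(tr) {
  n_nodes <- length(tr$tip.label) + tr$Nnode
  ch <- vector("list", n_nodes)
  for (k in seq_len(nrow(tr$edge)))
    ch[[tr$edge[k, 1L]]] <- c(ch[[tr$edge[k, 1L]]], tr$edge[k, 2L])
  ch
}

# leaf tip numbers under each node (a tip is under itself)
descendant_tips <- function(tr) {
  n <- length(tr$tip.label)
  ch <- children_list(tr)
  out <- vector("list", n + tr$Nnode)
  rec <- function(v) {
    if (v <= n) return(out[[v]] <<- v)
    kids <- unlist(lapply(ch[[v]], rec))
    out[[v]] <<- kids
    kids
  }
  rec(n + 1L)
  out
}

node_label <- function(tr, v) {
  n <- length(tr$tip.label)
  if (v <= n) tr$tip.label[v] else tr$node.label[v - n]
}

node_by_label <- function(tr, label) {
  n <- length(tr$tip.label)
  i <- match(label, tr$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tr$node.label)
  if (is.na(j)) stop("no node labelled ", label, " in tree")
  j + n
}

#' Neighbor-joining tree from a distance matrix
#'
#' A deterministic small-tree utility (used by the per-exon concerted
#' evolution test); validates the matrix and delegates to [ape::nj()].
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal and
#'   at least 3 taxa, with row/column names.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || nrow(d) < 3L)
    stop("distance matrix must be square with n >= 3")
  if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ape::nj(d)
}

#' Random Yule (pure-birth) species tree
#'
#' Branch lengths are rescaled to mean 1 so that per-branch expected
#' divergence equals the simulator's substitution rate on an average
#' branch. Fully determined by the seed.
#'
#' @param n_species number of leaves.
#' @param seed integer seed.
#' @return an [ape::phylo] tree with tips `sp01..` and labelled nodes.
#' @export
yule_tree <- function(n_species, seed) {
  tr <- withr::with_seed(as.integer(seed),
                         ape::rphylo(n_species, birth = 1, death = 0))
  tr$edge.length <- tr$edge.length / mean(tr$edge.length)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr$node.label <- NULL
  label_nodes(tr)
}
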