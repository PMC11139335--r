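#' Fitch ancestral-state reconstruction for a single alignment site
#'
#' Standard two-pass Fitch parsimony for an unordered multistate character
#' (for example the residue at one alignment position across species).
#' Tips with unknown state (`NA` or `"?"`) carry the full observed state
#' set. The bottom-up pass yields per-node state sets and the minimum
#' mutation count; the optional top-down pass commits one
#' minimum-mutation assignment (parent state when allowed, else the
#' lexicographically smallest member of the node set).
#'
#' @param tree rooted [ape::phylo] (binary or multifurcating).
#' @param tip_states named character vector over the leaves.
#' @return list with `node_sets` (list indexed by node number),
#'   `root_states` (character vector), `min_changes` (integer), and
#'   `assignment` (named character vector over all node labels).
#' @export
fitch_site_ancestral <- function(tree, tip_states) {
  tree <- label_nodes(tree)
  n <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing))
    stop("no state for leaves: ", paste(missing, collapse = ", "))
  st <- as.character(tip_states[tree$tip.label])
  unknown <- is.na(st) | st == "?"
  alphabet <- sort(unique(st[!unknown]))
  if (!length(alphabet)) stop("all tip states unknown")

  ch <- children_list(tree)
  sets <- vector("list", n + tree$Nnode)
  changes <- 0L
  up <- function(v) {
    if (v <= n) {
      sets[[v]] <<- if (unknown[v]) alphabet else st[v]
      return(sets[[v]])
    }
    kid_sets <- lapply(ch[[v]], up)
    # Hartigan's generalization for multifurcations: keep the states of
    # maximal child support; k - max(support) changes are incurred here.
    # On a binary node this is classic Fitch (intersection if nonempty,
    # else union with one change).
    all_states <- sort(unique(unlist(kid_sets)))
    support <- vapply(all_states, function(a)
      sum(vapply(kid_sets, function(s) a %in% s, logical(1))), integer(1))
    keep <- all_states[support == max(support)]
    changes <<- changes + length(kid_sets) - max(support)
    sets[[v]] <<- keep
    keep
  }
  root <- n + 1L
  up(root)

  assignment <- character(n + tree$Nnode)
  down <- function(v, parent_state) {
    s <- sets[[v]]
    assignment[v] <<- if (!is.null(parent_state) && parent_state %in% s)
      parent_state else s[1L]
    for (w in ch[[v]] %||% integer(0)) down(w, assignment[v])
  }
  down(root, NULL)
  names(assignment) <- vapply(seq_len(n + tree$Nnode), function(v)
    node_label(tree, v), character(1))
  list(node_sets = sets, root_states = sets[[root]],
       min_changes = changes, assignment = assignment)
}

#' Enumerate differences between two aligned sequences
#'
#' Positions are 1-based alignment columns; percent identity is computed
#' over aligned non-gap pairs only.
#'
#' @param seq1,seq2 equal-length (aligned) character strings.
#' @return list with `differences` (data.frame `position`, `res1`, `res2`)
#'   and `pct_identity` (0-100; `NaN` when no pair is aligned).
#' @export
pairwise_differences <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2))
    stop("sequences differ in length (", nchar(seq1), " vs ", nchar(seq2), ")")
  a <- strsplit(seq1, "")[[1L]]
  b <- strsplit(seq2, "")[[1L]]
  aligned <- a != "-" & b != "-"
  diff <- aligned & a != b
  list(differences = data.frame(position = which(diff),
                                res1 = a[diff], res2 = b[diff]),
       pct_identity = 100 * sum(aligned & a == b) / sum(aligned))
}
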