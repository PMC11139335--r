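#' Dollo reconstruction of a presence/absence character on a species tree
#'
#' Intron positions (and the variant genes they define) are treated as
#' Dollo characters: gained once, lost any number of times. The origin is
#' the most recent common ancestor of the present leaves (any deeper origin
#' only adds losses, so the MRCA is the unique parsimony optimum); losses
#' are the maximal clades within the origin clade containing no present
#' leaf, one loss per clade. Leaves with unknown state (the "?" species,
#' where no homolog could be assessed) are excluded from the loss count:
#' a maximal no-present clade consisting only of unknowns is reported as a
#' possible loss, and `n_losses_max` counts unknowns as losses, giving the
#' "some k" vs "up to m" pair of bounds.
#'
#' @param tree rooted [ape::phylo] (multifurcations allowed; a maximal
#'   absent clade under a multifurcation counts one loss per entirely
#'   absent child subtree).
#' @param pattern named character vector over all tree leaves with values
#'   `"present"`/`"absent"`/`"unknown"` (aliases `1`/`0`/`?` accepted).
#' @return object of class `dollo_result`: `origin_node` (label),
#'   `origin_node_num`, `loss_edges` (data.frame `parent`, `child`,
#'   `child_num`, `kind` in `loss`/`possible_loss`), `n_losses`,
#'   `n_losses_max`, `ambiguous`, plus the normalized `pattern`.
#' @export
dollo_reconstruct <- function(tree, pattern) {
  tree <- label_nodes(tree)
  pattern <- normalize_pattern(pattern, tree)
  n <- length(tree$tip.label)
  present <- which(pattern[tree$tip.label] == "present")
  if (!length(present))
    stop("all-absent pattern: no present leaf to place the character")
  origin <- if (length(present) == 1L) present
            else ape::getMRCA(tree, tree$tip.label[present])

  tips <- descendant_tips(tree)
  ch <- children_list(tree)
  state <- pattern[tree$tip.label]
  has_present <- vapply(tips, function(tp) any(state[tp] == "present"), logical(1))
  has_absent <- vapply(tips, function(tp) any(state[tp] == "absent"), logical(1))

  losses <- list()
  walk <- function(v) {
    for (w in ch[[v]] %||% integer(0)) {
      if (!has_present[w]) {
        kind <- if (has_absent[w]) "loss" else "possible_loss"
        losses[[length(losses) + 1L]] <<- data.frame(
          parent = node_label(tree, v), child = node_label(tree, w),
          child_num = w, kind = kind)
      } else walk(w)
    }
  }
  walk(origin)
  loss_edges <- if (length(losses)) do.call(rbind, losses)
                else data.frame(parent = character(0), child = character(0),
                                child_num = integer(0), kind = character(0))
  n_losses <- sum(loss_edges$kind == "loss")
  n_max <- nrow(loss_edges)
  structure(list(origin_node = node_label(tree, origin),
                 origin_node_num = origin,
                 loss_edges = loss_edges,
                 n_losses = n_losses,
                 n_losses_max = n_max,
                 ambiguous = n_max > n_losses,
                 pattern = pattern,
                 tree = tree),
            class = "dollo_result")
}

#' @export
print.dollo_result <- function(x, ...) {
  cat(sprintf("<dollo_result> origin %s; %d independent loss(es)%s\n",
              x$origin_node, x$n_losses,
              if (x$ambiguous) sprintf(" (up to %d counting unknowns)",
                                       x$n_losses_max) else ""))
  invisible(x)
}

#' Number of independent losses in a Dollo reconstruction
#'
#' Adjacent absent leaves under one maximal absent clade count as a single
#' loss.
#'
#' @param result a `dollo_result`.
#' @return integer loss count (excluding unknown-only clades).
#' @export
count_independent_losses <- function(result) {
  stopifnot(inherits(result, "dollo_result"))
  result$n_losses
}

normalize_pattern <- function(pattern, tree) {
  map <- c("present" = "present", "1" = "present", "+" = "present",
           "absent" = "absent", "0" = "absent", "-" = "absent",
           "unknown" = "unknown", "?" = "unknown", "NA" = "unknown")
  v <- map[as.character(pattern)]
  if (anyNA(v)) stop("presence states must be present/absent/unknown (1/0/?)")
  names(v) <- names(pattern)
  missing <- setdiff(tree$tip.label, names(v))
  if (length(missing))
    stop("no state for species: ", paste(missing, collapse = ", "))
  v[tree$tip.label]
}

#' Read / write a presence TSV (species, state in 1/0/?)
#' @param path TSV path with columns `species`, `state`.
#' @return named character vector of states.
#' @export
read_presence <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  stats::setNames(df$state, df$species)
}

#' @rdname read_presence
#' @param pattern named state vector.
#' @export
write_presence <- function(pattern, path) {
  rev_map <- c(present = "1", absent = "0", unknown = "?")
  st <- ifelse(as.character(pattern) %in% names(rev_map),
               rev_map[as.character(pattern)], as.character(pattern))
  utils::write.table(data.frame(species = names(pattern), state = st),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
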