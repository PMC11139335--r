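# Independent brute-force oracles used to validate the reconstruction code.
# They share no logic with the implementation: the Dollo oracle enumerates
# single-gain loss-set scenarios by subset search, the Fitch oracle
# enumerates all internal labelings.

# random rooted topology with labelled nodes
random_topology <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, br = NULL)
    tr$tip.label <- paste0("t", seq_len(n))
    introtrace:::label_nodes(tr)
  })
}

# logical node x leaf descendant matrix
desc_matrix <- function(tree) {
  tips <- introtrace:::descendant_tips(tree)
  n <- length(tree$tip.label)
  m <- matrix(FALSE, length(tips), n)
  for (v in seq_along(tips)) m[v, tips[[v]]] <- TRUE
  m
}

# minimum number of losses over all single-gain scenarios explaining a
# binary presence pattern, by iterative-deepening subset enumeration
dollo_oracle <- function(tree, present_leaves) {
  n <- length(tree$tip.label)
  M <- desc_matrix(tree)
  present <- tree$tip.label %in% present_leaves
  stopifnot(any(present))
  parent <- integer(n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge)))
    parent[tree$edge[k, 2L]] <- tree$edge[k, 1L]
  best <- Inf
  for (g in seq_len(n + tree$Nnode)) {
    if (!all(M[g, present])) next         # origin must cover present leaves
    # descendants of g (candidate loss-edge children)
    desc <- which(vapply(seq_len(n + tree$Nnode), function(w)
      w != g && all(M[w, ] <= M[g, ]), logical(1)))
    found <- FALSE
    for (k in 0:length(desc)) {
      if (k >= best) break
      combos <- if (k == 0L) list(integer(0))
                else asplit(utils::combn(desc, k), 2L)
      for (S in combos) {
        lost <- if (length(S)) apply(M[S, , drop = FALSE], 2L, any)
                else rep(FALSE, n)
        if (identical(unname(M[g, ] & !lost), unname(present))) {
          best <- min(best, k); found <- TRUE; break
        }
      }
      if (found) break
    }
  }
  best
}

# minimum mutation count by enumerating all internal-node labelings
fitch_oracle <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  alphabet <- sort(unique(as.character(tip_states)))
  m <- tree$Nnode
  grids <- do.call(expand.grid,
                   c(rep(list(alphabet), m), stringsAsFactors = FALSE))
  st <- as.character(tip_states[tree$tip.label])
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    lab <- c(st, as.character(grids[r, ]))
    changes <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
    best <- min(best, changes)
  }
  best
}

# closed-form Welch statistic, written independently of the implementation
welch_closed_form <- function(x, y, alternative) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- if (alternative == "less") stats::pt(t, df) else
    stats::pt(t, df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

# small constructor for in-memory annotated proteins
make_protein <- function(gene_id, aa, offsets = integer(0),
                         species = gene_id, cds = NA_character_) {
  introns <- if (length(offsets)) {
    do.call(rbind, lapply(sort(offsets), function(o)
      as.data.frame(intron_codon_phase(o))))
  } else {
    data.frame(coding_offset = integer(0), codon_index = integer(0),
               phase = integer(0), boundary = logical(0))
  }
  structure(list(gene_id = gene_id, species_id = species, aa = aa,
                 cds = cds, introns = introns),
            class = "annotated_protein")
}
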