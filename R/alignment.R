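#' Aligned protein family
#'
#' A named character vector of equal-length gapped rows (gap character
#' `-`). The degapped row of every gene must equal its protein sequence
#' exactly; [validate_alignment()] enforces this against a set of annotated
#' proteins and signals a stale alignment otherwise.
#'
#' @param rows named character vector of gapped sequences.
#' @param source provenance label (`"external"`, `"ungapped"`,
#'   `"progressive-nw"`).
#' @return object of class `aligned_family`.
#' @export
aligned_family <- function(rows, source = "external") {
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("alignment rows must have unique names")
  if (length(unique(nchar(rows))) > 1L)
    stop("alignment rows differ in length")
  structure(list(rows = rows, source = source), class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family> %d sequences x %d columns (%s)\n",
              length(x$rows), if (length(x$rows)) nchar(x$rows[[1L]]) else 0L,
              x$source))
  invisible(x)
}

#' Read an aligned FASTA into an [aligned_family]
#' @param path aligned FASTA path.
#' @export
read_alignment <- function(path) {
  xs <- Biostrings::readAAStringSet(path)
  rows <- stats::setNames(as.character(xs), sub("\\s.*$", "", names(xs)))
  aligned_family(rows, source = "external")
}

#' Write an [aligned_family] to FASTA
#' @param family an [aligned_family].
#' @param path output path.
#' @export
write_alignment <- function(family, path) {
  xs <- Biostrings::AAStringSet(family$rows)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Check that an alignment matches a set of annotated proteins
#'
#' Every annotated gene must be present as a row whose degapped sequence
#' equals the gene's protein exactly; a mismatch names the offending gene
#' (the usual cause is an alignment computed from a stale sequence set).
#'
#' @param family an [aligned_family].
#' @param proteins list of `annotated_protein` objects.
#' @export
validate_alignment <- function(family, proteins) {
  for (p in proteins) {
    row <- family$rows[p$gene_id]
    if (is.na(row)) stop("gene ", p$gene_id, " missing from alignment")
    if (gsub("-", "", row) != p$aa)
      stop("degapped alignment row of gene ", p$gene_id,
           " does not match its protein sequence (stale alignment?)")
  }
  invisible(TRUE)
}

#' Align a protein family
#'
#' Families whose members all have equal length (the indel-free case, as
#' produced by the default simulator mode) are passed through as an
#' ungapped column-for-column alignment. Otherwise a deterministic
#' progressive Needleman-Wunsch (BLOSUM62, affine gaps, ties resolved
#' toward the diagonal, merge in input order) is used. An externally
#' computed alignment can always be supplied instead via
#' [read_alignment()].
#'
#' @param proteins list of `annotated_protein` objects.
#' @param gap_open,gap_ext affine gap penalties (negative).
#' @return an [aligned_family].
#' @export
align_family <- function(proteins, gap_open = -10, gap_ext = -1) {
  seqs <- vapply(proteins, `[[`, character(1), "aa")
  names(seqs) <- vapply(proteins, `[[`, character(1), "gene_id")
  if (length(unique(nchar(seqs))) <= 1L)
    return(aligned_family(seqs, source = "ungapped"))
  prof <- matrix(strsplit(seqs[[1L]], "")[[1L]], nrow = 1L)
  rownames(prof) <- names(seqs)[1L]
  for (i in seq_along(seqs)[-1L]) {
    prof <- nw_profile(prof, strsplit(seqs[[i]], "")[[1L]], names(seqs)[i],
                       gap_open, gap_ext)
  }
  rows <- apply(prof, 1L, paste0, collapse = "")
  aligned_family(rows[names(seqs)], source = "progressive-nw")
}

# profile-to-sequence global alignment with affine gaps.
# Tie-break order: diagonal > gap-in-sequence (consume profile column) >
# gap-in-profile, making the result independent of floating-point noise.
nw_profile <- function(prof, seq, seq_name, gap_open, gap_ext) {
  S <- blosum62()
  n <- ncol(prof); m <- length(seq)
  seq <- aa_canon(seq, S)
  # mean substitution score of a residue against a profile column
  col_score <- function(j, a) {
    col <- prof[, j]
    res <- col[col != "-"]
    if (!length(res)) return(0)
    mean(S[cbind(aa_canon(res, S), rep(a, length(res)))])
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # match state
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in sequence (profile col vs -)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in profile (- vs residue)
  M[1L, 1L] <- 0
  for (i in seq_len(n) + 1L)
    X[i, 1L] <- gap_open + gap_ext * (i - 2L)
  for (j in seq_len(m) + 1L)
    Y[1L, j] <- gap_open + gap_ext * (j - 2L)
  ptrM <- matrix(0L, n + 1L, m + 1L)
  ptrX <- matrix(0L, n + 1L, m + 1L)
  ptrY <- matrix(0L, n + 1L, m + 1L)
  sc <- matrix(0, n, m)
  for (j in seq_len(m))
    for (i in seq_len(n)) sc[i, j] <- col_score(i, seq[j])
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      cand <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      k <- which.max(cand)
      M[i, j] <- cand[k] + sc[i - 1L, j - 1L]
      ptrM[i, j] <- k
      candx <- c(M[i - 1L, j] + gap_open, X[i - 1L, j] + gap_ext,
                 Y[i - 1L, j] + gap_open)
      k <- which.max(candx)
      X[i, j] <- candx[k]; ptrX[i, j] <- k
      candy <- c(M[i, j - 1L] + gap_open, X[i, j - 1L] + gap_open,
                 Y[i, j - 1L] + gap_ext)
      k <- which.max(candy)
      Y[i, j] <- candy[k]; ptrY[i, j] <- k
    }
  }
  # traceback from the best end state (M preferred on ties)
  st <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L]))
  i <- n + 1L; j <- m + 1L
  ops <- character(0)
  while (i > 1L || j > 1L) {
    if (i == 1L) st <- 3L else if (j == 1L) st <- 2L
    if (st == 1L) {
      ops <- c("M", ops); st <- ptrM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (st == 2L) {
      ops <- c("X", ops); st <- ptrX[i, j]; i <- i - 1L
    } else {
      ops <- c("Y", ops); st <- ptrY[i, j]; j <- j - 1L
    }
  }
  out <- matrix("-", nrow(prof) + 1L, length(ops))
  rownames(out) <- c(rownames(prof), seq_name)
  pi <- 0L; sj <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] %in% c("M", "X")) {
      pi <- pi + 1L
      out[seq_len(nrow(prof)), k] <- prof[, pi]
    }
    if (ops[k] %in% c("M", "Y")) {
      sj <- sj + 1L
      out[nrow(out), k] <- seq[sj]
    }
  }
  out
}
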