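#' Naive six-frame rescue scan for unannotated gene copies
#'
#' Translates every contig in all six frames and scores ungapped local
#' matches of a query peptide with BLOSUM62, reporting windows whose score
#' reaches `min_score`. This is a qualitative re-search for gene copies
#' missing from an annotation (annotation dropouts); it performs no gapped
#' extension and no e-value statistics.
#'
#' @param query_peptide amino-acid string, at least 15 residues (callers
#'   should pass the longest exon's peptide so hits are not split by
#'   introns).
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @param min_score minimum BLOSUM62 window score to report; default is 60%
#'   of the query's self-score.
#' @param window window length in residues; defaults to the query length.
#' @return data.frame with columns `contig`, `strand`, `frame` (1..3),
#'   `start`, `end` (1-based genomic nucleotide interval of the window),
#'   `score`, sorted by decreasing score (ties: contig, strand, frame,
#'   start). Zero rows when nothing reaches `min_score`.
#' @export
rescue_scan <- function(query_peptide, genome, min_score = NULL, window = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  q <- strsplit(toupper(query_peptide), "")[[1L]]
  if (length(q) < 15L) stop("query peptide must be at least 15 aa")
  S <- blosum62()
  q <- aa_canon(q, S)
  w <- min(window %||% length(q), length(q))
  qw <- q[seq_len(w)]
  if (is.null(min_score)) min_score <- 0.6 * sum(S[cbind(qw, qw)])

  hits <- list()
  for (contig in names(genome)) {
    fwd <- toupper(as.character(genome[[contig]]))
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      for (frame in 1:3) {
        n_aa <- (L - frame + 1L) %/% 3L
        if (n_aa < w) next
        nt <- substr(s, frame, frame + 3L * n_aa - 1L)
        t_aa <- strsplit(translate_frame(nt), "")[[1L]]
        t_aa <- aa_canon(t_aa, S)
        # window score = sum over i of S[q_i, t_{j+i-1}], via shifted rows
        nwin <- n_aa - w + 1L
        sc <- numeric(nwin)
        for (i in seq_len(w))
          sc <- sc + S[cbind(rep(qw[i], nwin), t_aa[i:(i + nwin - 1L)])]
        keep <- which(sc >= min_score)
        for (j in keep) {
          nt_start <- frame + 3L * (j - 1L)
          nt_end <- nt_start + 3L * w - 1L
          if (strand == "-") {
            tmp <- nt_start
            nt_start <- L - nt_end + 1L
            nt_end <- L - tmp + 1L
          }
          hits[[length(hits) + 1L]] <- data.frame(
            contig = contig, strand = strand, frame = frame,
            start = nt_start, end = nt_end, score = sc[j])
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(contig = character(0), strand = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$contig, h$strand, h$frame, h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# frame translation that tolerates internal stops (reported as '*')
translate_frame <- function(nt) {
  n <- nchar(nt)
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}
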