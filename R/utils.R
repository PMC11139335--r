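`%||%` <- function(a, b) if (is.null(a)) b else a

# one-line stage logging; pipeline bookkeeping mirrors record counts per stage
it_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# reverse complement on a plain character string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# map residues to BLOSUM62 rows, unknown characters scored as 'X'
aa_canon <- function(chars, mat) {
  chars[!chars %in% rownames(mat)] <- "X"
  chars
}
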