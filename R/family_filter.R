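#' Homolog set: candidate gene-family members with search provenance
#'
#' @param records list of `annotated_protein` objects with unique gene ids.
#' @param provenance optional named numeric vector of similarity-search
#'   e-values, named by gene id.
#' @return object of class `homolog_set` with fields `records`,
#'   `provenance`, `members` (collapse bookkeeping: representative ->
#'   member ids).
#' @export
homolog_set <- function(records, provenance = NULL) {
  ids <- vapply(records, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene ids in homolog set")
  structure(list(records = stats::setNames(records, ids),
                 provenance = provenance,
                 members = stats::setNames(as.list(ids), ids)),
            class = "homolog_set")
}

#' @export
print.homolog_set <- function(x, ...) {
  cat(sprintf("<homolog_set> %d records\n", length(x$records)))
  invisible(x)
}

#' Drop candidate homologs longer than a length cutoff
#'
#' Histone proteins are short; candidates longer than `max_aa` residues
#' (strictly more — a protein of exactly `max_aa` is kept) are treated as
#' dubious and removed.
#'
#' @param set a [homolog_set].
#' @param max_aa inclusive length cutoff in residues (default 200).
#' @export
length_filter <- function(set, max_aa = 200L) {
  keep <- vapply(set$records, function(p) nchar(p$aa) <= max_aa, logical(1))
  removed <- names(set$records)[!keep]
  if (length(removed))
    it_log("length_filter", "removed %d record(s) > %d aa: %s",
           length(removed), max_aa, paste(removed, collapse = ", "))
  subset_homolog_set(set, names(set$records)[keep])
}

#' Collapse identical records to one representative
#'
#' At `level = "protein"`, records sharing both an identical amino-acid
#' sequence and identical intron coding offsets collapse to one
#' representative (two genes with the same protein but introns at different
#' positions stay separate). At `level = "nucleotide"`, one representative
#' is kept per distinct CDS nucleotide sequence. The representative is the
#' lexicographically smallest gene id of the group, so output is independent
#' of input order; all member ids are recorded in `$members`.
#'
#' @param set a [homolog_set].
#' @param level `"protein"` or `"nucleotide"`.
#' @export
collapse_identical <- function(set, level = c("protein", "nucleotide")) {
  level <- match.arg(level)
  key <- vapply(set$records, function(p) {
    if (level == "protein")
      paste(p$aa, paste(p$introns$coding_offset, collapse = ","), sep = "|")
    else p$cds
  }, character(1))
  if (level == "nucleotide" && anyNA(key))
    stop("nucleotide-level collapse requires CDS sequences on all records")
  groups <- split(names(set$records), key)
  rep_of <- vapply(groups, function(g) sort(g)[1L], character(1))
  members <- lapply(groups, function(g) sort(unique(unlist(set$members[g]))))
  o <- order(rep_of)
  out <- subset_homolog_set(set, rep_of[o])
  out$members <- stats::setNames(members[o], rep_of[o])
  out
}

#' Filter candidates by similarity-search e-value
#'
#' Records with an e-value above `max_evalue` are removed; records without
#' provenance pass with a warning (the external search is pluggable and a
#' hits table may cover only part of the set).
#'
#' @param set a [homolog_set].
#' @param max_evalue inclusive e-value cutoff (default 1e-10).
#' @export
evalue_filter <- function(set, max_evalue = 1e-10) {
  ids <- names(set$records)
  if (is.null(set$provenance) || !length(set$provenance)) {
    warning("no search provenance: all ", length(ids),
            " records retained", call. = FALSE)
    return(set)
  }
  ev <- set$provenance[ids]
  missing <- ids[is.na(ev)]
  if (length(missing))
    warning("no e-value for ", length(missing),
            " record(s); retained: ", paste(missing, collapse = ", "),
            call. = FALSE)
  keep <- ids[is.na(ev) | ev <= max_evalue]
  subset_homolog_set(set, keep)
}

subset_homolog_set <- function(set, ids) {
  ids <- ids[ids %in% names(set$records)]
  structure(list(records = set$records[ids],
                 provenance = set$provenance,
                 members = set$members[ids]),
            class = "homolog_set")
}

#' Write collapse membership to a sidecar TSV
#'
#' @param set a [homolog_set] (after [collapse_identical()]).
#' @param path output TSV path with columns `representative`, `members`.
#' @export
write_members_tsv <- function(set, path) {
  df <- data.frame(representative = names(set$members),
                   members = vapply(set$members, paste, character(1),
                                    collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BLAST outfmt-6-like hits table into a provenance vector
#'
#' Only the `query`(1), `subject`(2) and `evalue`(11) columns are used; the
#' best (smallest) e-value per subject is kept.
#'
#' @param path tabular hits file (no header).
#' @return named numeric vector of e-values, named by subject id.
#' @export
read_hits_table <- function(path) {
  h <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  ev_col <- if (ncol(h) >= 11L) 11L else 3L
  ev <- tapply(h[[ev_col]], h[[2L]], min)
  stats::setNames(as.numeric(ev), names(ev))
}
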