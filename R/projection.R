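#' Project intron positions onto a protein multiple alignment
#'
#' Each intron is anchored to the alignment column of its `codon_index`
#' residue (for a phase-0 intron that is the upstream residue; for phase
#' 1/2 the interrupted residue), counting non-gap characters along the
#' gene's row. The phase is carried through unchanged.
#'
#' @param family an [aligned_family].
#' @param proteins list of `annotated_protein` objects; every annotated
#'   gene must be present in the alignment with a consistent row.
#' @return data.frame with columns `gene_id`, `column` (1-based alignment
#'   column), `phase`, `coding_offset`.
#' @export
project_introns <- function(family, proteins) {
  validate_alignment(family, proteins)
  out <- list()
  for (p in proteins) {
    if (!nrow(p$introns)) next
    row <- strsplit(family$rows[[p$gene_id]], "")[[1L]]
    res_col <- which(row != "-")  # residue index -> alignment column
    for (k in seq_len(nrow(p$introns))) {
      ci <- p$introns$codon_index[k]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = p$gene_id, column = res_col[ci],
        phase = p$introns$phase[k],
        coding_offset = p$introns$coding_offset[k])
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), column = integer(0),
                      phase = integer(0), coding_offset = integer(0)))
  do.call(rbind, out)
}

#' Group projected introns into shared-position classes
#'
#' Two projected introns belong to the same class iff they share both the
#' alignment column and the phase — matching is exact, with no sliding
#' tolerance, and a class can never contain two phases (near positions in
#' different phases are distinct characters). Class ids are
#' `"{column}.{phase}"`, the field's column.phase notation.
#'
#' @param projected data.frame from [project_introns()].
#' @return data.frame with columns `class_id`, `column`, `phase`,
#'   `n_members`, sorted by column then phase, carrying the member gene ids
#'   as a list in `attr(, "members")` (named by class id).
#' @export
build_classes <- function(projected) {
  if (!nrow(projected)) {
    out <- data.frame(class_id = character(0), column = integer(0),
                      phase = integer(0), n_members = integer(0))
    attr(out, "members") <- list()
    return(out)
  }
  key <- sprintf("%d.%d", projected$column, projected$phase)
  groups <- split(projected, key)
  df <- do.call(rbind, lapply(groups, function(g)
    data.frame(class_id = sprintf("%d.%d", g$column[1L], g$phase[1L]),
               column = g$column[1L], phase = g$phase[1L],
               n_members = length(unique(g$gene_id)))))
  o <- order(df$column, df$phase)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "members") <- stats::setNames(
    lapply(groups[o], function(g) sort(unique(g$gene_id))), df$class_id)
  df
}

#' Assign putative orthologs of a reference gene by shared intron classes
#'
#' The members of each class containing a reference-gene intron are the
#' putative orthologs of the reference variant. When the reference carries
#' several introns, members sharing only a subset are flagged partial,
#' naming the absent reference introns (the variant copy may have lost one
#' of them).
#'
#' @param classes output of [build_classes()].
#' @param reference_gene_id gene id of the reference variant; an error if
#'   it has no projected intron.
#' @return list with `reference_classes` (character vector of class ids),
#'   `orthologs` (data.frame `gene_id`, `n_shared`, `partial`, `flag`), and
#'   `members` (list class id -> member gene ids).
#' @export
assign_orthologs <- function(classes, reference_gene_id) {
  members <- attr(classes, "members")
  ref_classes <- names(members)[vapply(members, function(m)
    reference_gene_id %in% m, logical(1))]
  if (!length(ref_classes))
    stop("reference gene ", reference_gene_id,
         " has no projected intron in any class")
  genes <- sort(unique(unlist(members[ref_classes])))
  shared <- vapply(genes, function(g)
    sum(vapply(members[ref_classes], function(m) g %in% m, logical(1))),
    integer(1))
  flag <- vapply(genes, function(g) {
    absent <- ref_classes[!vapply(members[ref_classes], function(m)
      g %in% m, logical(1))]
    if (!length(absent)) ""
    else sprintf("partial (intron %s absent)", paste(absent, collapse = ","))
  }, character(1))
  list(reference_classes = ref_classes,
       orthologs = data.frame(gene_id = genes, n_shared = unname(shared),
                              partial = unname(shared) < length(ref_classes),
                              flag = unname(flag)),
       members = members[ref_classes])
}

#' Score an intron insertion point against the protosplice consensus
#'
#' New introns preferentially insert at exonic AG|GT ("protosplice")
#' sites. Given the coding sequence of an intronless paralog and the
#' homologous insertion offset, this extracts the 2 nt upstream + 2 nt
#' downstream four-mer, counts positional matches to A,G,G,T, and calls a
#' protosplice signal when either flanking dinucleotide matches in full
#' (upstream == AG or downstream == GT).
#'
#' @param core_cds coding sequence of the intronless paralog.
#' @param insertion_offset homologous coding offset of the insertion point;
#'   must satisfy `2 <= insertion_offset <= nchar(core_cds) - 2`.
#' @return list with `four_mer`, `matches` (logical length-4),
#'   `n_matches`, `signal`.
#' @export
flanking_site_score <- function(core_cds, insertion_offset) {
  core_cds <- toupper(core_cds)
  n <- nchar(core_cds)
  insertion_offset <- as.integer(insertion_offset)
  if (insertion_offset < 2L || insertion_offset > n - 2L)
    stop("insertion offset ", insertion_offset,
         " too close to CDS ends (need 2 nt context on both sides)")
  four <- substr(core_cds, insertion_offset - 1L, insertion_offset + 2L)
  chars <- strsplit(four, "")[[1L]]
  matches <- chars == c("A", "G", "G", "T")
  up <- substr(four, 1L, 2L); down <- substr(four, 3L, 4L)
  list(four_mer = paste0(up, "|", down), matches = matches,
       n_matches = sum(matches), signal = up == "AG" || down == "GT")
}

#' Map a coding offset from one gene to another through the alignment
#'
#' Converts the donor's intron position to its alignment column, reads off
#' the target residue at that column, and reconstructs the target's coding
#' offset preserving phase. When the target has a gap at the column the
#' position is declared unmappable rather than guessed.
#'
#' @param family an [aligned_family] containing both genes.
#' @param donor_gene,target_gene gene ids.
#' @param donor_offset coding offset in the donor.
#' @return list with `status` (`"ok"` or `"unmappable"`) and `offset`
#'   (integer, `NA` when unmappable).
#' @export
homologous_offset <- function(family, donor_gene, donor_offset, target_gene) {
  ann <- intron_codon_phase(donor_offset)
  drow <- strsplit(family$rows[[donor_gene]], "")[[1L]]
  trow <- strsplit(family$rows[[target_gene]], "")[[1L]]
  col <- which(drow != "-")[ann$codon_index]
  if (is.na(col)) stop("donor offset beyond donor sequence")
  if (trow[col] == "-")
    return(list(status = "unmappable", offset = NA_integer_, column = col))
  t_res <- sum(trow[seq_len(col)] != "-")
  offset <- if (ann$phase == 0L) 3L * t_res else 3L * (t_res - 1L) + ann$phase
  list(status = "ok", offset = as.integer(offset), column = col)
}

#' Write per-class and per-gene projection tables
#'
#' @param classes output of [build_classes()].
#' @param projected output of [project_introns()].
#' @param class_path,projection_path output TSV paths.
#' @export
write_projection_tables <- function(classes, projected, class_path,
                                    projection_path) {
  members <- attr(classes, "members")
  cls <- classes
  cls$member_gene_ids <- vapply(cls$class_id, function(id)
    paste(members[[id]], collapse = ","), character(1))
  utils::write.table(cls, class_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(projected, projection_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(class_path)
}
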