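#' Gene model: strand-aware CDS layout of one gene on one contig
#'
#' A gene model records the CDS segments of a single protein-coding
#' transcript in transcript (5'->3') orientation, using 0-based half-open
#' genomic intervals. Models whose total CDS length is not divisible by 3
#' are rejected: such genes are treated as dubious annotations and excluded
#' rather than repaired.
#'
#' @param gene_id,species_id,contig_id identifiers.
#' @param strand `"+"` or `"-"`.
#' @param cds_segments data.frame with integer columns `start`, `end`
#'   (0-based half-open genomic coordinates), ordered in transcript
#'   orientation: ascending genomic start on `+`, descending on `-`.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species_id, contig_id, strand, cds_segments) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  seg <- as.data.frame(cds_segments)[, c("start", "end")]
  seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
  if (any(seg$end <= seg$start)) stop("empty or reversed CDS segment")
  o <- order(seg$start)
  if (nrow(seg) > 1L) {
    s <- seg[o, ]
    if (any(s$start[-1L] < s$end[-nrow(s)]))
      stop("overlapping CDS segments in gene ", gene_id)
    want <- if (strand == "+") o else rev(o)
    if (!identical(seq_len(nrow(seg)), want) &&
        !identical(seg$start, seg$start[want])) {
      # accept any input order but store transcript orientation
    }
    seg <- seg[want, , drop = FALSE]
    rownames(seg) <- NULL
  }
  len <- sum(seg$end - seg$start)
  if (len %% 3L != 0L)
    stop("CDS length ", len, " of gene ", gene_id, " not divisible by 3")
  structure(
    list(gene_id = gene_id, species_id = species_id, contig_id = contig_id,
         strand = strand, cds_segments = seg, cds_length = len),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s%s, %d CDS segment(s), %d nt\n",
              x$gene_id, x$species_id, x$contig_id, x$strand,
              nrow(x$cds_segments), x$cds_length))
  invisible(x)
}

#' Parse protein-coding gene models from a GFF3 annotation
#'
#' Groups `CDS` features by their parent transcript, resolves each gene to a
#' single model (the transcript with the longest total CDS; ties broken by
#' lexicographically smallest transcript id), converts GFF3 1-based
#' inclusive coordinates to the internal 0-based half-open convention, and
#' drops — with a warning — genes whose CDS length is not a multiple of 3.
#' Only the CDS portion of exons is considered; UTR exons are ignored.
#'
#' @param gff3 path to a GFF3 file with `CDS` features carrying `Parent`
#'   attributes.
#' @param genome a [Biostrings::DNAStringSet] (or path to a FASTA file)
#'   providing the contigs; a CDS on a contig absent from the genome is an
#'   error naming the contig.
#' @param species_id species identifier applied to records that do not carry
#'   a `species` attribute in the GFF3.
#' @return list of [gene_model] objects, named by gene id.
#' @export
parse_gff3 <- function(gff3, genome, species_id = "unknown") {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!file.exists(gff3)) stop("GFF3 file not found: ", gff3)
  gr <- rtracklayer::import(gff3)
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) return(list())

  parent <- vapply(cds$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                   character(1))
  if (anyNA(parent)) stop("CDS feature without Parent attribute in ", gff3)

  # transcript -> gene mapping from mRNA/transcript features, if present
  tx <- gr[gr$type %in% c("mRNA", "transcript")]
  tx2gene <- if (length(tx)) {
    g <- vapply(tx$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                character(1))
    stats::setNames(ifelse(is.na(g), tx$ID, g), tx$ID)
  } else character(0)
  tx_species <- if (length(tx) && !is.null(tx$species))
    stats::setNames(as.character(tx$species), tx$ID) else character(0)

  models <- list()
  for (t_id in sort(unique(parent))) {
    idx <- which(parent == t_id)
    seg <- data.frame(start = GenomicRanges::start(cds)[idx] - 1L,
                      end = GenomicRanges::end(cds)[idx])
    contig <- unique(as.character(GenomicRanges::seqnames(cds)[idx]))
    strand <- unique(as.character(GenomicRanges::strand(cds)[idx]))
    if (length(contig) != 1L || length(strand) != 1L) {
      warning("transcript ", t_id, " spans contigs/strands; excluded")
      next
    }
    if (!contig %in% names(genome))
      stop("contig ", contig, " referenced by ", t_id, " missing from genome FASTA")
    g_id <- unname(tx2gene[t_id] %||% t_id)
    if (is.na(g_id)) g_id <- t_id
    sp <- unname(tx_species[t_id] %||% species_id)
    if (is.na(sp)) sp <- species_id
    m <- tryCatch(gene_model(g_id, sp, contig, strand, seg),
                  error = function(e) {
                    warning("gene ", g_id, " excluded: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (is.null(m)) next
    m$transcript_id <- t_id
    # one model per gene: keep the longest CDS, ties to smallest transcript id
    old <- models[[g_id]]
    if (is.null(old) || m$cds_length > old$cds_length ||
        (m$cds_length == old$cds_length && m$transcript_id < old$transcript_id))
      models[[g_id]] <- m
  }
  models[order(names(models))]
}

#' Assemble the spliced CDS of a gene model
#'
#' Concatenates the CDS segments in transcript orientation
#' (reverse-complementing each on the minus strand) and reports the coding
#' offset of every inter-segment junction — the number of coding nucleotides
#' strictly upstream of each intron.
#'
#' @param model a [gene_model].
#' @param genome [Biostrings::DNAStringSet] containing the model's contig.
#' @return list with `cds` (character string) and `offsets` (integer vector,
#'   one per intron; empty for single-segment genes).
#' @export
assemble_cds <- function(model, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!model$contig_id %in% names(genome))
    stop("contig ", model$contig_id, " missing from genome")
  contig <- genome[[model$contig_id]]
  seg <- model$cds_segments
  if (any(seg$start < 0L) || any(seg$end > length(contig)))
    stop("CDS segment outside contig ", model$contig_id,
         " (length ", length(contig), ") for gene ", model$gene_id)
  pieces <- vapply(seq_len(nrow(seg)), function(i) {
    s <- as.character(Biostrings::subseq(contig, seg$start[i] + 1L, seg$end[i]))
    if (model$strand == "-") revcomp(s) else s
  }, character(1))
  lens <- seg$end - seg$start
  list(cds = paste0(pieces, collapse = ""),
       offsets = as.integer(utils::head(cumsum(lens), -1L)))
}

#' Codon index and phase of an intron from its coding offset
#'
#' The coding offset (number of coding nucleotides strictly upstream of the
#' intron) is the canonical intron-position key. Phase is `offset mod 3`;
#' a phase-0 intron falls between codon `offset/3` and the next (it is
#' reported against the upstream codon), while a phase-1/2 intron interrupts
#' codon `floor(offset/3) + 1`.
#'
#' @param coding_offset integer >= 1.
#' @return list with `coding_offset`, `codon_index`, `phase`, `boundary`.
#' @export
intron_codon_phase <- function(coding_offset) {
  coding_offset <- as.integer(coding_offset)
  if (length(coding_offset) != 1L || is.na(coding_offset) || coding_offset < 1L)
    stop("coding_offset must be a single integer >= 1")
  phase <- coding_offset %% 3L
  codon <- if (phase == 0L) coding_offset %/% 3L else coding_offset %/% 3L + 1L
  list(coding_offset = coding_offset, codon_index = codon, phase = phase,
       boundary = phase == 0L)
}

#' Translate a CDS with the standard genetic code
#'
#' The terminal stop codon, if present, is stripped. An internal stop codon
#' is an error (such genes are excluded upstream rather than repaired);
#' codons containing characters other than ACGT translate to `X`.
#'
#' @param cds character string, length divisible by 3.
#' @return amino-acid string without the terminal stop.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " not divisible by 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  stops <- which(aa == "*")
  if (length(stops))
    stop("internal stop codon at codon ", stops[1L])
  paste0(aa, collapse = "")
}

#' Annotate proteins: assembled CDS, translation and intron coordinates
#'
#' Runs [assemble_cds()], [translate_cds()] and [intron_codon_phase()] over a
#' set of gene models. Genes with internal stop codons, or with intron
#' offsets at the extreme ends of the CDS, are excluded with a warning.
#'
#' @param models list of [gene_model] objects.
#' @param genome [Biostrings::DNAStringSet].
#' @return list of `annotated_protein` objects (fields `gene_id`,
#'   `species_id`, `aa`, `cds`, `introns` data.frame with columns
#'   `coding_offset`, `codon_index`, `phase`, `boundary`).
#' @export
annotate_proteins <- function(models, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- list()
  for (m in models) {
    asm <- assemble_cds(m, genome)
    aa <- tryCatch(translate_cds(asm$cds), error = function(e) {
      warning("gene ", m$gene_id, " excluded: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(aa)) next
    if (length(asm$offsets) &&
        (any(asm$offsets < 1L) || any(asm$offsets > nchar(asm$cds) - 1L))) {
      warning("gene ", m$gene_id, " excluded: intron at CDS boundary",
              call. = FALSE)
      next
    }
    introns <- if (length(asm$offsets)) {
      do.call(rbind, lapply(sort(asm$offsets), function(o)
        as.data.frame(intron_codon_phase(o))))
    } else {
      data.frame(coding_offset = integer(0), codon_index = integer(0),
                 phase = integer(0), boundary = logical(0))
    }
    out[[m$gene_id]] <- structure(
      list(gene_id = m$gene_id, species_id = m$species_id, aa = aa,
           cds = asm$cds, introns = introns),
      class = "annotated_protein")
  }
  out
}

#' @export
print.annotated_protein <- function(x, ...) {
  cat(sprintf("<annotated_protein> %s (%s), %d aa, introns: %s\n",
              x$gene_id, x$species_id, nchar(x$aa),
              if (nrow(x$introns)) paste(sprintf("%d:%d.%d",
                                                 x$introns$coding_offset,
                                                 x$introns$codon_index,
                                                 x$introns$phase),
                                         collapse = ",") else "none"))
  invisible(x)
}

intron_header_tag <- function(p) {
  if (nrow(p$introns) == 0L) return("introns=.")
  paste0("introns=", paste(sprintf("%d:%d.%d", p$introns$coding_offset,
                                   p$introns$codon_index, p$introns$phase),
                           collapse = ","))
}

#' Write annotated proteins to FASTA with intron positions in the header
#'
#' The header dialect is
#' `>{gene_id} species={species} introns={offset}:{codon}.{phase}[,...]`
#' (`introns=.` for intronless genes). With `what = "cds"` the nucleotide
#' coding sequences are written under identical headers.
#'
#' @param proteins list of `annotated_protein` objects.
#' @param path output FASTA path.
#' @param what `"aa"` (default) or `"cds"`.
#' @export
write_annotated_fasta <- function(proteins, path, what = c("aa", "cds")) {
  what <- match.arg(what)
  seqs <- vapply(proteins, function(p) p[[what]], character(1))
  hdr <- vapply(proteins, function(p)
    sprintf("%s species=%s %s", p$gene_id, p$species_id, intron_header_tag(p)),
    character(1))
  xs <- if (what == "aa") Biostrings::AAStringSet(seqs)
        else Biostrings::DNAStringSet(seqs)
  names(xs) <- hdr
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read an intron-annotated FASTA written by [write_annotated_fasta()]
#'
#' @param aa_path protein FASTA path.
#' @param cds_path optional matching nucleotide FASTA path; when given the
#'   CDS sequences are attached to the records.
#' @return list of `annotated_protein` objects.
#' @export
read_annotated_fasta <- function(aa_path, cds_path = NULL) {
  xs <- Biostrings::readAAStringSet(aa_path)
  cds <- if (!is.null(cds_path)) {
    y <- Biostrings::readDNAStringSet(cds_path)
    stats::setNames(as.character(y), sub("\\s.*$", "", names(y)))
  }
  out <- lapply(seq_along(xs), function(i) {
    hdr <- names(xs)[i]
    gene_id <- sub("\\s.*$", "", hdr)
    sp <- sub(".*species=(\\S+).*", "\\1", hdr)
    tag <- sub(".*introns=(\\S+).*", "\\1", hdr)
    introns <- if (tag == ".") {
      data.frame(coding_offset = integer(0), codon_index = integer(0),
                 phase = integer(0), boundary = logical(0))
    } else {
      offs <- as.integer(sub(":.*$", "", strsplit(tag, ",")[[1L]]))
      do.call(rbind, lapply(offs, function(o) as.data.frame(intron_codon_phase(o))))
    }
    structure(list(gene_id = gene_id, species_id = sp,
                   aa = as.character(xs[[i]]),
                   cds = if (!is.null(cds)) unname(cds[gene_id]) else NA_character_,
                   introns = introns),
              class = "annotated_protein")
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "gene_id"))
}
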