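#' Pipeline configuration
#'
#' Validates input paths and thresholds for [run_pipeline()]. Paths must
#' exist at validation time; thresholds must be positive.
#'
#' @param genome_fasta genome FASTA (all species' contigs).
#' @param gff3 GFF3 annotation covering the same contigs (records may
#'   carry a `species` attribute; otherwise all belong to `species_id`).
#' @param species_tree Newick species tree.
#' @param reference_gene gene id of the reference variant whose intron
#'   positions define the ortholog classes.
#' @param out_dir output directory (created if absent).
#' @param alignment optional externally aligned FASTA; when `NULL` the
#'   internal aligner is used.
#' @param hits optional BLAST-outfmt6-like hits table for the e-value
#'   filter.
#' @param quality optional genome-quality TSV
#'   (species/completeness/missing).
#' @param max_aa,max_evalue filter thresholds.
#' @param species_id fallback species id for records without a `species`
#'   attribute.
#' @param seed integer seed recorded in reports.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, gff3, species_tree, reference_gene,
                            out_dir, alignment = NULL, hits = NULL,
                            quality = NULL, max_aa = 200L,
                            max_evalue = 1e-10, species_id = "unknown",
                            seed = 1L) {
  for (p in c(genome_fasta, gff3, species_tree, alignment, hits, quality))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  if (max_aa <= 0 || max_evalue <= 0) stop("thresholds must be positive")
  structure(list(genome_fasta = genome_fasta, gff3 = gff3,
                 species_tree = species_tree,
                 reference_gene = reference_gene, out_dir = out_dir,
                 alignment = alignment, hits = hits, quality = quality,
                 max_aa = as.integer(max_aa), max_evalue = max_evalue,
                 species_id = species_id, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full intron-position profiling workflow
#'
#' Stages: parse genome + GFF3 into gene models; annotate introns in
#' coding coordinates and translate; filter the candidate family (e-value,
#' length); align (or ingest an external alignment); project introns onto
#' the alignment and build shared-position classes; assign putative
#' orthologs of the reference gene; derive a per-species presence pattern
#' per reference intron class; reconstruct origin and losses by Dollo
#' parsimony; score the insertion sites of the reference introns against
#' the protosplice consensus in intronless family members; optionally test
#' losses against assembly quality. Every stage writes its outputs under
#' `out_dir` and logs record counts.
#'
#' A species is scored `present` for a class when at least one of its
#' genes is a member, `absent` when it has annotated family genes but none
#' in the class, and `unknown` when it contributed no annotated family
#' gene at all.
#'
#' @param config a [pipeline_config].
#' @return list with `proteins`, `family`, `alignment`, `projected`,
#'   `classes`, `orthologs`, `presence` (list per reference class),
#'   `dollo` (list per reference class), `protosplice` (data.frame),
#'   `quality_test` (or `NULL`), `report_paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- Biostrings::readDNAStringSet(config$genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  tree <- read_species_tree(config$species_tree)

  models <- parse_gff3(config$gff3, genome, species_id = config$species_id)
  it_log("annotate", "%d gene model(s) parsed", length(models))
  proteins <- annotate_proteins(models, genome)
  it_log("annotate", "%d protein(s) annotated", length(proteins))
  write_annotated_fasta(proteins, file.path(config$out_dir, "proteins.faa"))
  write_annotated_fasta(proteins, file.path(config$out_dir, "cds.fna"),
                        what = "cds")

  prov <- if (!is.null(config$hits)) read_hits_table(config$hits)
  fam <- homolog_set(proteins, provenance = prov)
  if (!is.null(prov)) fam <- evalue_filter(fam, config$max_evalue)
  fam <- length_filter(fam, config$max_aa)
  it_log("filter", "%d record(s) after filtering", length(fam$records))
  if (!config$reference_gene %in% names(fam$records))
    stop("reference gene ", config$reference_gene,
         " absent from the filtered family")

  family <- if (!is.null(config$alignment)) read_alignment(config$alignment)
            else align_family(fam$records)
  validate_alignment(family, fam$records)
  it_log("align", "%d sequence(s) x %d column(s) [%s]",
         length(family$rows), nchar(family$rows[[1L]]), family$source)
  write_alignment(family, file.path(config$out_dir, "alignment.faa"))

  projected <- project_introns(family, fam$records)
  classes <- build_classes(projected)
  it_log("project", "%d projected intron(s) in %d class(es)",
         nrow(projected), nrow(classes))
  write_projection_tables(classes, projected,
                          file.path(config$out_dir, "classes.tsv"),
                          file.path(config$out_dir, "projected_introns.tsv"))

  orth <- assign_orthologs(classes, config$reference_gene)
  utils::write.table(orth$orthologs,
                     file.path(config$out_dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  it_log("classify", "reference class(es): %s; %d putative ortholog(s)",
         paste(orth$reference_classes, collapse = ","),
         nrow(orth$orthologs))

  species_of <- vapply(fam$records, `[[`, character(1), "species_id")
  annotated_species <- unique(species_of)
  presence <- list(); dollo <- list(); report_paths <- list()
  for (cls in orth$reference_classes) {
    member_species <- unique(species_of[orth$members[[cls]]])
    pat <- stats::setNames(rep("unknown", length(tree$tip.label)),
                           tree$tip.label)
    pat[tree$tip.label %in% annotated_species] <- "absent"
    pat[tree$tip.label %in% member_species] <- "present"
    presence[[cls]] <- pat
    write_presence(pat, file.path(config$out_dir,
                                  sprintf("presence_%s.tsv", cls)))
    d <- dollo_reconstruct(tree, pat)
    dollo[[cls]] <- d
    it_log("dollo", "class %s: origin %s, %d loss(es)%s", cls,
           d$origin_node, d$n_losses,
           if (d$ambiguous) sprintf(" (up to %d)", d$n_losses_max) else "")
    report_paths[[cls]] <- report_variant_history(
      d, file.path(config$out_dir, sprintf("history_%s", cls)))
  }

  protosplice <- protosplice_report(family, fam$records,
                                    config$reference_gene)
  if (!is.null(protosplice))
    utils::write.table(protosplice,
                       file.path(config$out_dir, "protosplice.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  qtest <- NULL
  if (!is.null(config$quality)) {
    qual <- read_quality_table(config$quality)
    main <- dollo[[orth$reference_classes[1L]]]
    loss_sp <- loss_species(main)
    qtest <- tryCatch(quality_loss_test(qual, loss_sp),
                      error = function(e) {
                        warning("quality test skipped: ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
    if (!is.null(qtest))
      utils::write.table(qtest,
                         file.path(config$out_dir, "quality_test.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(proteins = proteins, family = fam, alignment = family,
       projected = projected, classes = classes, orthologs = orth,
       presence = presence, dollo = dollo, protosplice = protosplice,
       quality_test = qtest, report_paths = report_paths)
}

# species under the loss edges of a reconstruction
loss_species <- function(dollo) {
  tree <- dollo$tree
  tips <- descendant_tips(tree)
  unique(unlist(lapply(dollo$loss_edges$child_num[
    dollo$loss_edges$kind == "loss"], function(v)
      tree$tip.label[tips[[v]]])))
}

# protosplice context of each reference intron in every intronless member
protosplice_report <- function(family, records, reference_gene) {
  ref <- records[[reference_gene]]
  if (is.null(ref) || !nrow(ref$introns)) return(NULL)
  intronless <- Filter(function(p) nrow(p$introns) == 0L &&
                         !is.na(p$cds), records)
  if (!length(intronless)) return(NULL)
  out <- list()
  for (k in seq_len(nrow(ref$introns))) {
    off <- ref$introns$coding_offset[k]
    for (p in intronless) {
      m <- homologous_offset(family, reference_gene, off, p$gene_id)
      if (m$status != "ok") {
        out[[length(out) + 1L]] <- data.frame(
          reference_intron = sprintf("%d.%d", ref$introns$codon_index[k],
                                     ref$introns$phase[k]),
          intronless_gene = p$gene_id, four_mer = NA_character_,
          n_matches = NA_integer_, signal = NA)
        next
      }
      sc <- tryCatch(flanking_site_score(p$cds, m$offset),
                     error = function(e) NULL)
      if (is.null(sc)) next
      out[[length(out) + 1L]] <- data.frame(
        reference_intron = sprintf("%d.%d", ref$introns$codon_index[k],
                                   ref$introns$phase[k]),
        intronless_gene = p$gene_id, four_mer = sc$four_mer,
        n_matches = sc$n_matches, signal = sc$signal)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Report a variant's reconstructed history
#'
#' Writes three renderings of a Dollo result: a TSV of events (origin plus
#' one row per loss edge), an annotated Newick in which the child node of
#' every loss edge carries a `#loss` (or `#loss?` for unknown-only clades)
#' label suffix, and an ASCII tree in which loss edges are marked with
#' hash marks, present species with `+`, absent with `-` and unknown with
#' `?`.
#'
#' @param dollo a `dollo_result`.
#' @param path_prefix output prefix; writes `<prefix>.tsv`,
#'   `<prefix>.nwk`, `<prefix>.txt`.
#' @return named character vector of the three paths.
#' @export
report_variant_history <- function(dollo, path_prefix) {
  tree <- dollo$tree
  events <- rbind(
    data.frame(event = "origin", node = dollo$origin_node,
               parent = NA_character_),
    if (nrow(dollo$loss_edges))
      data.frame(event = ifelse(dollo$loss_edges$kind == "loss",
                                "loss", "possible_loss"),
                 node = dollo$loss_edges$child,
                 parent = dollo$loss_edges$parent))
  events <- rbind(events,
                  data.frame(event = "n_losses",
                             node = as.character(dollo$n_losses),
                             parent = NA_character_),
                  data.frame(event = "n_losses_max",
                             node = as.character(dollo$n_losses_max),
                             parent = NA_character_))
  tsv <- paste0(path_prefix, ".tsv")
  utils::write.table(events, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tagged <- tree
  for (i in seq_len(nrow(dollo$loss_edges))) {
    lab <- dollo$loss_edges$child[i]
    tag <- if (dollo$loss_edges$kind[i] == "loss") "#loss" else "#loss?"
    ti <- match(lab, tagged$tip.label)
    if (!is.na(ti)) tagged$tip.label[ti] <- paste0(lab, tag)
    else {
      ni <- match(lab, tagged$node.label)
      tagged$node.label[ni] <- paste0(lab, tag)
    }
  }
  nwk <- paste0(path_prefix, ".nwk")
  ape::write.tree(tagged, nwk)

  txt <- paste0(path_prefix, ".txt")
  writeLines(ascii_history(dollo), txt)
  stats::setNames(c(tsv, nwk, txt), c("tsv", "nwk", "txt"))
}

#' ASCII rendering of a reconstructed variant history
#'
#' @param dollo a `dollo_result`.
#' @return character vector of lines.
#' @export
ascii_history <- function(dollo) {
  tree <- dollo$tree
  n <- length(tree$tip.label)
  ch <- children_list(tree)
  loss_children <- dollo$loss_edges$child_num
  loss_mark <- stats::setNames(
    ifelse(dollo$loss_edges$kind == "loss", "##", "#?"),
    dollo$loss_edges$child_num)
  state_mark <- c(present = "+", absent = "-", unknown = "?")

  lines <- character(0)
  rec <- function(v, prefix, edge_prefix) {
    mark <- if (v %in% loss_children) loss_mark[[as.character(v)]] else "--"
    origin <- if (v == dollo$origin_node_num) "*" else ""
    if (v <= n) {
      sp <- tree$tip.label[v]
      lines <<- c(lines, sprintf("%s%s %s %s%s", edge_prefix, mark, sp,
                                 state_mark[dollo$pattern[sp]], origin))
    } else {
      lines <<- c(lines, sprintf("%s%s %s%s", edge_prefix, mark,
                                 node_label(tree, v), origin))
      kids <- ch[[v]]
      for (i in seq_along(kids)) {
        last <- i == length(kids)
        rec(kids[i],
            paste0(prefix, if (last) "   " else "|  "),
            paste0(prefix, if (last) "`-" else "|-"))
      }
    }
  }
  rec(n + 1L, "", "")
  c(sprintf("origin: %s   losses: %d (upper bound %d)",
            dollo$origin_node, dollo$n_losses, dollo$n_losses_max),
    "legend: ## loss edge, #? possible loss (unknown-only clade), * origin",
    "", lines)
}
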