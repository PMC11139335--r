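#' One-tailed Welch t-test (unequal variances)
#'
#' Used to ask whether species with inferred gene losses have poorer genome
#' assemblies than species without: if losses were annotation artefacts,
#' the loss group should show lower completeness / higher missing-gene
#' estimates. Wraps [stats::t.test()] with `var.equal = FALSE`
#' (Welch-Satterthwaite degrees of freedom).
#'
#' @param values_loss_group,values_other_group numeric vectors, each of
#'   length >= 2, with nonzero variance in at least one group.
#' @param alternative `"less"` (loss group mean smaller) or `"greater"`.
#' @return list with `t`, `df`, `p`.
#' @export
welch_one_tailed_t <- function(values_loss_group, values_other_group,
                               alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(values_loss_group); y <- as.numeric(values_other_group)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both groups have zero variance; the test statistic is undefined")
  res <- stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Read a genome-quality table (BUSCO-style summary columns)
#'
#' @param path TSV with columns `species`, `completeness`, `missing`
#'   (percentages).
#' @return data.frame.
#' @export
read_quality_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("species", "completeness", "missing")
  if (!all(need %in% names(df)))
    stop("quality table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Test whether inferred losses track assembly quality
#'
#' Runs the one-tailed Welch t-test in both directions the question calls
#' for: completeness lower in the loss group (`alternative = "less"`) and
#' missing-gene estimate higher (`alternative = "greater"`). Large p-values
#' support the losses being real rather than annotation artefacts.
#'
#' @param quality data.frame from [read_quality_table()].
#' @param loss_species character vector of species with inferred losses.
#' @return data.frame with one row per metric: `metric`, `t`, `df`, `p`.
#' @export
quality_loss_test <- function(quality, loss_species) {
  in_loss <- quality$species %in% loss_species
  if (sum(in_loss) < 2L || sum(!in_loss) < 2L)
    stop("need at least 2 species in both the loss and the non-loss group")
  comp <- welch_one_tailed_t(quality$completeness[in_loss],
                             quality$completeness[!in_loss], "less")
  miss <- welch_one_tailed_t(quality$missing[in_loss],
                             quality$missing[!in_loss], "greater")
  data.frame(metric = c("completeness", "missing"),
             t = c(comp$t, miss$t), df = c(comp$df, miss$df),
             p = c(comp$p, miss$p))
}
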