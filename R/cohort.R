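## Cohort-level diagnostic-yield tabulation.
##
## A cohort table has one row per tested patient:
##   case_id, onset_days, syndrome ("unclassified" when no electroclinical
##   syndrome fits), gene, variant_class ("sequence", "CNV" or "none"),
##   classification (ACMG label of the finding, or "none").

onset_group_levels <- c("neonatal", "early infantile", "late infantile")

#' Assign the seizure-onset age group
#'
#' Cohort inclusion requires onset within the first year of life; cases
#' are stratified as neonatal (onset at up to 30 days), early infantile
#' (over 1 month and up to 6 months, i.e. 31-182 days) or late infantile
#' (183 days up to one year). Month boundaries use 1 month = 30 days and
#' 6 months = 182 days, right-inclusive.
#'
#' @param onset_days Integer vector of onset ages in days (0 to 365).
#' @return Character vector of group labels.
#' @export
assign_onset_group <- function(onset_days) {
  if (any(is.na(onset_days) | onset_days < 0)) {
    stop_config("onset ages must be non-negative and known")
  }
  if (any(onset_days >= 366)) {
    stop_config("onset at 12 months or later violates cohort inclusion")
  }
  ifelse(onset_days <= 30, "neonatal",
         ifelse(onset_days <= 182, "early infantile", "late infantile"))
}

#' Diagnostic yield, overall or by stratum
#'
#' The diagnostic yield is the fraction of tested patients in whom a
#' Pathogenic or Likely Pathogenic finding was established. Percentages
#' are reported at one decimal, rounded half away from zero; an empty
#' stratum reports `NA` rather than 0.
#'
#' @param cases Cohort data frame (see file header). A logical `diagnosed`
#'   column is used if present, otherwise derived from `classification`.
#' @param by Optional name of a column to stratify on (e.g.
#'   `"onset_group"`, `"syndrome_status"`); `NULL` gives the overall row.
#' @return Data frame with `stratum`, `diagnosed`, `total`, `percent`.
#' @export
compute_diagnostic_yield <- function(cases, by = NULL) {
  diagnosed <- if ("diagnosed" %in% names(cases)) {
    as.logical(cases$diagnosed)
  } else {
    cases$classification %in% c("Pathogenic", "Likely Pathogenic")
  }
  strata <- if (is.null(by)) {
    factor(rep("all", nrow(cases)))
  } else {
    if (!by %in% names(cases)) stop_config("no column '", by, "' to stratify on")
    if (is.factor(cases[[by]])) cases[[by]] else factor(cases[[by]])
  }
  d <- as.integer(tapply(diagnosed, strata, sum, default = 0L))
  n <- as.integer(table(strata))
  data.frame(
    stratum = levels(strata),
    diagnosed = d,
    total = n,
    percent = ifelse(n == 0L, NA_real_, round_half_away(100 * d / n, 1)),
    stringsAsFactors = FALSE
  )
}

#' Per-gene frequency of diagnostic findings
#'
#' Counts diagnosed cases per gene, split by variant class: sequence
#' variants are tallied under their gene symbol, while CNV events keep
#' their (possibly multi-gene) label and are counted per event. A patient
#' carrying both a sequence variant and a CNV would count once per
#' finding here but once for yield.
#'
#' @param cases Cohort data frame (see [compute_diagnostic_yield()]).
#' @return Data frame `gene`, `variant_class`, `n`, sorted by descending
#'   `n`; empty input gives an empty table.
#' @export
tabulate_gene_frequencies <- function(cases) {
  diagnosed <- if ("diagnosed" %in% names(cases)) {
    as.logical(cases$diagnosed)
  } else {
    cases$classification %in% c("Pathogenic", "Likely Pathogenic")
  }
  hit <- cases[diagnosed & cases$variant_class %in% c("sequence", "CNV"), , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(data.frame(gene = character(), variant_class = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  agg <- aggregate(
    list(n = hit$case_id),
    by = list(gene = hit$gene, variant_class = hit$variant_class),
    FUN = length
  )
  agg <- agg[order(-agg$n, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Bar chart of diagnostic yield by stratum
#'
#' Renders a per-stratum diagnosed/undiagnosed stacked bar chart of a
#' yield table. Requires ggplot2.
#'
#' @param yield Data frame from [compute_diagnostic_yield()].
#' @return A ggplot object.
#' @export
plot_yield <- function(yield) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_yield() requires the ggplot2 package")
  }
  long <- rbind(
    data.frame(stratum = yield$stratum, outcome = "diagnosed",
               n = yield$diagnosed),
    data.frame(stratum = yield$stratum, outcome = "not diagnosed",
               n = yield$total - yield$diagnosed)
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$stratum, y = .data$n, fill = .data$outcome
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "patients", fill = NULL) +
    ggplot2::theme_minimal()
}
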