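#' Per-sample IQR fences for CNV calling
#'
#' For each sample, the 25th and 75th percentiles of its dual Z-scores over
#' all exons define fences at `q25 - 2.5 * IQR` (deletion) and
#' `q75 + 2.5 * IQR` (duplication). Quartiles use linear interpolation
#' between order statistics (`quantile()` type 7).
#'
#' @param z Dual-stage Z-score matrix (exons x samples) from
#'   [normalize_double_zscore()].
#' @param multiplier Fence multiplier (default 2.5).
#' @return Data frame with one row per sample: `sample`, `q25`, `q75`,
#'   `iqr`, `lower`, `upper`.
#' @export
compute_sample_fences <- function(z, multiplier = 2.5) {
  if (!is.matrix(z)) stop_config("z must be a matrix (exons x samples)")
  if (nrow(z) < 4L) stop_config("quartiles are unstable with fewer than 4 exons per sample")
  q <- apply(z, 2L, quantile, probs = c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L, ] - q[1L, ]
  data.frame(
    sample = colnames(z),
    q25 = q[1L, ],
    q75 = q[2L, ],
    iqr = iqr,
    lower = q[1L, ] - multiplier * iqr,
    upper = q[2L, ] + multiplier * iqr,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Flag outlier samples by their own-fence exceedance rate
#'
#' A sample whose Z-score distribution is contaminated (degraded library,
#' failed capture) produces spurious exon calls batch-wide, so such samples
#' are dropped before calling. A sample is flagged when the fraction of its
#' exons falling outside its own fences exceeds `max_flag_fraction`.
#' The caller ([call_cnvs()]) re-runs the across-sample normalization and
#' fences once on the retained set.
#'
#' @param z Dual-stage Z-score matrix.
#' @param fences Output of [compute_sample_fences()] for `z`.
#' @param max_flag_fraction Largest tolerated outside-fence exon fraction
#'   (default 0.10); `1.0` disables flagging.
#' @return List with character vectors `retained` and `flagged`, plus
#'   `fraction_outside` (named, per sample).
#' @export
flag_outlier_samples <- function(z, fences, max_flag_fraction = 0.10) {
  check_fence_match(z, fences)
  frac <- vapply(seq_len(ncol(z)), function(j) {
    mean(z[, j] < fences$lower[j] | z[, j] > fences$upper[j])
  }, numeric(1))
  names(frac) <- colnames(z)
  flagged <- names(frac)[frac > max_flag_fraction]
  if (length(flagged) == ncol(z)) {
    stop_config("all samples flagged as outliers; review max_flag_fraction")
  }
  list(
    retained = setdiff(colnames(z), flagged),
    flagged = flagged,
    fraction_outside = frac
  )
}

check_fence_match <- function(z, fences) {
  if (!identical(as.character(fences$sample), colnames(z))) {
    stop_config("fence table does not match the samples of the Z-score matrix")
  }
}

#' Call exon-level deletions and duplications
#'
#' An exon is called a deletion in a sample when its Z-score is strictly
#' below that sample's lower fence, and a duplication when strictly above
#' the upper fence; values equal to a fence are never called.
#'
#' @param z Dual-stage Z-score matrix.
#' @param fences Output of [compute_sample_fences()] for `z` (same samples,
#'   same order).
#' @return Data frame of calls: `sample`, `exon_key`, `call`
#'   (`"deletion"`/`"duplication"`), `z`, `lower`, `upper`.
#' @export
call_exon_cnvs <- function(z, fences) {
  check_fence_match(z, fences)
  out <- vector("list", ncol(z))
  for (j in seq_len(ncol(z))) {
    del <- z[, j] < fences$lower[j]
    dup <- z[, j] > fences$upper[j]
    idx <- which(del | dup)
    if (length(idx) == 0L) next
    out[[j]] <- data.frame(
      sample = colnames(z)[j],
      exon_key = rownames(z)[idx],
      call = ifelse(del[idx], "deletion", "duplication"),
      z = z[idx, j],
      lower = fences$lower[j],
      upper = fences$upper[j],
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sample = character(), exon_key = character(),
                      call = character(), z = numeric(),
                      lower = numeric(), upper = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Aggregate exon calls to gene-level CNV calls
#'
#' A gene is called deleted (or duplicated) in a sample when strictly more
#' than half of its exons in the panel design carry same-direction exon
#' calls. The denominator is the design's exon count for the gene, so
#' exons without data count against the call; exactly half does not
#' qualify. Opposite-direction calls within one gene are tallied
#' separately and can never jointly reach a call.
#'
#' @param exon_calls Data frame from [call_exon_cnvs()].
#' @param design The [panel_design()] defining per-gene exon counts.
#' @return Data frame: `sample`, `gene`, `call`, `n_exons_called`,
#'   `n_exons_total`.
#' @export
aggregate_gene_calls <- function(exon_calls, design) {
  empty <- data.frame(sample = character(), gene = character(),
                      call = character(), n_exons_called = integer(),
                      n_exons_total = integer(), stringsAsFactors = FALSE)
  if (nrow(exon_calls) == 0L) return(empty)
  unknown <- setdiff(exon_calls$exon_key, design$exon_key)
  if (length(unknown) > 0L) {
    stop_config("exon calls reference exons absent from the design: ",
                paste(head(unknown, 3L), collapse = ", "))
  }
  per_gene <- exons_per_gene(design)
  gene_of <- setNames(design$gene, design$exon_key)
  calls <- exon_calls
  calls$gene <- gene_of[calls$exon_key]
  agg <- aggregate(
    list(n_exons_called = calls$exon_key),
    by = list(sample = calls$sample, gene = calls$gene, call = calls$call),
    FUN = length
  )
  agg$n_exons_total <- as.integer(per_gene[agg$gene])
  agg <- agg[agg$n_exons_called > agg$n_exons_total / 2, , drop = FALSE]
  agg <- agg[order(agg$sample, agg$gene, agg$call),
             c("sample", "gene", "call", "n_exons_called", "n_exons_total")]
  rownames(agg) <- NULL
  agg
}

#' Read-depth CNV calling pipeline for one panel batch
#'
#' Runs the full chain on an RPKM matrix: dual Z-score normalization,
#' per-sample IQR fences, outlier-sample flagging (with one re-run of the
#' across-sample stage and fences on the retained samples), exon-level
#' calling, and gene-level aggregation.
#'
#' @param rpkm RPKM matrix (exons x samples) for samples sequenced on the
#'   same panel version.
#' @param design The [panel_design()].
#' @param max_flag_fraction Outlier-sample threshold, see
#'   [flag_outlier_samples()].
#' @param multiplier Fence multiplier, see [compute_sample_fences()].
#' @param recompute_after_removal Re-normalize and recompute fences after
#'   dropping flagged samples (default `TRUE`); if `FALSE`, flagged
#'   samples are dropped but the original scores and fences are kept.
#' @return List with `gene_calls`, `exon_calls`, `z`, `fences`,
#'   `flagged_samples`.
#' @export
call_cnvs <- function(rpkm, design, max_flag_fraction = 0.10, multiplier = 2.5,
                      recompute_after_removal = TRUE) {
  z <- normalize_double_zscore(rpkm)
  fences <- compute_sample_fences(z, multiplier)
  flags <- flag_outlier_samples(z, fences, max_flag_fraction)
  if (length(flags$flagged) > 0L) {
    z <- if (recompute_after_removal) {
      normalize_double_zscore(rpkm[, flags$retained, drop = FALSE])
    } else {
      z[, flags$retained, drop = FALSE]
    }
    fences <- compute_sample_fences(z, multiplier)
  }
  exon_calls <- call_exon_cnvs(z, fences)
  list(
    gene_calls = aggregate_gene_calls(exon_calls, design),
    exon_calls = exon_calls,
    z = z,
    fences = fences,
    flagged_samples = flags$flagged
  )
}
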