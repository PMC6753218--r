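## Amplicon-based validation of low-allele-fraction variants.
##
## Reads are pooled PCR amplicons tagged on the forward primer with a
## 6-nt sample barcode followed by the fixed adaptor "AGAT"; the template
## begins at base 11 and carries the site under validation.

amplicon_adaptor <- "AGAT"
barcode_length <- 6L

validate_barcodes <- function(barcodes) {
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes)))) {
    stop_config("barcodes must be a named vector (sample -> barcode)")
  }
  barcodes <- setNames(toupper(as.character(barcodes)), names(barcodes))
  if (any(nchar(barcodes) != barcode_length)) {
    stop_config("barcodes must be exactly ", barcode_length, " nt")
  }
  if (any(grepl("[^ACGT]", barcodes))) {
    stop_config("barcodes may contain only A, C, G, T")
  }
  if (anyDuplicated(barcodes)) stop_config("duplicate barcodes across samples")
  barcodes
}

#' Demultiplex barcoded amplicon reads
#'
#' Assigns each read to a sample when its first 6 bases exactly match that
#' sample's barcode and bases 7-10 equal the adaptor `AGAT`; all other
#' reads fall into the unassigned bin. Matching tolerates no mismatches:
#' with 6-nt barcodes any tolerance risks collisions. The result is a
#' partition: every read is assigned to exactly one sample or unassigned.
#'
#' @param reads Character vector of read sequences (optionally named with
#'   read IDs), e.g. from [read_amplicon_fastq()].
#' @param barcodes Named character vector, sample ID -> 6-nt barcode.
#' @return List with `assigned` (list of per-sample character vectors, one
#'   element per sample in `barcodes`) and `unassigned`.
#' @export
demultiplex_reads <- function(reads, barcodes) {
  barcodes <- validate_barcodes(barcodes)
  prefix <- substr(reads, 1L, barcode_length)
  adaptor_ok <- substr(reads, barcode_length + 1L, barcode_length + 4L) == amplicon_adaptor
  sample_of <- names(barcodes)[match(prefix, barcodes)]
  sample_of[!adaptor_ok] <- NA_character_
  assigned <- lapply(setNames(names(barcodes), names(barcodes)), function(s) {
    reads[!is.na(sample_of) & sample_of == s]
  })
  list(assigned = assigned, unassigned = reads[is.na(sample_of)])
}

#' Count reference and variant alleles at one site
#'
#' Classifies each read of one sample by the base it carries at the
#' validated site: the reference allele, the variant allele, or anything
#' else (sequencing-error bases, N calls).
#'
#' @param reads Character vector of full reads (barcode + adaptor +
#'   template) for one sample.
#' @param site List with `offset` (1-based position of the site within the
#'   template, i.e. after the 10-base tag), `ref` and `alt` (single bases).
#' @param sample Sample ID recorded in the output (default `""`).
#' @return One-row data frame: `sample`, `ref_count`, `var_count`,
#'   `other_count`.
#' @export
count_alleles_at_site <- function(reads, site, sample = "") {
  pos <- barcode_length + 4L + site$offset
  if (length(reads) > 0L && any(nchar(reads) < pos)) {
    stop_config("site offset lies beyond the end of the reads")
  }
  base <- substr(reads, pos, pos)
  data.frame(
    sample = sample,
    ref_count = sum(base == site$ref),
    var_count = sum(base == site$alt),
    other_count = sum(base != site$ref & base != site$alt),
    stringsAsFactors = FALSE
  )
}

#' Variant allele fraction from allele counts
#'
#' `vaf_percent = 100 * var / (ref + var)`, rounded half away from zero.
#' By default the precision adapts to the magnitude as in validation
#' reports: one decimal, or two decimals below 2% where a single decimal
#' would obscure low-level signal.
#'
#' @param counts Data frame with `ref_count` and `var_count` (one or more
#'   rows, e.g. from [count_alleles_at_site()]).
#' @param digits Fixed number of decimals, or `NULL` (default) for the
#'   adaptive rule.
#' @return `counts` with `total_informative` and `vaf_percent` appended.
#' @export
compute_vaf <- function(counts, digits = NULL) {
  total <- counts$ref_count + counts$var_count
  if (any(total == 0)) {
    stop_config("zero informative reads for sample(s): ",
                paste(counts$sample[total == 0], collapse = ", "))
  }
  pct <- 100 * counts$var_count / total
  d <- if (is.null(digits)) ifelse(pct < 2, 2L, 1L) else rep(digits, length(pct))
  counts$total_informative <- total
  counts$vaf_percent <- round_half_away(pct, d)
  counts
}

#' Assess parental mosaic-carrier status
#'
#' A parent is reported as a mosaic carrier of the proband's variant when
#' its variant read count is significantly above the amplicon background
#' error rate (one-sided binomial test, alpha 0.01 with Bonferroni
#' correction over the tested parents) and its VAF is at least five times
#' the background rate. When no background estimate is supplied, the
#' pooled rate of the apparently negative parents (those within 1.5x the
#' lowest parental rate) is used.
#'
#' @param parents Data frame with `sample`, `ref_count`, `var_count`.
#' @param background Background variant-read rate as a fraction (e.g.
#'   `0.01` for 1%), or `NULL` to estimate from the batch.
#' @param alpha Family-wise significance level before Bonferroni
#'   correction (default 0.01).
#' @param min_fold Minimum VAF / background ratio (default 5).
#' @return `parents` with `vaf_percent`, `p_value`, `status`
#'   (`"mosaic carrier"` / `"negative"`) and the `background` used
#'   (as an attribute).
#' @export
assess_parental_mosaicism <- function(parents, background = NULL,
                                      alpha = 0.01, min_fold = 5) {
  if (nrow(parents) == 0L) stop_config("no parental counts supplied")
  total <- parents$ref_count + parents$var_count
  if (any(total == 0)) stop_config("zero informative reads for a parent")
  rate <- parents$var_count / total
  if (is.null(background)) {
    negative_pool <- rate <= 1.5 * min(rate)
    background <- sum(parents$var_count[negative_pool]) / sum(total[negative_pool])
  }
  if (background <= 0) background <- 1 / sum(total)   # floor: one read in the pool
  p <- vapply(seq_len(nrow(parents)), function(i) {
    binom.test(parents$var_count[i], total[i], p = background,
               alternative = "greater")$p.value
  }, numeric(1))
  thresh <- alpha / nrow(parents)
  carrier <- p < thresh & rate >= min_fold * background
  parents$vaf_percent <- round_half_away(100 * rate, 2)
  parents$p_value <- p
  parents$status <- ifelse(carrier, "mosaic carrier", "negative")
  attr(parents, "background") <- background
  parents
}

#' Compare computed VAF percentages against printed values
#'
#' Recomputes the VAF of each allele-count record and compares it, at the
#' decimal precision of the printed value, against the `printed_percent`
#' column. Rows whose printed percentage cannot be reproduced from their
#' own counts are flagged; they are reported, never corrected.
#'
#' @param counts Data frame with `ref_count`, `var_count` and a character
#'   `printed_percent` column (e.g. the packaged validation table, see
#'   [read_amplicon_counts_tsv()]).
#' @return `counts` with `computed_percent` and logical `discrepant`
#'   columns.
#' @export
vaf_discrepancy_report <- function(counts) {
  printed <- sub("%$", "", trimws(as.character(counts$printed_percent)))
  dec <- ifelse(grepl("\\.", printed), nchar(sub("^[^.]*\\.", "", printed)), 0L)
  pct <- 100 * counts$var_count / (counts$ref_count + counts$var_count)
  computed <- round_half_away(pct, dec)
  counts$computed_percent <- computed
  counts$discrepant <- abs(computed - as.numeric(printed)) > 1e-9
  counts
}
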