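#' Construct a depth matrix
#'
#' Per-exon read counts for a batch of samples sequenced on the same panel,
#' together with each sample's total mapped read count (the RPKM
#' denominator). Rows are exon keys, columns are sample IDs.
#'
#' @param counts Non-negative integer matrix, exons x samples, with
#'   `rownames` set to exon keys and `colnames` to sample IDs.
#' @param total_reads Named positive numeric vector of total mapped reads
#'   per sample. Defaults to the on-target column sums.
#' @return A `depth_matrix`: the count matrix with a `total_reads` attribute.
#' @export
depth_matrix <- function(counts, total_reads = NULL) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_config("counts must be a matrix with exon-key rownames and sample colnames")
  }
  if (any(counts < 0) || anyNA(counts)) stop_config("counts must be non-negative")
  if (is.null(total_reads)) total_reads <- colSums(counts)
  total_reads <- total_reads[colnames(counts)]
  if (anyNA(total_reads)) stop_config("total_reads missing for some samples")
  structure(counts, total_reads = total_reads, class = c("depth_matrix", "matrix", "array"))
}

#' Count MQ-filtered reads per target exon
#'
#' Builds the per-exon read count matrix from alignment records. A read
#' contributes one count to every target exon its aligned span overlaps by
#' at least 1 bp; reads whose mapping quality is not strictly above
#' `mq_min` are excluded. Each sample's total mapped read count is the
#' number of its MQ-passing alignments (wherever they map), unless
#' `on_target_totals` restricts the denominator to reads overlapping at
#' least one target.
#'
#' @param alignments Data frame of per-read records with columns `sample`,
#'   `chrom`, `start`, `end` (0-based half-open aligned span) and `mq`.
#' @param design A [panel_design()].
#' @param mq_min Mapping-quality threshold; reads must be strictly above it
#'   (default 15, so MQ 15 itself is excluded).
#' @param on_target_totals If `TRUE`, per-sample totals count only reads
#'   overlapping a target exon.
#' @return A [depth_matrix()] with one row per design exon (in design
#'   order) and one column per sample present in `alignments`.
#' @export
count_reads_per_exon <- function(alignments, design, mq_min = 15L,
                                 on_target_totals = FALSE) {
  need <- c("sample", "chrom", "start", "end", "mq")
  if (!all(need %in% names(alignments))) {
    stop_config("alignments must have columns: ", paste(need, collapse = ", "))
  }
  keep <- alignments$mq > mq_min
  aln <- alignments[keep, , drop = FALSE]

  unknown <- !(aln$chrom %in% unique(design$chrom))
  if (any(unknown)) {
    warning(sum(unknown), " alignment(s) on chromosomes absent from the panel design; skipped")
  }

  samples <- sort(unique(as.character(alignments$sample)))
  counts <- matrix(0L, nrow = nrow(design), ncol = length(samples),
                   dimnames = list(design$exon_key, samples))
  totals <- setNames(numeric(length(samples)), samples)

  target_gr <- GenomicRanges::GRanges(
    seqnames = design$chrom,
    ranges = IRanges::IRanges(start = design$start + 1L, end = design$end)
  )
  usable <- aln[!unknown, , drop = FALSE]
  if (nrow(usable) > 0L) {
    read_gr <- GenomicRanges::GRanges(
      seqnames = usable$chrom,
      ranges = IRanges::IRanges(start = usable$start + 1L, end = usable$end)
    )
    hits <- GenomicRanges::findOverlaps(read_gr, target_gr, minoverlap = 1L)
    if (length(hits) > 0L) {
      hit_sample <- as.character(usable$sample)[S4Vectors::queryHits(hits)]
      tab <- table(
        factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(design))),
        factor(hit_sample, levels = samples)
      )
      counts[] <- as.integer(tab)
    }
    if (on_target_totals) {
      on <- unique(S4Vectors::queryHits(hits))
      tt <- table(factor(as.character(usable$sample)[on], levels = samples))
      totals[] <- as.numeric(tt)
    }
  }
  if (!on_target_totals) {
    tt <- table(factor(as.character(aln$sample), levels = samples))
    totals[] <- as.numeric(tt)
  }
  depth_matrix(counts, totals)
}

#' Convert read counts to RPKM
#'
#' Reads per kilobase of target per million mapped reads:
#' `RPKM = count / ((exon length / 1e3) * (total mapped reads / 1e6))`.
#' A zero count gives RPKM 0; doubling all counts and totals leaves the
#' matrix unchanged.
#'
#' @param depth A [depth_matrix()].
#' @param design The [panel_design()] supplying exon lengths; rows of
#'   `depth` must be design exon keys.
#' @return Numeric RPKM matrix with the same dimnames as `depth`.
#' @export
compute_rpkm <- function(depth, design) {
  totals <- attr(depth, "total_reads")
  if (is.null(totals)) totals <- colSums(depth)
  if (any(totals <= 0)) {
    stop_config("zero total mapped reads for sample(s): ",
                paste(colnames(depth)[totals <= 0], collapse = ", "))
  }
  len <- exon_lengths(design)
  missing <- setdiff(rownames(depth), names(len))
  if (length(missing) > 0L) {
    stop_config("depth matrix rows absent from panel design: ",
                paste(head(missing, 3L), collapse = ", "))
  }
  len <- len[rownames(depth)]
  rpkm <- unclass(depth) / outer(len / 1e3, totals / 1e6)
  attr(rpkm, "total_reads") <- NULL
  rpkm
}

standardize <- function(x) {
  s <- pop_sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Dual Z-score normalization of an RPKM matrix
#'
#' Coverage in targeted sequencing fluctuates both between samples and
#' between targets, so scores are standardized twice: first within each
#' sample across its exons (removing per-sample depth and capture-batch
#' effects), then for each exon across the samples of the batch (removing
#' per-exon capture-efficiency effects). Both stages use the population
#' (divide-by-n) SD; a zero-SD sample or exon yields scores of 0 rather
#' than NaN.
#'
#' @param rpkm Numeric matrix, exons x samples (e.g. from [compute_rpkm()]).
#' @param stage `"dual"` (default) for both passes or `"within-sample"` to
#'   stop after the first.
#' @return Matrix of normalized scores with a `stage` attribute. After the
#'   within-sample stage every column has mean 0; after the dual stage
#'   every row additionally has mean 0 (and SD 1 unless degenerate).
#' @export
normalize_double_zscore <- function(rpkm, stage = c("dual", "within-sample")) {
  stage <- match.arg(stage)
  if (!is.matrix(rpkm) || nrow(rpkm) < 2L) {
    stop_config("need a matrix with at least 2 exons")
  }
  if (ncol(rpkm) < 2L) {
    stop_config("across-sample standardization needs at least 2 samples in the batch")
  }
  z <- apply(rpkm, 2L, standardize)
  if (stage == "dual") {
    z <- t(apply(z, 1L, standardize))
  }
  dimnames(z) <- dimnames(rpkm)
  attr(z, "stage") <- stage
  z
}
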