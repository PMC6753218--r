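#' Construct a panel design
#'
#' A panel design is the ordered table of capture targets for one version of
#' the gene panel: one row per targeted exon with 0-based, half-open
#' coordinates. Exon keys (`gene|exon_index`) identify rows of depth, RPKM
#' and Z-score matrices throughout the pipeline.
#'
#' @param gene Character vector of gene symbols, one per target exon.
#' @param exon_index Integer ordinal of the exon within its gene (1-based).
#' @param chrom Chromosome of each target.
#' @param start,end 0-based half-open interval of each target (`end > start`).
#' @param version Optional panel version label (e.g. `"kit-1"`).
#'
#' @return A `panel_design` data frame with columns `gene`, `exon_index`,
#'   `chrom`, `start`, `end`, `exon_key`, sorted by coordinate, with the
#'   version label stored as an attribute.
#' @export
panel_design <- function(gene, exon_index, chrom, start, end, version = "panel") {
  df <- data.frame(
    gene = as.character(gene),
    exon_index = as.integer(exon_index),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  df$exon_key <- paste(df$gene, df$exon_index, sep = "|")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  validate_panel_design(df)
  attr(df, "version") <- version
  class(df) <- c("panel_design", "data.frame")
  df
}

validate_panel_design <- function(df) {
  if (nrow(df) == 0L) stop_config("panel design has no target exons")
  if (any(df$end <= df$start)) {
    stop_config("panel design has empty or inverted target intervals")
  }
  if (anyDuplicated(df$exon_key)) {
    stop_config("duplicate (gene, exon_index) keys in panel design")
  }
  by_chrom <- split(df, df$chrom)
  for (d in by_chrom) {
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      stop_config("panel design has overlapping target intervals on ", d$chrom[1L])
    }
  }
  invisible(df)
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf(
    "Panel design '%s': %d genes, %d target exons, %.1f kb\n",
    attr(x, "version") %||% "panel",
    length(unique(x$gene)), nrow(x), sum(x$end - x$start) / 1000
  ))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Exon lengths of a panel design, in bp
#' @param design A [panel_design()].
#' @return Named numeric vector keyed by `exon_key`.
#' @export
exon_lengths <- function(design) {
  setNames(as.numeric(design$end - design$start), design$exon_key)
}

#' Number of targeted exons per gene
#' @param design A [panel_design()].
#' @return Named integer vector keyed by gene.
#' @export
exons_per_gene <- function(design) {
  tab <- table(design$gene)
  setNames(as.integer(tab), names(tab))
}

#' Write a panel design as a BED file
#'
#' Targets are written 0-based half-open with the exon key
#' (`gene|exon_index`) in the BED name column.
#'
#' @param design A [panel_design()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(design, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = design$chrom,
    ranges = IRanges::IRanges(start = design$start + 1L, end = design$end),
    name = design$exon_key
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a panel design from a BED file
#'
#' Expects the name column to carry `gene|exon_index` keys as written by
#' [write_panel_bed()].
#'
#' @param path BED file path.
#' @param version Panel version label to attach.
#' @return A [panel_design()].
#' @export
read_panel_bed <- function(path, version = "panel") {
  gr <- rtracklayer::import(path, format = "BED")
  name <- gr$name
  if (is.null(name) || anyNA(name) || !all(grepl("|", name, fixed = TRUE))) {
    stop_config("BED name column must carry 'gene|exon_index' keys")
  }
  parts <- strsplit(name, "|", fixed = TRUE)
  panel_design(
    gene = vapply(parts, `[[`, "", 1L),
    exon_index = as.integer(vapply(parts, `[[`, "", 2L)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    version = version
  )
}
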