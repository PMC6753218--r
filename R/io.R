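## Readers and writers for the pipeline's on-disk formats. Matrices
## travel as TSV with row keys in the first column; panel designs as BED
## (see panel_design.R); amplicon reads as FASTQ; variant and cohort
## tables as flat TSV (VCF via vcfR); truth sets as JSON.

#' Write a depth/RPKM/Z-score matrix as TSV
#'
#' Rows are exon keys, columns sample IDs. An optional `# stage:` header
#' line records the normalization stage; a `# total_reads:` line records
#' per-sample totals of a depth matrix.
#'
#' @param m Matrix with dimnames (a [depth_matrix()] or plain matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  stage <- attr(m, "stage")
  if (!is.null(stage)) writeLines(paste0("# stage: ", stage), con)
  totals <- attr(m, "total_reads")
  if (!is.null(totals)) {
    writeLines(paste0("# total_reads: ",
                      paste(names(totals), totals, sep = "=", collapse = ",")), con)
  }
  df <- data.frame(exon_key = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return Matrix with `stage`/`total_reads` attributes restored when
#'   present; depth matrices come back as [depth_matrix()].
#' @export
read_matrix_tsv <- function(path) {
  header <- character()
  con <- file(path, "r")
  repeat {
    line <- readLines(con, n = 1L)
    if (!startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  stage <- sub("^# stage: ", "", grep("^# stage: ", header, value = TRUE))
  totals_line <- grep("^# total_reads: ", header, value = TRUE)
  if (length(totals_line) == 1L) {
    kv <- strsplit(strsplit(sub("^# total_reads: ", "", totals_line), ",")[[1L]], "=")
    totals <- setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
                       vapply(kv, `[[`, "", 1L))
    m <- depth_matrix(m, totals)
  } else if (length(stage) == 1L) {
    attr(m, "stage") <- stage
  }
  m
}

#' Write amplicon reads as FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path (plain, uncompressed FASTQ).
#' @return `path`, invisibly.
#' @export
write_amplicon_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads)
  if (is.null(names(seqs))) names(seqs) <- sprintf("read%06d", seq_along(seqs))
  quals <- Biostrings::PhredQuality(
    vapply(Biostrings::width(seqs),
           function(w) paste(rep("I", w), collapse = ""), character(1))
  )
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read amplicon reads from FASTQ
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_amplicon_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(seqs), names(seqs))
}

#' Write a variant table as TSV
#' @param variants Variant data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant table from TSV
#'
#' Accepts tables written by [write_variants_tsv()] or transcriptions of
#' published variant tables; columns are taken as-is.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_variants_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             quote = "", na.strings = c("NA", ""))
}

#' Write a variant table as VCF
#'
#' Encodes each record as one VCF row on a synthetic contig, with the
#' sample's ref/alt read depths in the `AD` genotype field and the
#' population frequency and inheritance model as INFO tags.
#'
#' @param variants Variant data frame (see `R/variant_filter.R`).
#' @param path Output path; vcfR appends `.gz` handling by extension
#'   (use a `.vcf.gz` path for compressed output).
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("write_variants_vcf() requires the vcfR package")
  }
  n <- nrow(variants)
  info <- paste0(
    "GENE=", variants$gene,
    ";MODEL=", variants$inheritance_model,
    ifelse(is.na(variants$pop_frequency), "",
           paste0(";AF_POP=", signif(variants$pop_frequency, 6)))
  )
  fix <- cbind(
    CHROM = "chrS", POS = as.character(seq_len(n) * 1000L),
    ID = variants$variant, REF = "A", ALT = "G", QUAL = ".",
    FILTER = "PASS", INFO = info
  )
  gt <- cbind(
    FORMAT = "GT:AD:DP",
    SAMPLE = paste0(
      "0/1:", variants$ref_depth, ",", variants$alt_depth, ":",
      variants$ref_depth + variants$alt_depth
    )
  )
  meta <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene\">",
    "##INFO=<ID=MODEL,Number=1,Type=String,Description=\"Inheritance model\">",
    "##INFO=<ID=AF_POP,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">"
  )
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read a variant table from VCF
#'
#' Recovers sample-level ref/alt depths from the `AD` genotype field and
#' the `GENE`/`MODEL`/`AF_POP` INFO tags written by
#' [write_variants_vcf()].
#'
#' @param path VCF path (plain or gzipped).
#' @return Variant data frame.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_variants_vcf() requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1L]
  parts <- strsplit(ad, ",", fixed = TRUE)
  info_tag <- function(tag) {
    m <- regmatches(fix$INFO, regexpr(paste0(tag, "=[^;]+"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    out[grepl(paste0(tag, "="), fix$INFO)] <- sub(paste0(tag, "="), "", m)
    out
  }
  freq <- suppressWarnings(as.numeric(info_tag("AF_POP")))
  data.frame(
    sample = "SAMPLE",
    gene = info_tag("GENE"),
    variant = fix$ID,
    inheritance_model = info_tag("MODEL"),
    pop_frequency = freq,
    ref_depth = as.integer(vapply(parts, `[[`, "", 1L)),
    alt_depth = as.integer(vapply(parts, `[[`, "", 2L)),
    inheritance_obs = "not evaluated",
    stringsAsFactors = FALSE
  )
}

#' Read alignment records from a BAM file
#'
#' Adapter for BAM input to [count_reads_per_exon()]: yields one row per
#' primary aligned read with its reference span (0-based half-open,
#' CIGAR-aware) and mapping quality.
#'
#' @param path BAM file path (indexed or not).
#' @param sample Sample ID to attach to every record.
#' @return Data frame with columns `sample`, `chrom`, `start`, `end`, `mq`.
#' @export
read_alignments_bam <- function(path, sample = "SAMPLE") {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("read_alignments_bam() requires the GenomicAlignments package")
  }
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(what = "mapq")
  )
  data.frame(
    sample = sample,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    mq = S4Vectors::mcols(ga)$mapq,
    stringsAsFactors = FALSE
  )
}

#' Write a cohort table as TSV
#' @param cases Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cases, path) {
  write.table(cases, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from TSV
#' @param path TSV path.
#' @return Data frame.
#' @export
read_cohort_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("NA", ""))
}

#' Read a published amplicon allele-count table from TSV
#'
#' The packaged transcription keeps the printed percentage column as
#' character so that [vaf_discrepancy_report()] can compare at the
#' printed precision.
#'
#' @param path TSV path.
#' @return Data frame with `printed_percent` as character.
#' @export
read_amplicon_counts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = NA, na.strings = c("NA", ""))
  df$printed_percent <- as.character(df$printed_percent)
  df
}

#' Write a truth set as JSON
#' @param truth List or data frame of simulation ground truth.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under `inst/extdata`, or `NULL` to list them.
#' @return File path (or vector of available names).
#' @export
epipanel_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "epipanel"))
  } else {
    path <- system.file("extdata", file, package = "epipanel")
    if (!nzchar(path)) stop_config("no packaged file '", file, "'")
    path
  }
}
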