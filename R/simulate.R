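## Synthetic-data generator.
##
## Produces panel designs, multi-sample coverage matrices with spiked
## CNVs, annotated variant tables, barcoded amplicon read pools and
## cohort tables with known ground truth, so every downstream stage can
## be exercised and scored without patient data. Each generator draws
## from its own seeded RNG stream (withr::with_seed), so stages can be
## re-run independently and a config seed fixes all outputs bit-for-bit.

#' Simulation configuration
#'
#' Collects the knobs of the synthetic coverage model. Defaults emulate a
#' deep targeted epilepsy panel run: around 1,300x mean coverage, capture
#' targets of a few hundred bp (exon plus probe flanks), an order-of-
#' magnitude spread in capture efficiency across targets (log-SD 0.5) and
#' a modest within-batch spread in per-sample depth (log-SD 0.1), with
#' Poisson counting noise on top of the multiplicative expectation.
#'
#' @param seed Integer seed; fixes all generator outputs bit-for-bit.
#' @param n_samples Number of samples in the batch.
#' @param n_genes Number of panel genes.
#' @param exons_per_gene Count or range of targeted exons per gene.
#' @param exon_length Range of capture-target lengths in bp.
#' @param mean_depth Mean coverage depth (x) of the batch.
#' @param read_length Read length in bp used to convert depth to expected
#'   read counts (`expected count = depth * target length / read length`).
#' @param sample_depth_sd Log-scale SD of per-sample depth factors.
#' @param exon_bias_sd Log-scale SD of per-target capture-efficiency factors.
#' @param cnv_spikes Data frame of CNV spike-ins with columns `sample`,
#'   `gene`, `type` (`"deletion"`/`"duplication"`) and `dosage` (expected
#'   depth ratio in (0, 2]: 0.5 = heterozygous deletion, 1.5 =
#'   single-copy duplication), or `NULL`.
#' @param mosaic_spikes Data frame of mosaic variant spike-ins with
#'   columns `sample`, `site`, `vaf` (true fraction in \[0, 1\]) and
#'   `depth`, or `NULL`.
#' @param error_rate Per-base sequencing error probability.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_samples = 20L,
                       n_genes = 79L,
                       exons_per_gene = c(8L, 16L),
                       exon_length = c(280L, 420L),
                       mean_depth = 1337,
                       read_length = 100,
                       sample_depth_sd = 0.1,
                       exon_bias_sd = 0.5,
                       cnv_spikes = NULL,
                       mosaic_spikes = NULL,
                       error_rate = 1e-3) {
  if (!is_number(seed)) stop_config("seed must be a single integer")
  if (!is_number(n_samples) || n_samples < 1) stop_config("n_samples must be >= 1")
  if (!is_number(n_genes) || n_genes < 1) stop_config("n_genes must be >= 1")
  epg <- as_range(exons_per_gene, "exons_per_gene")
  if (epg[1] < 1) stop_config("exons_per_gene must be >= 1")
  len <- as_range(exon_length, "exon_length")
  if (len[1] < 1) stop_config("exon_length must be positive")
  if (!is_number(mean_depth) || mean_depth <= 0) stop_config("mean_depth must be positive")
  if (!is.null(cnv_spikes)) {
    need <- c("sample", "gene", "type", "dosage")
    if (!all(need %in% names(cnv_spikes))) {
      stop_config("cnv_spikes needs columns: ", paste(need, collapse = ", "))
    }
    if (any(cnv_spikes$dosage <= 0 | cnv_spikes$dosage > 2)) {
      stop_config("CNV dosage ratios must lie in (0, 2]")
    }
    if (!all(cnv_spikes$type %in% c("deletion", "duplication"))) {
      stop_config("CNV spike type must be 'deletion' or 'duplication'")
    }
  }
  if (!is.null(mosaic_spikes)) {
    need <- c("sample", "site", "vaf", "depth")
    if (!all(need %in% names(mosaic_spikes))) {
      stop_config("mosaic_spikes needs columns: ", paste(need, collapse = ", "))
    }
    if (any(mosaic_spikes$vaf < 0 | mosaic_spikes$vaf > 1)) {
      stop_config("true VAF must lie in [0, 1]")
    }
  }
  if (!is_number(error_rate) || error_rate < 0 || error_rate > 1) {
    stop_config("error_rate must be a probability")
  }
  structure(list(
    seed = as.integer(seed),
    n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(epg),
    exon_length = as.integer(len),
    mean_depth = mean_depth,
    read_length = read_length,
    sample_depth_sd = sample_depth_sd,
    exon_bias_sd = exon_bias_sd,
    cnv_spikes = cnv_spikes,
    mosaic_spikes = mosaic_spikes,
    error_rate = error_rate
  ), class = "sim_config")
}

sample_ids <- function(n) sprintf("S%02d", seq_len(n))

# draw integers uniformly from [r[1], r[2]]; safe for degenerate ranges
# (sample(4:4, ...) would draw from 1:4)
sample_range <- function(r, n) {
  r[1] + sample.int(r[2] - r[1] + 1L, n, replace = TRUE) - 1L
}

#' Simulate a panel design
#'
#' Generates `n_genes` genes with a drawn number of target exons each,
#' laid out as sorted, non-overlapping half-open intervals on one
#' synthetic chromosome with fixed inter-target gaps.
#'
#' @param config A [sim_config()].
#' @return A [panel_design()].
#' @export
simulate_panel_design <- function(config) {
  withr::with_seed(config$seed + 101L, {
    epg <- config$exons_per_gene
    n_exons <- sample_range(epg, config$n_genes)
    len <- sample_range(config$exon_length, sum(n_exons))
    gene <- rep(sprintf("GENE%03d", seq_len(config$n_genes)), n_exons)
    exon_index <- unlist(lapply(n_exons, seq_len), use.names = FALSE)
    gap <- 2000L
    end <- cumsum(len + gap)
    panel_design(
      gene = gene, exon_index = exon_index, chrom = "chrS",
      start = end - len, end = end,
      version = sprintf("sim-%dgenes", config$n_genes)
    )
  })
}

#' Simulate a coverage matrix with spiked CNVs
#'
#' Expected counts follow a multiplicative model,
#' `mean_depth * sample factor * exon factor * dosage * length / read length`,
#' with log-normal sample and exon factors and Poisson counting noise.
#' CNV spike-ins scale the expectation of every exon of the named gene in
#' the named sample by the dosage ratio.
#'
#' @param design A [panel_design()], typically from
#'   [simulate_panel_design()].
#' @param config The same [sim_config()].
#' @return List with `depth` (a [depth_matrix()]) and `truth` (data frame
#'   of spiked gene-level CNVs: `sample`, `gene`, `type`, `dosage`).
#' @export
simulate_coverage_matrix <- function(design, config) {
  samples <- sample_ids(config$n_samples)
  spikes <- config$cnv_spikes
  if (!is.null(spikes)) {
    if (!all(spikes$sample %in% samples)) {
      stop_config("CNV spike references a sample absent from the batch")
    }
    if (!all(spikes$gene %in% design$gene)) {
      stop_config("CNV spike references a gene absent from the design")
    }
  }
  withr::with_seed(config$seed + 202L, {
    n_e <- nrow(design)
    n_s <- config$n_samples
    # mean-one log-normal factors, so mean_depth is the realized cohort mean
    sf <- exp(rnorm(n_s, -config$sample_depth_sd^2 / 2, config$sample_depth_sd))
    ef <- exp(rnorm(n_e, -config$exon_bias_sd^2 / 2, config$exon_bias_sd))
    dosage <- matrix(1, n_e, n_s, dimnames = list(design$exon_key, samples))
    if (!is.null(spikes)) {
      for (i in seq_len(nrow(spikes))) {
        dosage[design$gene == spikes$gene[i], spikes$sample[i]] <- spikes$dosage[i]
      }
    }
    len <- design$end - design$start
    mu <- config$mean_depth * outer(ef * len / config$read_length, sf) * dosage
    counts <- matrix(rpois(length(mu), mu), n_e, n_s,
                     dimnames = list(design$exon_key, samples))
    truth <- if (is.null(spikes)) {
      data.frame(sample = character(), gene = character(),
                 type = character(), dosage = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      spikes[, c("sample", "gene", "type", "dosage")]
    }
    list(depth = depth_matrix(counts), truth = truth)
  })
}

## Fixed 80-bp synthetic template around the validated site; the variant
## position is base 41 of the template (read position 51 after the
## 10-base barcode+adaptor tag).
amplicon_template_seq <- paste0(
  "ACGTTCGAACGGATTACAGCTTGGCCATAGCATCAGGTAC",  # 1-40
  "GTTACCGGTTAGGCATCCGATTACGGATCAGGCTTACAGT"   # 41-80
)
amplicon_site_offset <- 41L

#' Site descriptor of the synthetic amplicon
#'
#' @return List with `offset` (position within the template), `ref` and
#'   `alt` alleles of the simulated variant site.
#' @export
amplicon_site <- function() {
  list(offset = amplicon_site_offset,
       ref = substr(amplicon_template_seq, amplicon_site_offset,
                    amplicon_site_offset),
       alt = "A")
}

#' Simulate a barcoded amplicon read pool
#'
#' Each sample contributes `n_reads` reads of the form
#' `barcode + "AGAT" + 80-bp template`; the template carries the variant
#' allele with probability equal to the sample's true VAF (Bernoulli
#' draws), after which uniform per-base substitution errors are injected
#' across the whole read. Reads from all samples are pooled and shuffled.
#'
#' @param barcodes Named character vector, sample -> 6-nt barcode
#'   (pairwise distinct).
#' @param site_vaf Named numeric vector, sample -> true variant allele
#'   fraction in \[0, 1\]; names must match `barcodes`.
#' @param n_reads Reads per sample.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return List with `reads` (named character vector of pooled reads),
#'   `site` (see [amplicon_site()]) and `truth` (data frame `sample`,
#'   `true_vaf`, `n_reads`, `n_alt_drawn`).
#' @export
simulate_amplicon_readset <- function(barcodes, site_vaf, n_reads = 10000L,
                                      error_rate = 1e-3, seed = 1L) {
  barcodes <- validate_barcodes(barcodes)
  if (!setequal(names(site_vaf), names(barcodes))) {
    stop_config("site_vaf must be named by the same samples as barcodes")
  }
  if (any(site_vaf < 0 | site_vaf > 1)) stop_config("true VAF must lie in [0, 1]")
  site <- amplicon_site()
  withr::with_seed(as.integer(seed) + 303L, {
    pieces <- lapply(names(barcodes), function(s) {
      is_alt <- runif(n_reads) < site_vaf[[s]]
      template <- rep(amplicon_template_seq, n_reads)
      substr(template, site$offset, site$offset) <-
        ifelse(is_alt, site$alt, site$ref)
      list(reads = paste0(barcodes[[s]], amplicon_adaptor, template),
           n_alt = sum(is_alt))
    })
    reads <- unlist(lapply(pieces, `[[`, "reads"), use.names = FALSE)
    if (error_rate > 0) reads <- inject_errors(reads, error_rate)
    names(reads) <- sprintf("read%06d", seq_along(reads))
    reads <- reads[sample.int(length(reads))]
    truth <- data.frame(
      sample = names(barcodes),
      true_vaf = as.numeric(site_vaf[names(barcodes)]),
      n_reads = as.integer(n_reads),
      n_alt_drawn = vapply(pieces, function(p) as.integer(p$n_alt), integer(1)),
      stringsAsFactors = FALSE
    )
    list(reads = reads, site = site, truth = truth)
  })
}

## Uniform substitution errors: each base is replaced, with probability
## error_rate, by one of the three other bases.
inject_errors <- function(reads, error_rate) {
  read_len <- nchar(reads[1L])
  mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                nrow = length(reads), ncol = read_len, byrow = TRUE)
  hit <- which(matrix(runif(length(mat)) < error_rate,
                      nrow = nrow(mat)), arr.ind = FALSE)
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(mat[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1))
    mat[hit] <- repl
  }
  apply(mat, 1L, paste0, collapse = "")
}

#' Simulate a cohort table with fixed per-group yields
#'
#' Builds one case record per patient with exact group sizes and exactly
#' `round(size * yield)` diagnosed cases per group. Groups named after
#' the onset strata (`"neonatal"`, `"early infantile"`, `"late
#' infantile"`) get onset ages drawn within the group's day range and
#' syndrome labels left unclassified; any other group name is treated as
#' a syndrome stratum with onset drawn across the first year.
#'
#' @param group_sizes Named integer vector, group -> number of cases.
#' @param group_yields Named numeric vector, group -> diagnostic yield in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @return Cohort data frame (`case_id`, `group`, `onset_days`,
#'   `onset_group`, `syndrome`, `gene`, `variant_class`,
#'   `classification`, `diagnosed`).
#' @export
simulate_cohort <- function(group_sizes, group_yields, seed = 1L) {
  if (any(group_sizes < 0)) stop_config("group sizes must be non-negative")
  if (any(group_yields < 0 | group_yields > 1)) {
    stop_config("group yields must lie in [0, 1]")
  }
  if (!setequal(names(group_sizes), names(group_yields))) {
    stop_config("group_sizes and group_yields must share names")
  }
  day_range <- list(
    "neonatal" = c(0L, 30L),
    "early infantile" = c(31L, 182L),
    "late infantile" = c(183L, 365L)
  )
  panel_genes <- c("PRRT2", "SCN1A", "KCNQ2", "SCN2A", "STXBP1", "SCN8A")
  withr::with_seed(as.integer(seed) + 404L, {
    rows <- lapply(names(group_sizes), function(g) {
      n <- as.integer(group_sizes[[g]])
      if (n == 0L) return(NULL)
      n_dx <- as.integer(round(n * group_yields[[g]]))
      r <- day_range[[g]] %||% c(0L, 365L)
      onset <- sample(r[1]:r[2], n, replace = TRUE)
      diagnosed <- seq_len(n) <= n_dx
      data.frame(
        case_id = paste0(gsub(" ", "_", g), "_", sprintf("%03d", seq_len(n))),
        group = g,
        onset_days = onset,
        onset_group = assign_onset_group(onset),
        syndrome = if (g %in% names(day_range)) "unclassified" else g,
        gene = ifelse(diagnosed,
                      sample(panel_genes, n, replace = TRUE), "none"),
        variant_class = ifelse(diagnosed, "sequence", "none"),
        classification = ifelse(diagnosed, "Pathogenic", "none"),
        diagnosed = diagnosed,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate an annotated variant table
#'
#' Draws variant records of four classes: `common` (nonzero population
#' frequency), `rare-AD` (novel variants in dominant genes), `rare-AR`
#' (sub-0.01% variants in recessive genes) and `mosaic` (true VAF drawn
#' uniformly in \[0.05, 0.25\] at total depth of at least 500, with the
#' variant read count drawn binomially). The truth set records the
#' spiked mosaic entries with their realized counts.
#'
#' @param n_variants Number of records.
#' @param class_mix Named proportions over
#'   `c("common", "rare-AD", "rare-AR", "mosaic")`; must sum to 1.
#' @param seed Integer seed.
#' @return List with `variants` (data frame; see `R/variant_filter.R` for
#'   the column contract) and `truth` (mosaic rows with `true_vaf`).
#' @export
simulate_variant_table <- function(n_variants,
                                   class_mix = c("common" = 0.4,
                                                 "rare-AD" = 0.25,
                                                 "rare-AR" = 0.15,
                                                 "mosaic" = 0.2),
                                   seed = 1L) {
  classes <- c("common", "rare-AD", "rare-AR", "mosaic")
  if (!setequal(names(class_mix), classes)) {
    stop_config("class_mix must be named: ", paste(classes, collapse = ", "))
  }
  if (abs(sum(class_mix) - 1) > 1e-8) stop_config("class_mix must sum to 1")
  class_mix <- class_mix[classes]
  counts <- diff(c(0L, round(cumsum(class_mix) * n_variants)))
  names(counts) <- classes
  withr::with_seed(as.integer(seed) + 505L, {
    cls <- rep(classes, counts)
    n <- length(cls)
    depth <- ifelse(cls == "mosaic",
                    sample(500:3000, n, replace = TRUE),
                    sample(200:3000, n, replace = TRUE))
    true_vaf <- ifelse(cls == "mosaic",
                       runif(n, 0.05, 0.25),
                       pmin(pmax(rnorm(n, 0.5, 0.05), 0), 1))
    alt <- rbinom(n, depth, true_vaf)
    freq <- numeric(n)
    freq[cls == "common"] <- 10^runif(sum(cls == "common"), -4, -1)
    freq[cls == "rare-AR"] <- runif(sum(cls == "rare-AR"), 0, 1e-4)
    variants <- data.frame(
      sample = sprintf("S%02d", sample.int(20L, n, replace = TRUE)),
      gene = sprintf("GENE%03d", sample.int(79L, n, replace = TRUE)),
      variant = sprintf("var%04d", seq_len(n)),
      inheritance_model = ifelse(cls == "rare-AR", "AR", "AD"),
      pop_frequency = ifelse(freq == 0, NA_real_, freq),
      ref_depth = depth - alt,
      alt_depth = alt,
      inheritance_obs = "not evaluated",
      sim_class = cls,
      stringsAsFactors = FALSE
    )
    truth <- variants[cls == "mosaic", , drop = FALSE]
    truth$true_vaf <- true_vaf[cls == "mosaic"]
    rownames(truth) <- NULL
    list(variants = variants, truth = truth)
  })
}
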