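# Small fixed designs and simulation shortcuts used across test files.

toy_design <- function() {
  # three exons of one gene plus one exon of a second gene, on two chromosomes
  panel_design(
    gene = c("GA", "GA", "GA", "GB"),
    exon_index = c(1L, 2L, 3L, 1L),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 300L, 600L, 50L),
    end = c(200L, 450L, 700L, 150L),
    version = "toy"
  )
}

# One 20-sample batch at the deep-coverage study scale, optionally with a
# heterozygous whole-gene deletion spiked into sample S01.
cnv_batch_config <- function(seed, spike = TRUE) {
  spikes <- if (spike) {
    data.frame(sample = "S01", gene = "GENE007", type = "deletion",
               dosage = 0.5, stringsAsFactors = FALSE)
  }
  sim_config(
    seed = seed, n_samples = 20L, n_genes = 119L, exons_per_gene = 10L,
    mean_depth = 1000, cnv_spikes = spikes
  )
}

run_cnv_batch <- function(seed, spike = TRUE) {
  cfg <- cnv_batch_config(seed, spike)
  design <- simulate_panel_design(cfg)
  cov <- simulate_coverage_matrix(design, cfg)
  rpkm <- compute_rpkm(cov$depth, design)
  res <- call_cnvs(rpkm, design)
  res$truth <- cov$truth
  res
}
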