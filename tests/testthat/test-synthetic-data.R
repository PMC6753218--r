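# Synthetic-data generator: designs, coverage, amplicons, cohorts, variants.

test_that("panel design generation respects size, ordering and determinism", {
  cfg <- sim_config(seed = 7L, n_genes = 79L)
  d <- simulate_panel_design(cfg)
  expect_s3_class(d, "panel_design")
  expect_equal(length(unique(d$gene)), 79L)
  expect_true(all(d$end > d$start))
  expect_true(all(diff(d$start) > 0))           # sorted, non-overlapping
  expect_true(all(d$start[-1L] >= d$end[-nrow(d)]))
  # minimal case
  d1 <- simulate_panel_design(sim_config(seed = 1L, n_genes = 1L,
                                         exons_per_gene = 1L))
  expect_equal(nrow(d1), 1L)
  # determinism
  expect_identical(d, simulate_panel_design(sim_config(seed = 7L, n_genes = 79L)))
  # invalid ranges are configuration errors
  expect_error(sim_config(seed = 1L, n_genes = 0L), "n_genes")
  expect_error(sim_config(seed = 1L, exons_per_gene = c(5L, 2L)), "range")
})

test_that("spiked deletions halve mean coverage relative to the cohort", {
  cfg0 <- sim_config(
    seed = 1L, n_samples = 8L, n_genes = 6L, exons_per_gene = 4L,
    mean_depth = 300,
    cnv_spikes = data.frame(sample = "S01", gene = "GENE003",
                            type = "deletion", dosage = 0.5)
  )
  design <- simulate_panel_design(cfg0)
  in_gene <- design$gene == "GENE003"
  ratios <- vapply(1:100, function(k) {
    cfg <- sim_config(
      seed = k, n_samples = 8L, n_genes = 6L, exons_per_gene = 4L,
      mean_depth = 300,
      cnv_spikes = cfg0$cnv_spikes
    )
    cov <- simulate_coverage_matrix(design, cfg)
    m <- unclass(cov$depth)
    # per-exon ratio of the spiked sample to the unspiked cohort mean
    mean(m[in_gene, "S01"] / rowMeans(m[in_gene, -1L]))
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.5), 3 * se + 0.02)
})

test_that("coverage is deterministic, integer, and validates spikes", {
  cfg <- sim_config(seed = 5L, n_samples = 4L, n_genes = 5L,
                    exons_per_gene = c(2L, 4L), mean_depth = 150)
  design <- simulate_panel_design(cfg)
  cov1 <- simulate_coverage_matrix(design, cfg)
  cov2 <- simulate_coverage_matrix(design, cfg)
  expect_identical(unclass(cov1$depth), unclass(cov2$depth))
  expect_true(all(cov1$depth >= 0))
  expect_true(all(cov1$depth == floor(cov1$depth)))
  bad <- sim_config(seed = 5L, n_samples = 4L, n_genes = 5L,
                    cnv_spikes = data.frame(sample = "S01", gene = "NOPE",
                                            type = "deletion", dosage = 0.5))
  expect_error(simulate_coverage_matrix(simulate_panel_design(bad), bad),
               "absent from the design")
  expect_error(sim_config(seed = 1L,
                          cnv_spikes = data.frame(sample = "S01", gene = "G",
                                                  type = "deletion", dosage = 3)),
               "dosage")
})

test_that("without spikes, mean RPKM matches the analytic expectation", {
  # zero dispersion: expected RPKM is flat across exons at
  # 1e9 * depth / (read_length * sum of expected counts)
  cfg0 <- sim_config(seed = 1L, n_samples = 5L, n_genes = 4L,
                     exons_per_gene = 3L, mean_depth = 200,
                     sample_depth_sd = 0, exon_bias_sd = 0)
  design <- simulate_panel_design(cfg0)
  len <- exon_lengths(design)
  expected_total <- sum(200 * len / 100)
  expected_rpkm <- 1e9 * 200 / (100 * expected_total)
  reps <- vapply(1:60, function(k) {
    cfg <- sim_config(seed = k, n_samples = 5L, n_genes = 4L,
                      exons_per_gene = 3L, mean_depth = 200,
                      sample_depth_sd = 0, exon_bias_sd = 0)
    cov <- simulate_coverage_matrix(design, cfg)
    mean(compute_rpkm(cov$depth, design))
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected_rpkm), 3 * se + 1e-3 * expected_rpkm)
})

test_that("amplicon pools conserve reads and hit the requested VAF", {
  bc <- c(S1 = "AACCGG", S2 = "TTGGCC", S3 = "ACGTAC")
  rs <- simulate_amplicon_readset(bc, c(S1 = 0, S2 = 0.5, S3 = 0.1),
                                  n_reads = 10000L, error_rate = 0, seed = 3L)
  expect_length(rs$reads, 30000L)
  expect_identical(
    rs$reads,
    simulate_amplicon_readset(bc, c(S1 = 0, S2 = 0.5, S3 = 0.1),
                              n_reads = 10000L, error_rate = 0, seed = 3L)$reads
  )
  dm <- demultiplex_reads(rs$reads, bc)
  expect_equal(sum(lengths(dm$assigned)) + length(dm$unassigned), 30000L)
  # VAF 0 with no errors: zero alt reads
  c1 <- count_alleles_at_site(dm$assigned$S1, rs$site, "S1")
  expect_equal(c1$var_count, 0L)
  # VAF 0.5: within 3 binomial SE of 5,000
  c2 <- count_alleles_at_site(dm$assigned$S2, rs$site, "S2")
  expect_lt(abs(c2$var_count - 5000), 3 * sqrt(10000 * 0.25))
  expect_error(
    simulate_amplicon_readset(c(S1 = "AACCGG", S2 = "AACCGG"),
                              c(S1 = 0, S2 = 0), seed = 1L),
    "duplicate"
  )
})

test_that("cohort simulation hits exact group sizes and diagnosed counts", {
  co <- simulate_cohort(c("neonatal" = 26L), c("neonatal" = 16 / 26), seed = 2L)
  expect_equal(nrow(co), 26L)
  expect_equal(sum(co$diagnosed), 16L)
  expect_true(all(co$onset_group == "neonatal"))

  sizes <- c("neonatal" = 26L, "early infantile" = 58L, "late infantile" = 28L)
  yields <- c("neonatal" = 16 / 26, "early infantile" = 29 / 58,
              "late infantile" = 8 / 28)
  co3 <- simulate_cohort(sizes, yields, seed = 2L)
  expect_equal(nrow(co3), 112L)
  expect_equal(as.vector(table(co3$group)[names(sizes)]), unname(sizes),
               ignore_attr = TRUE)
  expect_identical(co3, simulate_cohort(sizes, yields, seed = 2L))
  # zero yield
  expect_equal(sum(simulate_cohort(c(g = 10L), c(g = 0), seed = 1L)$diagnosed), 0L)
  expect_error(simulate_cohort(c(g = -1L), c(g = 0.5), seed = 1L), "non-negative")
})

test_that("variant tables honor the class mix and mosaic depth contract", {
  vt <- simulate_variant_table(200L, seed = 9L)
  expect_equal(nrow(vt$variants), 200L)
  mos <- vt$variants[vt$variants$sim_class == "mosaic", ]
  expect_true(all(mos$ref_depth + mos$alt_depth >= 500L))
  expect_true(all(vt$truth$true_vaf >= 0.05 & vt$truth$true_vaf <= 0.25))
  expect_equal(nrow(vt$truth), sum(vt$variants$sim_class == "mosaic"))
  expect_identical(vt, simulate_variant_table(200L, seed = 9L))
  # 100% common: the frequency filter removes everything
  all_common <- simulate_variant_table(
    50L, class_mix = c("common" = 1, "rare-AD" = 0, "rare-AR" = 0, "mosaic" = 0),
    seed = 1L
  )
  expect_equal(nrow(population_frequency_filter(all_common$variants)), 0L)
  expect_error(simulate_variant_table(10L, class_mix = c(common = 0.5)), "named")
})
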