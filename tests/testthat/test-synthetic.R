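test_that("simulated somatic VAF follows the dosage formula", {
  # analytic expectation: purity 0.57, heterozygous diploid -> 0.285;
  # Monte-Carlo mean over many seeds must agree within 3 standard errors
  panel <- small_panel()
  vafs <- vapply(1:200, function(s) {
    truth <- simulation_truth(purity = 0.57, clones = clone(), seed = s)
    tab <- simulate_variant_table(truth, panel)
    tab$vaf[tab$truth_class == "somatic_driver"]
  }, numeric(1))
  expect_equal(unique(vapply(1:5, function(s) {
    truth <- simulation_truth(purity = 0.57, clones = clone(), seed = s)
    simulate_variant_table(truth, panel)$expected_vaf[1]
  }, numeric(1))), 0.285)
  se <- sd(vafs) / sqrt(length(vafs))
  expect_lt(abs(mean(vafs) - 0.285), 3 * se)
})

test_that("hom_loh dosage pushes VAF through the mixing model", {
  truth <- simulation_truth(
    purity = 0.8, clones = clone(copy_state = "hom_loh"), seed = 2
  )
  tab <- simulate_variant_table(truth, small_panel())
  expect_equal(tab$expected_vaf[1], 0.8 / (2 - 0.8))
})

test_that("zero purity yields no somatic calls", {
  truth <- simulation_truth(purity = 0, clones = clone(), seed = 4)
  tab <- simulate_variant_table(truth, small_panel())
  expect_equal(sum(tab$truth_class %in%
                     c("somatic_driver", "somatic_benign")), 0)
})

test_that("simulators are deterministic given the seed", {
  panel <- small_panel()
  truth <- simulation_truth(purity = 0.4, clones = clone(),
                            germline_snps = 20, artifact_rate = 0.05,
                            seed = 99)
  expect_identical(simulate_variant_table(truth, panel),
                   simulate_variant_table(truth, panel))
  expect_identical(simulate_coverage(truth, panel),
                   simulate_coverage(truth, panel))
  d1 <- simulate_droplets(0.1, 0.5, seed = 7)
  d2 <- simulate_droplets(0.1, 0.5, seed = 7)
  expect_identical(d1, d2)
})

test_that("truth construction rejects invalid parameters", {
  expect_error(simulation_truth(purity = 1.2), "purity")
  expect_error(simulation_truth(purity = -0.1), "purity")
  expect_error(simulation_truth(0.5, clones = clone(clonal_fraction = 0)),
               "clonal fractions")
  expect_error(simulate_variant_table(
    simulation_truth(0.5, clone()), small_panel(), mean_depth = 0
  ), "mean_depth")
  expect_error(simulate_coverage(simulation_truth(0.5), small_panel(),
                                 noise_cv = -1), "noise_cv")
  expect_error(simulate_droplets(-1, 0.5), "lambda")
})

test_that("coverage obeys the purity/copy-number mixing formula", {
  panel <- default_panel()
  truth <- simulation_truth(purity = 0.3, amplified_genes = c(MYCN = 50),
                            seed = 1)
  # noiseless: exact fold change (2(1-p) + C p)/2 = 8.2 over neutral
  cov0 <- simulate_coverage(truth, panel, noise_cv = 0)
  neutral <- cov0$umi_depth[cov0$gene == "ALK"][1]
  expect_equal(unique(cov0$umi_depth[cov0$gene == "MYCN"]) / neutral, 8.2)
  # copy-neutral noiseless sample: all autosomal coverages identical
  flat <- simulate_coverage(simulation_truth(purity = 0.5), panel,
                            noise_cv = 0)
  expect_equal(length(unique(flat$umi_depth[flat$chrom != "chrX"])), 1)
  # chrX targets scale by germline X copies / 2
  expect_equal(unique(flat$umi_depth[flat$chrom == "chrX"]) /
                 unique(flat$umi_depth[flat$chrom != "chrX"]), 0.5)
  # Monte-Carlo: spiked-gene fold recovered within 3 SE over 100 seeds
  folds <- vapply(1:100, function(s) {
    cv <- simulate_coverage(truth, panel, noise_cv = 0.1, seed = s)
    mean(cv$umi_depth[cv$gene == "MYCN"]) /
      mean(cv$umi_depth[cv$gene %in% c("ALK", "TP53", "KRAS")])
  }, numeric(1))
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 8.2), 3 * se)
})

test_that("droplet positives follow 1 - exp(-lambda)", {
  d <- simulate_droplets(lambda_wt = 0.05, lambda_mut = 1.0,
                         n_droplets = 20000, seed = 3)
  p <- 1 - exp(-1)
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(d$n_mut_pos / d$n_total - p), 3 * se)
  # zero-rate channel gives zero positives
  d0 <- simulate_droplets(lambda_wt = 0.5, lambda_mut = 0, seed = 3)
  expect_equal(d0$n_mut_pos, 0L)
})

test_that("clonal-evolution scenario reproduces its design", {
  sc <- scenario_clonal_evolution(seed = 1)
  drv <- sc$variants[sc$variants$truth_class == "somatic_driver", ]
  expect_equal(sum(drv$sample_id == "P1_diag_ctDNA"), 2)
  expect_equal(sum(drv$sample_id == "P1_remission_ctDNA"), 0)
  expect_equal(sum(drv$sample_id == "P1_relapse_ctDNA"), 1)
  expect_equal(sum(drv$sample_id == "P1_diag_tumour"), 1)
  expect_identical(scenario_clonal_evolution(seed = 5)$variants,
                   scenario_clonal_evolution(seed = 5)$variants)
})
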