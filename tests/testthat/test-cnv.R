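flat_coverage <- function(depth = 1000, panel = small_panel()) {
  tibble::tibble(
    sample_id = "S1", target_id = panel$target_id, gene = panel$gene,
    chrom = panel$chrom, start = panel$start, end = panel$end,
    umi_depth = depth
  )
}

test_that("baseline on uniform depth is exact and exclusions apply", {
  cov <- flat_coverage(depth = 1500)
  bl <- compute_baseline(cov, trim_fraction = 0)
  expect_equal(bl$mu, 1500)
  expect_equal(bl$sigma, 0)
  # chrX targets are never part of the baseline
  expect_false(any(bl$included_targets %in%
                     cov$target_id[cov$chrom == "chrX"]))
  expect_true(all(c("chrX") %in% bl$excluded$reason))
  # known-amplified exclusion
  bl2 <- compute_baseline(cov, known_amplified = "MYCN")
  expect_false(any(grepl("^MYCN_", bl2$included_targets)))
  # exclusion + trimming partition the panel
  expect_equal(sort(c(bl2$included_targets, bl2$excluded$target_id)),
               sort(cov$target_id))
})

test_that("trimming keeps a 50x spike out of the baseline", {
  set.seed(42)
  cov <- flat_coverage(depth = 1000)
  cov$umi_depth <- cov$umi_depth * (1 + rnorm(nrow(cov), 0, 0.02))
  cov$umi_depth[cov$gene == "MYCN"] <- 50000
  bl <- compute_baseline(cov, trim_fraction = 0.05)
  expect_false(any(grepl("^MYCN_", bl$included_targets)))
  expect_lt(abs(bl$mu - 1000) / 1000, 0.01)
})

test_that("baseline fails loudly when too few targets survive", {
  cov <- flat_coverage(panel = default_panel(n_genes = 2,
                                             targets_per_gene = 3))
  expect_error(compute_baseline(cov, known_amplified = c("ALK", "MYCN")),
               "at least 5")
})

test_that("z-scores equal the brute-force (x - mu) / sigma", {
  panel <- default_panel(targets_per_gene = 1)
  cov <- flat_coverage(panel = panel)
  cov$umi_depth <- c(rep(100, 40), rep(1000, 2))
  # independent recomputation on the same baseline-included depths
  bl <- compute_baseline(cov, trim_fraction = 0)
  inc <- cov$umi_depth[cov$target_id %in% bl$included_targets]
  mu <- sum(inc) / length(inc)
  sigma <- sqrt(sum((inc - mu)^2) / (length(inc) - 1))
  z <- z_scores(cov, bl)
  expect_equal(z$z, (cov$umi_depth - mu) / sigma, tolerance = 1e-12)
  expect_equal(z$inv_z, -z$z)
  # unit checks: x = mu -> 0, x = mu + sigma -> 1
  expect_equal(unname((mu - mu) / sigma), 0)
  idx <- which.max(z$umi_depth)
  expect_equal(z$z[idx], (1000 - mu) / sigma, tolerance = 1e-12)
  # baseline-included z has mean 0, sd 1
  zin <- z$z[z$in_baseline]
  expect_equal(mean(zin), 0, tolerance = 1e-12)
  expect_equal(sd(zin), 1, tolerance = 1e-12)
})

test_that("z-scores are invariant to depth rescaling and refuse sigma 0", {
  truth <- simulation_truth(purity = 0.3, amplified_genes = c(MYCN = 20),
                            seed = 8)
  cov <- simulate_coverage(truth, small_panel(), noise_cv = 0.1)
  bl <- compute_baseline(cov)
  z1 <- z_scores(cov, bl)$z
  cov2 <- dplyr::mutate(cov, umi_depth = umi_depth * 7)
  z2 <- z_scores(cov2, compute_baseline(cov2))$z
  expect_equal(z1, z2, tolerance = 1e-9)
  expect_error(z_scores(flat_coverage(),
                        compute_baseline(flat_coverage(),
                                         trim_fraction = 0)),
               "standard deviation is 0")
})

test_that("simulated MNA is called amplified; neutral and off-panel are not", {
  panel <- default_panel()
  mna <- simulation_truth(purity = 0.3, amplified_genes = c(MYCN = 50),
                          seed = 31)
  calls <- detect_amplifications(
    simulate_coverage(mna, panel, noise_cv = 0.1)
  )$calls
  expect_equal(calls$status[calls$gene == "MYCN"], "amplified")
  # an amplification entirely outside the panel footprint leaves no
  # coverage signal and is never called
  off <- simulation_truth(purity = 0.9, amplified_genes = c(OFFPANEL = 80),
                          seed = 31)
  calls_off <- detect_amplifications(
    simulate_coverage(off, panel, noise_cv = 0.1)
  )$calls
  expect_equal(sum(calls_off$status != "neutral"), 0)
})

test_that("amplification thresholds are validated and zero-target genes warned", {
  set.seed(42)
  cov <- flat_coverage()
  cov$umi_depth <- cov$umi_depth * (1 + rnorm(nrow(cov), 0, 0.05))
  z <- z_scores(cov, compute_baseline(cov))
  expect_error(call_amplifications(z, z_amp = 2, z_gain = 5), "z_amp")
  expect_warning(
    call_amplifications(z[z$gene != "ALK", ], panel = small_panel()),
    "ALK"
  )
})
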