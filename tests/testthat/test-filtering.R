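test_that("sample QC fails below the cfDNA fraction threshold", {
  expect_equal(qc_sample(0.06), "fail")
  expect_equal(qc_sample(0.20), "pass")  # boundary: rule is strictly below
  expect_equal(qc_sample(1.0), "pass")
  expect_error(qc_sample(1.5), "\\[0, 1\\]")
})

test_that("depth/VAF filter applies inclusive-keep boundaries", {
  v <- driver_row(vaf = c(0.0285, 0.30, 0.004, 0.005, 0.01),
                  depth = c(5000, 99, 5000, 100, 100))
  kept <- depth_vaf_filter(v)
  expect_equal(kept$vaf, c(0.0285, 0.005, 0.01))
  # flagged artifacts and duplicates are removed regardless of depth/VAF
  flagged <- driver_row(artifact_flag = c(TRUE, FALSE),
                        duplicate_flag = c(FALSE, TRUE))
  expect_equal(nrow(depth_vaf_filter(flagged)), 0)
  expect_equal(nrow(depth_vaf_filter(driver_row()[0, ])), 0)
})

test_that("population filter removes only demonstrably common variants", {
  v <- driver_row(gnomad_af = c(0.02, NA, 0.009, NA),
                  dbsnp_common_maf = c(NA, NA, NA, 0.01))
  kept <- population_germline_filter(v)
  expect_equal(kept$gnomad_af, c(NA, 0.009))
})

test_that("population filter separates germline SNPs from drivers by truth label", {
  truth <- simulation_truth(
    purity = 0.5,
    clones = clone(gene = rep(c("ALK", "TP53", "KRAS", "NRAS", "PTPN11"), 2),
                   clonal_fraction = rep(c(1, 0.5), each = 5)),
    germline_snps = 100, seed = 12
  )
  tab <- simulate_variant_table(truth, default_panel())
  kept <- population_germline_filter(tab)
  expect_equal(sum(kept$truth_class == "germline_snp"), 0)
  expect_equal(sum(kept$truth_class == "somatic_driver"),
               sum(tab$truth_class == "somatic_driver"))
})

test_that("matched germline subtraction is an exact set difference", {
  shared <- driver_row(pos = 1:50 * 100L)
  private <- driver_row(pos = 9000L + 1:5, gene = "TP53")
  tumour <- dplyr::bind_rows(shared, private)
  out <- matched_germline_subtract(tumour, shared)
  expect_equal(nrow(out), 5)
  expect_equal(attr(out, "n_germline_removed"), 50L)
  expect_equal(nrow(matched_germline_subtract(tumour, tumour[0, ])), 55)
  expect_warning(matched_germline_subtract(tumour, NULL), "germline")
})

test_that("reporting threshold gates on tier and strict VAF", {
  v <- classify_variants(driver_row(vaf = c(0.0138, 0.009, 0.50)))
  v$tier[3] <- factor("VUS", levels = levels(v$tier), ordered = TRUE)
  rep <- apply_reporting_threshold(v)
  expect_equal(rep$vaf, 0.0138)
})

test_that("the cascade is monotone, idempotent and order-invariant", {
  truth <- simulation_truth(
    purity = 0.4, clones = clone(gene = c("ALK", "TP53")),
    germline_snps = 40, artifact_rate = 0.1, seed = 21
  )
  tab <- simulate_variant_table(truth, default_panel())
  cfg <- filter_config()
  base <- filter_variants(tab, cfg)
  # raising any threshold never grows the retained set
  for (stricter in list(filter_config(min_depth = 1000),
                        filter_config(min_vaf = 0.05),
                        filter_config(max_population_af = 0.001))) {
    expect_true(all(
      variant_key(filter_variants(tab, stricter)) %in% variant_key(base)
    ))
  }
  # idempotence
  expect_equal(nrow(filter_variants(base, cfg)), nrow(base))
  # order-invariance: stage composition in any order gives the same set
  a <- population_germline_filter(depth_vaf_filter(tab, cfg), cfg)
  b <- depth_vaf_filter(population_germline_filter(tab, cfg), cfg)
  expect_setequal(variant_key(a), variant_key(b))
  expect_setequal(variant_key(a), variant_key(base))
})

test_that("generator truth survives the cascade: drivers kept, noise removed", {
  panel <- default_panel()
  for (s in 1:10) {
    truth <- simulation_truth(
      purity = 0.57,
      clones = clone(gene = c("ALK", "TP53", "PTPN11"),
                     clonal_fraction = c(1, 0.5, 0.1)),
      germline_snps = 50, artifact_rate = 0.1, seed = s
    )
    tab <- simulate_variant_table(truth, panel, mean_depth = 2228)
    kept <- filter_variants(tab)
    expect_equal(sum(kept$truth_class == "artifact"), 0)
    expect_equal(sum(kept$truth_class == "germline_snp"), 0)
    # expected VAFs 28.5%, 14.25%, 2.85% all well above the 0.5% floor
    expect_equal(sum(kept$truth_class == "somatic_driver"),
                 sum(tab$truth_class == "somatic_driver"))
  }
})
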