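test_that("identical call sets are fully shared", {
  a <- driver_row(pos = c(100L, 200L, 300L))
  res <- classify_concordance(a, a)
  expect_equal(unname(res$counts), c(3, 0, 0))
  expect_true(all(res$pairs$category == "shared"))
})

test_that("disjoint sets split into private categories; swap is symmetric", {
  a <- driver_row(pos = 1:4 * 10L)
  b <- driver_row(pos = 1:7 * 1000L, gene = "TP53")
  res <- classify_concordance(a, b)
  expect_equal(unname(res$counts), c(0, 4, 7))
  swapped <- classify_concordance(b, a)
  expect_equal(unname(swapped$counts), c(0, 7, 4))
  expect_equal(sum(res$counts), sum(swapped$counts))
})

test_that("concordance refuses samples from different patients", {
  a <- driver_row()
  b <- driver_row(sample_id = "S2")
  meta <- tibble::tibble(sample_id = c("S1", "S2"),
                         patient_id = c("P1", "P2"))
  expect_error(classify_concordance(a, b, metadata = meta), "one patient")
  meta$patient_id <- "P1"
  expect_silent(classify_concordance(a, b, metadata = meta))
})

test_that("diagnosis pair of the clonal-evolution scenario splits as designed", {
  sc <- scenario_clonal_evolution(seed = 2)
  drv <- sc$variants[sc$variants$truth_class == "somatic_driver", ]
  res <- classify_concordance(
    drv[drv$sample_id == "P1_diag_ctDNA", ],
    drv[drv$sample_id == "P1_diag_tumour", ]
  )
  expect_equal(unname(res$counts), c(1, 1, 0))
  expect_equal(res$pairs$category[res$pairs$key ==
                                    sc$expected$diagnosis_shared_key],
               "shared")
  expect_equal(res$pairs$category[res$pairs$key ==
                                    sc$expected$diagnosis_ctdna_only_key],
               "ctDNA_only")
})

test_that("trajectory labels presence transitions and VAF trends", {
  meta <- tibble::tibble(
    sample_id = c("d", "m", "r"), patient_id = "P1",
    timepoint = c("diagnosis", "remission", "relapse")
  )
  mk <- function(samples, vafs, pos = 100L) {
    driver_row(sample_id = samples, vaf = vafs, pos = pos)
  }
  # present, absent, absent -> lost
  lost <- vaf_trajectory(mk("d", 0.0285), meta)
  expect_equal(lost$label, "lost")
  # present, absent, present -> the treatment-response pattern
  lte <- vaf_trajectory(mk(c("d", "r"), c(0.285, 0.98)), meta)
  expect_equal(lte$label, "lost_then_emergent")
  expect_equal(unname(lte$series[[1]]), c(0.285, 0, 0.98))
  # constant series -> stable; monotone growth -> rising
  expect_equal(vaf_trajectory(mk(c("d", "m", "r"), c(0.3, 0.3, 0.3)),
                              meta)$label, "stable")
  expect_equal(vaf_trajectory(mk(c("d", "m", "r"), c(0.1, 0.2, 0.4)),
                              meta)$label, "rising")
  # absent then present -> emergent
  expect_equal(vaf_trajectory(mk("r", 0.4), meta)$label, "emergent")
  # a single timepoint cannot form a trajectory
  expect_error(vaf_trajectory(mk("d", 0.1), meta[1, ]), "two timepoints")
})

test_that("sub-threshold VAFs count as absent but keep their raw value", {
  meta <- tibble::tibble(sample_id = c("d", "r"), patient_id = "P1",
                         timepoint = c("diagnosis", "relapse"))
  tr <- vaf_trajectory(driver_row(sample_id = c("d", "r"),
                                  vaf = c(0.25, 0.004), pos = 100L), meta)
  expect_equal(tr$label, "lost")
  expect_equal(unname(tr$series[[1]]["relapse"]), 0.004)
})

test_that("purity model matches its closed forms and flags impossibilities", {
  expect_equal(purity_from_vaf(0.5, "het_diploid")$purity, 1.0)
  expect_equal(purity_from_vaf(0, "het_diploid")$purity, 0)
  expect_equal(purity_from_vaf(0, "hom_loh")$purity, 0)
  # homozygous-after-LOH at VAF 10.5% implies ~19% tumour content:
  # forward check - 19% hemizygous-mutant cells in 81% diploid gives
  # 0.19 / (0.19 + 2 * 0.81) = 0.1049
  est <- purity_from_vaf(0.105, "hom_loh")
  expect_equal(est$purity, 0.19, tolerance = 0.005)
  expect_equal(vaf_from_purity(0.19, "hom_loh"),
               0.19 / (0.19 + 2 * 0.81), tolerance = 1e-12)
  expect_error(purity_from_vaf(1, "het_diploid"), "impossible")
  # VAF larger than the state allows is clipped and flagged
  clip <- purity_from_vaf(0.8, "het_diploid")
  expect_true(clip$clipped)
  expect_equal(clip$purity, 1)
})

test_that("purity inverts the forward mixing map on a grid", {
  grid <- seq(0.05, 0.95, by = 0.05)
  for (state in c("het_diploid", "hom_loh")) {
    round_trip <- purity_from_vaf(vaf_from_purity(grid, state), state)
    expect_equal(round_trip$purity, grid, tolerance = 1e-9)
    expect_false(any(round_trip$clipped))
  }
})

test_that("scenario trajectory labels match generator truth across seeds", {
  for (s in 1:10) {
    sc <- scenario_clonal_evolution(seed = s)
    cl <- classify_variants(filter_variants(sc$variants))
    rep <- apply_reporting_threshold(cl)
    ct_meta <- sc$metadata[startsWith(sc$metadata$material, "ctDNA"), ]
    tr <- vaf_trajectory(rep[rep$sample_id %in% ct_meta$sample_id, ],
                         ct_meta)
    got <- setNames(tr$label, tr$key)
    want <- setNames(sc$expected$trajectory_labels$label,
                     sc$expected$trajectory_labels$key)
    expect_equal(got[names(want)], want)
  }
})
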