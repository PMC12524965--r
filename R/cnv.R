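#' Trimmed within-sample coverage baseline
#'
#' The baseline estimates the copy-neutral coverage level of one sample.
#' Targets of known-amplified genes and of X-chromosomal genes are
#' excluded outright, then the top and bottom `trim_fraction` of the
#' remaining target depths are symmetrically trimmed so that
#' over- and underrepresented targets (unknown amplifications, capture
#' dropouts) do not inflate the spread. The mean and standard deviation of
#' the survivors are the mu and sigma used for z-scores.
#'
#' @param coverages A coverage tibble (`sample_id`, `target_id`, `gene`,
#'   `chrom`, `start`, `end`, `umi_depth`) for a single sample.
#' @param known_amplified Genes excluded as known amplified (e.g. MYCN in
#'   an MNA sample).
#' @param chrx_genes Genes excluded as X-chromosomal; defaults to genes
#'   whose targets lie on chrX.
#' @param trim_fraction Fraction trimmed from each tail (default 0.05).
#' @return A `coverage_baseline` list: `mu`, `sigma`, `included_targets`,
#'   and `excluded` (target, reason).
#' @export
compute_baseline <- function(coverages, known_amplified = character(),
                             chrx_genes = NULL, trim_fraction = 0.05) {
  coverages <- as_tibble(coverages)
  if (length(unique(coverages$sample_id)) > 1) {
    abort("compute_baseline works on one sample at a time")
  }
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    abort("trim_fraction must lie in [0, 0.5)")
  }
  if (is.null(chrx_genes)) {
    chrx_genes <- unique(coverages$gene[coverages$chrom == "chrX"])
  }
  reason <- rep(NA_character_, nrow(coverages))
  reason[coverages$gene %in% chrx_genes] <- "chrX"
  reason[coverages$gene %in% known_amplified] <- "known_amplified"
  candidate <- which(is.na(reason))
  n_trim <- floor(length(candidate) * trim_fraction)
  if (n_trim > 0) {
    ord <- candidate[order(coverages$umi_depth[candidate])]
    trimmed <- c(head(ord, n_trim), utils::tail(ord, n_trim))
    reason[trimmed] <- "trimmed"
  }
  included <- which(is.na(reason))
  if (length(included) < 5) {
    abort(paste0(
      "only ", length(included),
      " targets survive baseline exclusion; need at least 5 - relax ",
      "exclusions or trim_fraction"
    ))
  }
  depths <- coverages$umi_depth[included]
  structure(
    list(
      mu = mean(depths),
      sigma = sd(depths),
      included_targets = coverages$target_id[included],
      excluded = tibble(
        target_id = coverages$target_id[!is.na(reason)],
        gene = coverages$gene[!is.na(reason)],
        reason = reason[!is.na(reason)]
      )
    ),
    class = "coverage_baseline"
  )
}

#' Per-target coverage z-scores
#'
#' `z = (x - mu) / sigma` for every target (including baseline-excluded
#' ones, which are scored against the same baseline). The sign-flipped
#' `inv_z` column is the presentation convention in which amplified
#' regions stand out as long positive bins.
#'
#' @param coverages A single-sample coverage tibble.
#' @param baseline A [compute_baseline()] result for the same sample.
#' @return The coverage tibble with `z`, `inv_z` and `in_baseline`
#'   columns.
#' @export
#' @examples
#' truth <- simulation_truth(purity = 0.3, amplified_genes = c(MYCN = 50))
#' cov <- simulate_coverage(truth, default_panel())
#' z <- z_scores(cov, compute_baseline(cov))
z_scores <- function(coverages, baseline) {
  stopifnot(inherits(baseline, "coverage_baseline"))
  coverages <- as_tibble(coverages)
  if (baseline$sigma == 0) {
    abort(paste0(
      "baseline standard deviation is 0; z-scores are undefined - ",
      "widen the baseline or add coverage noise"
    ))
  }
  coverages %>%
    mutate(
      z = (.data$umi_depth - baseline$mu) / baseline$sigma,
      inv_z = -.data$z,
      in_baseline = .data$target_id %in% baseline$included_targets
    )
}

#' Gene-level amplification calls from per-target z-scores
#'
#' Aggregates per-target z to a gene-level statistic by the median (robust
#' to single-target dropouts) and thresholds it: `amplified` when
#' `gene_z >= z_amp`, `gain` when `z_gain <= gene_z < z_amp`, otherwise
#' `neutral`. A gene amplified only outside the panel footprint produces
#' no coverage signal and is therefore never called — matching the known
#' blind spot of panel-based CNV detection for partial amplifications.
#'
#' @param z_tbl Output of [z_scores()].
#' @param z_amp,z_gain Amplification and gain thresholds on gene_z
#'   (`z_amp > z_gain > 0`).
#' @param panel Optional panel tibble; genes on the panel with no coverage
#'   rows are dropped with a warning.
#' @return A tibble of `cnv_call`s: `gene`, `gene_z`, `n_targets`,
#'   `status` plus a `per_target` list column of per-target z.
#' @export
call_amplifications <- function(z_tbl, z_amp = 5, z_gain = 2,
                                panel = NULL) {
  if (!(z_amp > z_gain && z_gain > 0)) {
    abort("thresholds must satisfy z_amp > z_gain > 0")
  }
  z_tbl <- as_tibble(z_tbl)
  if (!"z" %in% names(z_tbl)) abort("run z_scores() first")
  if (!is.null(panel)) {
    missing_genes <- setdiff(panel_genes(panel), unique(z_tbl$gene))
    if (length(missing_genes) > 0) {
      warn(paste0("panel gene(s) with no coverage targets excluded: ",
                  paste(missing_genes, collapse = ", ")))
    }
  }
  z_tbl %>%
    group_by(gene = .data$gene) %>%
    summarise(
      gene_z = median(.data$z),
      n_targets = n(),
      per_target = list(setNames(.data$z, .data$target_id)),
      .groups = "drop"
    ) %>%
    mutate(status = dplyr::case_when(
      .data$gene_z >= z_amp ~ "amplified",
      .data$gene_z >= z_gain ~ "gain",
      TRUE ~ "neutral"
    )) %>%
    select("gene", "gene_z", "n_targets", "status", "per_target") %>%
    arrange(dplyr::desc(.data$gene_z))
}

#' One-call CNV analysis of a single sample
#'
#' Convenience wrapper: baseline, z-scores, gene-level calls.
#'
#' @inheritParams compute_baseline
#' @inheritParams call_amplifications
#' @return A list with `baseline`, `z` and `calls`.
#' @export
detect_amplifications <- function(coverages, known_amplified = character(),
                                  chrx_genes = NULL, trim_fraction = 0.05,
                                  z_amp = 5, z_gain = 2) {
  baseline <- compute_baseline(coverages, known_amplified, chrx_genes,
                               trim_fraction)
  z <- z_scores(coverages, baseline)
  list(baseline = baseline, z = z,
       calls = call_amplifications(z, z_amp = z_amp, z_gain = z_gain))
}
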