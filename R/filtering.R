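#' Filtering thresholds for the somatic variant cascade
#'
#' Defaults follow stringent ctDNA panel practice: calls below 100x UMI
#' depth or 0.5% VAF are unreliable and removed; variants common in any
#' population (>= 1% MAF in dbSNP-common super-populations, or > 1% in
#' gnomAD exomes) are treated as germline; reporting is restricted to
#' driver-tier variants above 1% VAF; samples whose cfDNA fraction falls
#' below 20% fail QC.
#'
#' @param min_depth Minimum UMI depth to retain a call (keep `depth >=
#'   min_depth`).
#' @param min_vaf Minimum VAF to retain a call (keep `vaf >= min_vaf`).
#' @param max_population_af Population-frequency cut-off above which a
#'   variant is considered common germline.
#' @param reporting_vaf Strict lower bound for reportable driver variants
#'   (report `vaf > reporting_vaf`).
#' @param cfdna_fraction_threshold Minimum cfDNA fraction for sample QC.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 100, min_vaf = 0.005,
                          max_population_af = 0.01, reporting_vaf = 0.01,
                          cfdna_fraction_threshold = 0.20) {
  fracs <- c(min_vaf = min_vaf, max_population_af = max_population_af,
             reporting_vaf = reporting_vaf,
             cfdna_fraction_threshold = cfdna_fraction_threshold)
  if (any(fracs < 0 | fracs > 1)) {
    abort("fractional thresholds must lie in [0, 1]")
  }
  if (min_depth < 0) abort("min_depth must be >= 0")
  structure(
    list(min_depth = min_depth, min_vaf = min_vaf,
         max_population_af = max_population_af,
         reporting_vaf = reporting_vaf,
         cfdna_fraction_threshold = cfdna_fraction_threshold),
    class = "filter_config"
  )
}

#' Sample-level cfDNA quality control
#'
#' A plasma sample whose cfDNA fraction is below the threshold carries too
#' little analysable template and is excluded from all downstream stages.
#'
#' @param cfdna_fraction cfDNA fraction(s) of total DNA, in \[0, 1\].
#' @param cfg A [filter_config()].
#' @return `"pass"` or `"fail"` per sample.
#' @export
#' @examples
#' qc_sample(c(0.06, 0.20, 1.0))  # fail, pass, pass
qc_sample <- function(cfdna_fraction, cfg = filter_config()) {
  if (any(is.na(cfdna_fraction)) ||
      any(cfdna_fraction < 0 | cfdna_fraction > 1)) {
    abort("cfdna_fraction must lie in [0, 1]")
  }
  ifelse(cfdna_fraction < cfg$cfdna_fraction_threshold, "fail", "pass")
}

# Each stage removes rows only on positive evidence of a violation:
# a missing depth, VAF or population frequency never causes removal.
flag_depth_vaf <- function(variants, cfg) {
  low_depth <- !is.na(variants$depth) & variants$depth < cfg$min_depth
  low_vaf <- !is.na(variants$vaf) & variants$vaf < cfg$min_vaf
  art <- variants$artifact_flag %in% TRUE | variants$duplicate_flag %in% TRUE
  list(low_depth = low_depth, low_vaf = low_vaf, artifact = art)
}

flag_population <- function(variants, cfg) {
  (!is.na(variants$dbsnp_common_maf) &
     variants$dbsnp_common_maf >= cfg$max_population_af) |
    (!is.na(variants$gnomad_af) &
       variants$gnomad_af > cfg$max_population_af)
}

#' Depth / VAF / artifact filter
#'
#' Removes calls with UMI depth below `min_depth`, VAF below `min_vaf`, or
#' flagged upstream as recurrent artifacts or PCR duplicates. Missing
#' depth or VAF does not cause removal.
#'
#' @param variants A variant tibble.
#' @param cfg A [filter_config()].
#' @return The retained rows.
#' @export
depth_vaf_filter <- function(variants, cfg = filter_config()) {
  variants <- validate_variants(variants)
  f <- flag_depth_vaf(variants, cfg)
  variants[!(f$low_depth | f$low_vaf | f$artifact), , drop = FALSE]
}

#' Population germline filter
#'
#' Removes variants that are common in any population: dbSNP-common
#' maximum super-population MAF at or above the cut-off, or gnomAD exomes
#' frequency above it. Variants with no recorded population frequency are
#' retained — only demonstrably common variants are germline by this rule.
#'
#' @inheritParams depth_vaf_filter
#' @return The retained rows.
#' @export
population_germline_filter <- function(variants, cfg = filter_config()) {
  variants <- validate_variants(variants)
  variants[!flag_population(variants, cfg), , drop = FALSE]
}

#' Matched-germline subtraction
#'
#' Removes every call whose genomic key occurs in the patient's matched
#' germline call set (e.g. from 30x WGS of blood). With no germline set
#' supplied the input passes through unchanged, with a warning.
#'
#' @param variants A variant tibble (tumour or ctDNA calls).
#' @param germline A variant tibble of matched germline calls, or `NULL`.
#' @return The retained rows; the number removed is attached as attribute
#'   `n_germline_removed`.
#' @export
matched_germline_subtract <- function(variants, germline = NULL) {
  variants <- validate_variants(variants)
  if (is.null(germline) || nrow(germline) == 0) {
    if (is.null(germline)) {
      warn("no matched germline set supplied; skipping subtraction")
    }
    attr(variants, "n_germline_removed") <- 0L
    return(variants)
  }
  germline <- validate_variants(germline)
  hit <- variant_key(variants) %in% unique(variant_key(germline))
  out <- variants[!hit, , drop = FALSE]
  attr(out, "n_germline_removed") <- sum(hit)
  out
}

#' Run the full filtering cascade, annotating decisions
#'
#' Applies the depth/VAF/artifact, population-germline and (optionally)
#' matched-germline stages and records the outcome per row in a `filter`
#' column: `PASS`, or the semicolon-joined failure reasons among
#' `low_depth`, `low_vaf`, `artifact`, `pop_germline`, `matched_germline`.
#' Because every stage is a row-wise predicate, the retained set is the
#' same whatever order the stages run in, and re-filtering retained rows
#' changes nothing.
#'
#' @inheritParams depth_vaf_filter
#' @param germline Optional matched germline variant tibble.
#' @param keep_all If `TRUE`, return all rows with their `filter`
#'   annotation; if `FALSE` (default), return only `PASS` rows.
#' @return A variant tibble with a `filter` column.
#' @export
filter_variants <- function(variants, cfg = filter_config(),
                            germline = NULL, keep_all = FALSE) {
  variants <- validate_variants(variants)
  f <- flag_depth_vaf(variants, cfg)
  pop <- flag_population(variants, cfg)
  matched <- if (!is.null(germline) && nrow(germline) > 0) {
    variant_key(variants) %in% unique(variant_key(validate_variants(germline)))
  } else {
    rep(FALSE, nrow(variants))
  }
  reasons <- cbind(low_depth = f$low_depth, low_vaf = f$low_vaf,
                   artifact = f$artifact, pop_germline = pop,
                   matched_germline = matched)
  variants$filter <- apply(reasons, 1, function(r) {
    if (!any(r)) "PASS" else paste(colnames(reasons)[r], collapse = ";")
  })
  if (nrow(variants) == 0) variants$filter <- character(0)
  if (keep_all) variants else variants[variants$filter == "PASS", , drop = FALSE]
}

#' Reporting threshold for classified variants
#'
#' A variant is reportable when it is driver tier (pathogenic or likely
#' pathogenic) and its VAF strictly exceeds the reporting threshold
#' (default 1%).
#'
#' @param classified A variant tibble carrying a `tier` column (see
#'   [classify_variants()]).
#' @param cfg A [filter_config()].
#' @return The reportable rows.
#' @export
apply_reporting_threshold <- function(classified, cfg = filter_config()) {
  if (!"tier" %in% names(classified)) {
    abort("apply_reporting_threshold needs classified variants (tier column)")
  }
  keep <- classified$tier %in% c("pathogenic", "likely_pathogenic") &
    !is.na(classified$vaf) & classified$vaf > cfg$reporting_vaf
  classified[keep, , drop = FALSE]
}
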