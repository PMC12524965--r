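tier_levels <- c("benign", "VUS", "likely_pathogenic", "pathogenic")

#' Assign pathogenicity tiers from in-silico scores and COSMIC presence
#'
#' Deterministic rule set, applied in order per variant:
#'
#' 1. **pathogenic** — REVEL > 0.7 and catalogued in COSMIC;
#' 2. **likely_pathogenic** — COSMIC presence together with a deleterious
#'    SIFT call and a damaging PolyPhen-2 call, *or* a truncating
#'    consequence (frameshift, nonsense, splice donor) in a driver gene —
#'    this is the path for variants whose REVEL score is missing or whose
#'    scores do not apply (e.g. indels);
#' 3. **VUS** — some in-silico evidence of damage (deleterious SIFT,
#'    damaging PolyPhen-2, REVEL > 0.7, or a truncating consequence) but
#'    neither rule above met;
#' 4. **benign** — otherwise.
#'
#' "Damaging" PolyPhen-2 means a `PRD` or `POD` call (score >= 0.447 when
#' only a score is given); "deleterious" SIFT means the vendor call, or
#' score <= 0.05 when only a score is given. A *driver* variant is one in
#' tier pathogenic or likely_pathogenic.
#'
#' @param variants A variant tibble (see [variant_columns]).
#' @param driver_genes Gene set in which truncating variants count as
#'   likely pathogenic; defaults to the built-in 42-gene panel.
#' @return The input with columns `tier` (factor, ordered benign < VUS <
#'   likely_pathogenic < pathogenic), `evidence` (semicolon-joined fired
#'   rules) and `is_driver`.
#' @export
#' @examples
#' v <- variant_table(gene = "ALK", revel_score = 0.885,
#'                    cosmic_id = "COSV66555567", sift_score = 0,
#'                    sift_call = "deleterious", polyphen_call = "PRD")
#' classify_variants(v)$tier
classify_variants <- function(variants, driver_genes = NULL) {
  variants <- validate_variants(variants)
  if (is.null(driver_genes)) driver_genes <- panel_genes(default_panel())

  cosmic <- !is.na(variants$cosmic_id) & nzchar(variants$cosmic_id)
  revel_high <- !is.na(variants$revel_score) & variants$revel_score > 0.7
  sift_del <- ifelse(
    !is.na(variants$sift_call),
    tolower(variants$sift_call) %in% c("deleterious", "del"),
    !is.na(variants$sift_score) & variants$sift_score <= 0.05
  )
  polyphen_dam <- ifelse(
    !is.na(variants$polyphen_call),
    variants$polyphen_call %in% c("PRD", "POD"),
    !is.na(variants$polyphen_score) & variants$polyphen_score >= 0.447
  )
  truncating <- variants$consequence %in%
    c("frameshift", "nonsense", "splice_donor") &
    variants$gene %in% driver_genes

  tier <- dplyr::case_when(
    revel_high & cosmic ~ "pathogenic",
    (cosmic & sift_del & polyphen_dam) | truncating ~ "likely_pathogenic",
    sift_del | polyphen_dam | revel_high ~ "VUS",
    TRUE ~ "benign"
  )
  fired <- cbind(cosmic_present = cosmic, revel_gt_0.7 = revel_high,
                 sift_deleterious = sift_del,
                 polyphen_damaging = polyphen_dam,
                 truncating_in_driver_gene = truncating)
  variants$tier <- factor(tier, levels = tier_levels, ordered = TRUE)
  variants$evidence <- apply(fired, 1, function(r) {
    paste(colnames(fired)[r], collapse = ";")
  })
  if (nrow(variants) == 0) variants$evidence <- character(0)
  variants$is_driver <- variants$tier >= "likely_pathogenic"
  variants
}

#' Summarise driver variants per sample and per gene
#'
#' Produces the headline counts of a ctDNA panel study: how many distinct
#' ctDNA samples carry at least one driver variant, how many driver
#' variants those samples hold in total, and per-gene counts of variants
#' and of distinct samples (a sample contributes once per gene), split by
#' material.
#'
#' @param classified A classified variant tibble (see
#'   [classify_variants()]).
#' @param metadata Optional sample sheet with `sample_id` and `material`;
#'   when absent, a `material` column on the variants themselves is used.
#' @return A `driver_summary` list: `n_ctdna_samples_with_driver`,
#'   `n_ctdna_driver_variants`, `per_gene` (ctDNA-restricted and
#'   all-material counts), `per_sample`, `tier_counts`.
#' @export
summarize_drivers <- function(classified, metadata = NULL) {
  if (!"tier" %in% names(classified)) {
    abort("summarize_drivers needs classified variants (tier column)")
  }
  classified <- as_tibble(classified)
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    classified <- classified %>%
      select(-dplyr::any_of("material")) %>%
      left_join(metadata[c("sample_id", "material")], by = "sample_id")
  }
  if (!"material" %in% names(classified)) {
    abort("supply a material column or sample metadata")
  }
  if (any(is.na(classified$material))) {
    abort("every variant must map to a sample with a material label")
  }
  drivers <- classified[classified$tier %in%
                          c("pathogenic", "likely_pathogenic"), ,
                        drop = FALSE]
  ct <- drivers[is_ctdna_material(drivers$material), , drop = FALSE]

  per_gene_all <- drivers %>%
    group_by(gene = .data$gene) %>%
    summarise(n_samples = n_distinct(.data$sample_id),
              n_variants = n(), .groups = "drop")
  per_gene_ct <- ct %>%
    group_by(gene = .data$gene) %>%
    summarise(n_ctdna_samples = n_distinct(.data$sample_id),
              n_ctdna_variants = n(), .groups = "drop")
  per_gene <- dplyr::full_join(per_gene_all, per_gene_ct, by = "gene") %>%
    mutate(
      n_ctdna_samples = tidyr::replace_na(.data$n_ctdna_samples, 0L),
      n_ctdna_variants = tidyr::replace_na(.data$n_ctdna_variants, 0L)
    ) %>%
    arrange(dplyr::desc(.data$n_samples), .data$gene)

  per_sample <- classified %>%
    group_by(sample_id = .data$sample_id, material = .data$material) %>%
    summarise(
      n_variants = n(),
      n_drivers = sum(.data$tier %in% c("pathogenic", "likely_pathogenic")),
      .groups = "drop"
    )
  tier_counts <- table(factor(as.character(classified$tier),
                              levels = tier_levels))

  structure(
    list(
      n_ctdna_samples_with_driver = n_distinct(ct$sample_id),
      n_ctdna_driver_variants = nrow(ct),
      per_gene = per_gene,
      per_sample = per_sample,
      tier_counts = tier_counts
    ),
    class = "driver_summary"
  )
}

#' @export
print.driver_summary <- function(x, ...) {
  cat("Driver summary\n")
  cat("  ctDNA samples with >=1 driver:", x$n_ctdna_samples_with_driver,
      "\n")
  cat("  ctDNA driver variants:        ", x$n_ctdna_driver_variants, "\n")
  cat("  tiers:",
      paste(names(x$tier_counts), as.integer(x$tier_counts),
            sep = "=", collapse = ", "), "\n")
  cat("  top genes:\n")
  print(head(x$per_gene, 8), n = 8)
  invisible(x)
}
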