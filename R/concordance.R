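#' Cross-compartment concordance of variant calls
#'
#' Categorises the union of two driver call sets — typically ctDNA versus
#' matched tumour for the same patient — by genomic key into `shared`,
#' `ctDNA_only` and `tumour_only`. When sample metadata is supplied, all
#' samples on both sides must belong to one patient; comparing
#' compartments across patients is an error, not a silent mismatch.
#'
#' @param ctdna,tumour Variant tibbles (restrict to driver tier first for
#'   the usual analysis).
#' @param metadata Optional sample sheet with `sample_id` and
#'   `patient_id` used to enforce the single-patient precondition.
#' @return A list with `pairs` (key, per-side VAF, category) and `counts`
#'   (named vector: shared, ctDNA_only, tumour_only).
#' @export
#' @examples
#' sc <- scenario_clonal_evolution(seed = 1)
#' diag <- sc$variants[sc$variants$truth_class == "somatic_driver", ]
#' classify_concordance(diag[diag$sample_id == "P1_diag_ctDNA", ],
#'                      diag[diag$sample_id == "P1_diag_tumour", ])$counts
classify_concordance <- function(ctdna, tumour, metadata = NULL) {
  ctdna <- validate_variants(ctdna)
  tumour <- validate_variants(tumour)
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    ids <- unique(c(ctdna$sample_id, tumour$sample_id))
    pts <- unique(metadata$patient_id[metadata$sample_id %in% ids])
    if (length(setdiff(ids, metadata$sample_id)) > 0) {
      abort("samples missing from metadata")
    }
    if (length(pts) != 1) {
      abort(paste0("concordance pairs require samples of one patient; got: ",
                   paste(pts, collapse = ", ")))
    }
  }
  ct_keys <- unique(variant_key(ctdna))
  tu_keys <- unique(variant_key(tumour))
  all_keys <- union(ct_keys, tu_keys)
  ct_vaf <- setNames(ctdna$vaf, variant_key(ctdna))
  tu_vaf <- setNames(tumour$vaf, variant_key(tumour))
  pairs <- tibble(
    key = all_keys,
    vaf_ctdna = unname(ct_vaf[all_keys]),
    vaf_tumour = unname(tu_vaf[all_keys]),
    category = dplyr::case_when(
      all_keys %in% ct_keys & all_keys %in% tu_keys ~ "shared",
      all_keys %in% ct_keys ~ "ctDNA_only",
      TRUE ~ "tumour_only"
    )
  )
  counts <- c(
    shared = sum(pairs$category == "shared"),
    ctDNA_only = sum(pairs$category == "ctDNA_only"),
    tumour_only = sum(pairs$category == "tumour_only")
  )
  list(pairs = pairs, counts = counts)
}

timepoint_levels <- c("diagnosis", "post_chemo", "remission", "relapse")

label_trajectory <- function(present, vafs, rel_tol) {
  present <- unname(present)
  vafs <- unname(vafs)
  runs <- rle(present)
  pattern <- runs$values
  if (all(present)) {
    v0 <- vafs[1]
    vn <- vafs[length(vafs)]
    dirs <- sign(diff(vafs))
    monotone_up <- all(dirs >= 0)
    monotone_down <- all(dirs <= 0)
    if (monotone_up && vn > v0 * (1 + rel_tol)) return("rising")
    if (monotone_down && vn < v0 * (1 - rel_tol)) return("falling")
    return("stable")
  }
  if (identical(pattern, c(TRUE, FALSE))) return("lost")
  if (identical(pattern, c(FALSE, TRUE))) return("emergent")
  if (identical(pattern, c(TRUE, FALSE, TRUE))) return("lost_then_emergent")
  if (identical(pattern, c(FALSE, TRUE, FALSE))) return("emergent_then_lost")
  if (all(!present)) return("absent")
  "complex"
}

#' Longitudinal VAF trajectories with clonal-event labels
#'
#' Tracks each variant key across a patient's samples ordered by
#' timepoint (diagnosis, post-chemotherapy, remission, relapse) and labels
#' the presence/VAF pattern: `lost`, `emergent`, `lost_then_emergent`
#' (the treatment-response pattern of a clone cleared at remission and
#' fixed at relapse), `emergent_then_lost`, `rising`, `falling`, `stable`,
#' or `complex`. A variant below the reporting threshold counts as absent
#' for labelling, but its raw VAF is retained in the series for
#' inspection.
#'
#' @param variants Variant tibble covering one patient's samples.
#' @param metadata Sample sheet with `sample_id` and `timepoint`; at
#'   least two distinct timepoints are required.
#' @param reporting_vaf Detection threshold below which a variant is
#'   treated as absent (default 0.01).
#' @param rel_tol Relative VAF change below which an always-present
#'   variant is `stable`.
#' @return A tibble: `key`, `gene`, `label`, and a `series` list column
#'   of per-timepoint VAFs (absent coded 0).
#' @export
vaf_trajectory <- function(variants, metadata, reporting_vaf = 0.01,
                           rel_tol = 0.2) {
  variants <- validate_variants(variants)
  # every metadata row defines a timepoint, including samples with zero
  # calls (absence at a sampled timepoint is evidence, e.g. remission)
  meta <- as_tibble(metadata)
  if (!all(meta$timepoint %in% timepoint_levels)) {
    abort(paste0("timepoint must be one of: ",
                 paste(timepoint_levels, collapse = ", ")))
  }
  tps <- intersect(timepoint_levels, unique(meta$timepoint))
  if (length(tps) < 2) {
    abort("trajectories need samples from at least two timepoints")
  }
  variants$key <- variant_key(variants)
  variants <- left_join(variants, meta[c("sample_id", "timepoint")],
                        by = "sample_id")
  purrr::map_dfr(unique(variants$key), function(k) {
    rows <- variants[variants$key == k, ]
    vafs <- vapply(tps, function(tp) {
      v <- rows$vaf[rows$timepoint == tp]
      if (length(v) == 0) 0 else max(v)
    }, numeric(1))
    present <- vafs > reporting_vaf
    tibble(
      key = k,
      gene = rows$gene[1],
      protein_change = rows$protein_change[1],
      label = label_trajectory(present, vafs, rel_tol),
      series = list(setNames(vafs, tps))
    )
  })
}

#' Forward mixing model: expected VAF at a given tumour purity
#'
#' `het_diploid`: tumour cells are diploid and heterozygous, normal cells
#' contribute reference only, so `vaf = p / 2`. `hom_loh`: tumour cells
#' have lost the wild-type allele (copy number 1, 100% mutant, e.g. a
#' TP53 mutation rendered homozygous by 17p loss) mixed with diploid
#' normal cells, so `vaf = p / (2 - p)`.
#'
#' @param purity Tumour cell fraction(s) in \[0, 1\].
#' @param copy_state `"het_diploid"` or `"hom_loh"` (recycled).
#' @return Expected VAF(s).
#' @export
vaf_from_purity <- function(purity,
                            copy_state = c("het_diploid", "hom_loh")) {
  if (any(purity < 0 | purity > 1)) abort("purity must lie in [0, 1]")
  n <- max(length(purity), length(copy_state))
  purity <- rep_len(purity, n)
  copy_state <- rep_len(match.arg(copy_state, several.ok = TRUE), n)
  bad <- !copy_state %in% c("het_diploid", "hom_loh")
  if (any(bad)) abort("copy_state must be 'het_diploid' or 'hom_loh'")
  ifelse(copy_state == "het_diploid", purity / 2, purity / (2 - purity))
}

#' Tumour purity from a somatic VAF
#'
#' Inverts the forward mixing model of [vaf_from_purity()]:
#' `het_diploid` gives `purity = 2 vaf`; `hom_loh` gives
#' `purity = 2 vaf / (1 + vaf)`. Values that invert above 1 (VAF larger
#' than any purity can explain under the assumed state) are clipped to 1
#' and flagged.
#'
#' @param vaf Observed VAF(s) in \[0, 1); a VAF of 1 under `het_diploid`
#'   is impossible at any purity and raises an error.
#' @param copy_state `"het_diploid"` or `"hom_loh"` (recycled).
#' @return A tibble: `vaf`, `copy_state`, `purity`, `clipped`.
#' @export
#' @examples
#' purity_from_vaf(0.105, "hom_loh")  # ~ 0.19
purity_from_vaf <- function(vaf, copy_state = c("het_diploid", "hom_loh")) {
  if (any(is.na(vaf)) || any(vaf < 0 | vaf > 1)) {
    abort("vaf must lie in [0, 1]")
  }
  n <- max(length(vaf), length(copy_state))
  vaf <- rep_len(vaf, n)
  copy_state <- rep_len(match.arg(copy_state, several.ok = TRUE), n)
  if (any(copy_state == "het_diploid" & vaf == 1)) {
    abort(paste0(
      "VAF of 1 is impossible for a heterozygous diploid tumour at any ",
      "purity; use copy_state = 'hom_loh' if the wild-type allele is lost"
    ))
  }
  raw <- ifelse(copy_state == "het_diploid", 2 * vaf,
                2 * vaf / (1 + vaf))
  tibble(
    vaf = vaf, copy_state = copy_state,
    purity = pmin(raw, 1), clipped = raw > 1
  )
}
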