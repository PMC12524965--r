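#' Columns of an annotated variant table
#'
#' A variant table is a tibble with one row per called variant per sample.
#' Scores that were not reported by the annotator are `NA`, never 0-coded.
#'
#' @format Character vector of required column names:
#' \describe{
#'   \item{sample_id}{sample the call was made in}
#'   \item{gene}{gene symbol}
#'   \item{chrom, pos, ref, alt}{genomic key; `pos` is 1-based (VCF
#'     convention); may be `NA` for published tables that only print the
#'     HGVS change, in which case `gene` + `base_change` identify the
#'     variant}
#'   \item{vaf}{variant allele frequency, fraction of UMI families
#'     supporting the alternate allele, in \[0, 1\]}
#'   \item{depth}{UMI read depth at the locus}
#'   \item{base_change, protein_change}{HGVS c. and p. strings}
#'   \item{consequence}{one of `missense`, `frameshift`, `splice_donor`,
#'     `nonsense`, `other`}
#'   \item{sift_score, sift_call}{SIFT score (0 = deleterious) and call
#'     (`deleterious`/`tolerated`)}
#'   \item{polyphen_score, polyphen_call}{PolyPhen-2 score (1 = damaging)
#'     and call (`PRD`/`POD`/`B`)}
#'   \item{revel_score}{REVEL ensemble score in \[0, 1\]}
#'   \item{cosmic_id}{COSMIC identifier, `NA` when the variant is not
#'     catalogued}
#'   \item{gnomad_af}{gnomAD exomes allele frequency}
#'   \item{dbsnp_common_maf}{maximum minor allele frequency across the five
#'     super-populations (AFR, AMR, EAS, EUR, SAS) in dbSNP-common}
#'   \item{artifact_flag, duplicate_flag}{upstream caller flags for
#'     recurrent artifacts and PCR duplicates}
#' }
#' @export
variant_columns <- c(
  "sample_id", "gene", "chrom", "pos", "ref", "alt", "vaf", "depth",
  "base_change", "protein_change", "consequence",
  "sift_score", "sift_call", "polyphen_score", "polyphen_call",
  "revel_score", "cosmic_id", "gnomad_af", "dbsnp_common_maf",
  "artifact_flag", "duplicate_flag"
)

consequence_levels <- c("missense", "frameshift", "splice_donor",
                        "nonsense", "other")

#' Build a variant table with the full column set
#'
#' Fills unspecified columns with `NA` of the right type and validates the
#' result. Intended for constructing small tables in analyses and tests;
#' file input goes through [read_variants()].
#'
#' @param ... Vectors for any subset of [variant_columns], recycled to a
#'   common length.
#' @return A validated variant tibble.
#' @export
variant_table <- function(...) {
  given <- tibble(...)
  bad <- setdiff(names(given), variant_columns)
  if (length(bad) > 0) {
    abort(paste0("unknown variant column(s): ", paste(bad, collapse = ", ")))
  }
  n <- nrow(given)
  defaults <- list(
    sample_id = NA_character_, gene = NA_character_, chrom = NA_character_,
    pos = NA_integer_, ref = NA_character_, alt = NA_character_,
    vaf = NA_real_, depth = NA_real_,
    base_change = NA_character_, protein_change = NA_character_,
    consequence = "other",
    sift_score = NA_real_, sift_call = NA_character_,
    polyphen_score = NA_real_, polyphen_call = NA_character_,
    revel_score = NA_real_, cosmic_id = NA_character_,
    gnomad_af = NA_real_, dbsnp_common_maf = NA_real_,
    artifact_flag = FALSE, duplicate_flag = FALSE
  )
  for (col in variant_columns) {
    if (!col %in% names(given)) {
      given[[col]] <- rep(defaults[[col]], length.out = n)
    }
  }
  validate_variants(given[variant_columns])
}

#' Validate a variant table
#'
#' Checks the column contract and the row invariants: `vaf` in \[0, 1\],
#' `depth` non-negative, known consequence terms, and an unambiguous
#' genomic key per sample.
#'
#' @param variants A variant tibble.
#' @return The input, invisibly coerced to a tibble, if valid.
#' @export
validate_variants <- function(variants) {
  variants <- as_tibble(variants)
  missing_cols <- setdiff(variant_columns, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0("variant table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_vaf <- which(!is.na(variants$vaf) &
                     (variants$vaf < 0 | variants$vaf > 1))
  if (length(bad_vaf) > 0) {
    abort(paste0("vaf outside [0, 1] at row(s): ",
                 paste(head(bad_vaf, 5), collapse = ", ")))
  }
  bad_depth <- which(!is.na(variants$depth) & variants$depth < 0)
  if (length(bad_depth) > 0) {
    abort(paste0("negative depth at row(s): ",
                 paste(head(bad_depth, 5), collapse = ", ")))
  }
  bad_csq <- which(!variants$consequence %in% consequence_levels)
  if (length(bad_csq) > 0) {
    abort(paste0(
      "unknown consequence '", variants$consequence[bad_csq[1]],
      "' at row ", bad_csq[1], "; expected one of: ",
      paste(consequence_levels, collapse = ", ")
    ))
  }
  variants
}

#' Genomic key of each variant
#'
#' `chrom:pos:ref:alt` when coordinates are available, otherwise
#' `gene:base_change` (the key used for published tables that print only
#' the HGVS change). Used for matched-germline subtraction, concordance
#' matching and trajectory tracking.
#'
#' @param variants A variant tibble.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(variants) {
  ifelse(
    !is.na(variants$pos),
    paste(variants$chrom, variants$pos, variants$ref, variants$alt,
          sep = ":"),
    paste(variants$gene, variants$base_change, sep = ":")
  )
}

# ctDNA materials share the "ctDNA" prefix (blood or bone-marrow plasma)
is_ctdna_material <- function(material) {
  startsWith(as.character(material), "ctDNA")
}
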