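# INFO keys of the package's VCF dialect, in write order
vcf_info_keys <- c(
  SAMPLE = "String", GENE = "String", VAF = "Float", DP = "Integer",
  BASE_CHANGE = "String", PROTEIN_CHANGE = "String", CSQ_CLASS = "String",
  SIFT = "Float", SIFT_CALL = "String", POLYPHEN = "Float",
  POLYPHEN_CALL = "String", REVEL = "Float", COSMIC_ID = "String",
  GNOMAD_AF = "Float", DBSNP_MAF = "Float"
)

#' Read annotated variants from VCF or a published-table TSV
#'
#' Two dialects are supported. `"vcf"` reads a VCF 4.2 whose INFO field
#' carries the annotations this pipeline consumes (keys `SAMPLE`, `GENE`,
#' `VAF`, `DP`, `BASE_CHANGE`, `PROTEIN_CHANGE`, `CSQ_CLASS`, `SIFT`,
#' `SIFT_CALL`, `POLYPHEN`, `POLYPHEN_CALL`, `REVEL`, `COSMIC_ID`,
#' `GNOMAD_AF`, `DBSNP_MAF`, plus flags `ARTIFACT` and `DUPLICATE`);
#' positions stay 1-based as in the file. `"table1_tsv"` reads the
#' transcription layout of a published driver-variant table (percent
#' VAFs, vendor-style score calls, a `material` column, no genomic
#' coordinates); see `inst/extdata/table1.tsv`.
#'
#' @param path File path.
#' @param dialect `"vcf"` or `"table1_tsv"`.
#' @return A validated variant tibble; the TSV dialect adds a `material`
#'   column.
#' @export
read_variants <- function(path, dialect = c("vcf", "table1_tsv")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         vcf = read_variants_vcf(path),
         table1_tsv = read_variants_table1(path))
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix  # full fixed region including INFO
  if (is.null(fix) || nrow(fix) == 0) {
    return(variant_table())
  }
  info_chr <- function(key) as.character(vcfR::extract.info(vcf, key))
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, key)))
  }
  info_flag <- function(key) {
    grepl(paste0("(^|;)", key, "(;|$)"), fix[, "INFO"])
  }
  out <- tibble(
    sample_id = info_chr("SAMPLE"),
    gene = info_chr("GENE"),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    vaf = info_num("VAF"),
    depth = info_num("DP"),
    base_change = info_chr("BASE_CHANGE"),
    protein_change = info_chr("PROTEIN_CHANGE"),
    consequence = info_chr("CSQ_CLASS"),
    sift_score = info_num("SIFT"),
    sift_call = info_chr("SIFT_CALL"),
    polyphen_score = info_num("POLYPHEN"),
    polyphen_call = info_chr("POLYPHEN_CALL"),
    revel_score = info_num("REVEL"),
    cosmic_id = info_chr("COSMIC_ID"),
    gnomad_af = info_num("GNOMAD_AF"),
    dbsnp_common_maf = info_num("DBSNP_MAF"),
    artifact_flag = info_flag("ARTIFACT"),
    duplicate_flag = info_flag("DUPLICATE")
  )
  out$consequence[is.na(out$consequence)] <- "other"
  validate_variants(out)
}

fmt_info_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         formatC(x, digits = 10, format = "g"))
}

#' Write a variant table as VCF 4.2
#'
#' Writes the package's VCF dialect (see [read_variants()]); the output
#' is bgzip-compatible gzip text (name it `.vcf.gz`). Every row needs
#' genomic coordinates — tables keyed only by HGVS strings (the published
#' table dialect) cannot be written as VCF.
#'
#' @param variants A variant tibble.
#' @param path Output path (conventionally ending in `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  variants <- validate_variants(variants)
  if (any(is.na(variants$pos) | is.na(variants$ref) |
            is.na(variants$alt) | is.na(variants$chrom))) {
    abort("VCF output requires chrom, pos, ref and alt on every row")
  }
  info_defs <- vapply(names(vcf_info_keys), function(k) {
    sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
            k, vcf_info_keys[[k]], k)
  }, character(1))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=liquidpanel",
    info_defs,
    '##INFO=<ID=ARTIFACT,Number=0,Type=Flag,Description="Recurrent artifact">',
    '##INFO=<ID=DUPLICATE,Number=0,Type=Flag,Description="PCR duplicate">'
  )
  vals <- list(
    SAMPLE = variants$sample_id, GENE = variants$gene,
    VAF = fmt_info_num(variants$vaf), DP = fmt_info_num(variants$depth),
    BASE_CHANGE = variants$base_change,
    PROTEIN_CHANGE = variants$protein_change,
    CSQ_CLASS = variants$consequence,
    SIFT = fmt_info_num(variants$sift_score),
    SIFT_CALL = variants$sift_call,
    POLYPHEN = fmt_info_num(variants$polyphen_score),
    POLYPHEN_CALL = variants$polyphen_call,
    REVEL = fmt_info_num(variants$revel_score),
    COSMIC_ID = variants$cosmic_id,
    GNOMAD_AF = fmt_info_num(variants$gnomad_af),
    DBSNP_MAF = fmt_info_num(variants$dbsnp_common_maf)
  )
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- purrr::imap_chr(vals, function(v, k) {
      if (is.na(v[i])) NA_character_ else paste0(k, "=", v[i])
    })
    parts <- parts[!is.na(parts)]
    if (isTRUE(variants$artifact_flag[i])) parts <- c(parts, "ARTIFACT")
    if (isTRUE(variants$duplicate_flag[i])) parts <- c(parts, "DUPLICATE")
    paste(parts, collapse = ";")
  }, character(1))
  filt <- if ("filter" %in% names(variants)) variants$filter else "."
  fix <- cbind(
    CHROM = variants$chrom, POS = as.character(variants$pos), ID = ".",
    REF = variants$ref, ALT = variants$alt, QUAL = ".",
    FILTER = as.character(filt), INFO = info
  )
  vcf <- methods::new(methods::className("vcfR", "vcfR"),
                      meta = meta, fix = fix,
                      gt = matrix(character(0), nrow = 0, ncol = 0))
  vcfR::write.vcf(vcf, path)
  invisible(path)
}

#' The bundled published driver-variant table
#'
#' A machine-readable transcription of the printed table of driver
#' variants detected in 32 neuroblastoma ctDNA samples, 3 germline DNA
#' samples and 2 control cell lines: 22 records (15 ctDNA, 2 germline, 5
#' cell line) with percent VAFs, SIFT/PolyPhen-2 calls and scores, REVEL
#' scores and COSMIC IDs. Values are transcribed verbatim, including the
#' printed discrepancy between the ctD11/gD1 protein changes (H179G vs
#' H179Q) and their distinct COSMIC accessions.
#'
#' @return A variant tibble with a `material` column.
#' @export
#' @examples
#' t1 <- table1_fixture()
#' nrow(t1)  # 22
table1_fixture <- function() {
  read_variants(
    system.file("extdata", "table1.tsv", package = "liquidpanel",
                mustWork = TRUE),
    dialect = "table1_tsv"
  )
}

read_variants_table1 <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(),
      material = readr::col_character(),
      vaf_pct = readr::col_double(),
      gene = readr::col_character(),
      chrom = readr::col_character(),
      arm = readr::col_character(),
      base_change = readr::col_character(),
      protein_change = readr::col_character(),
      consequence = readr::col_character(),
      cosmic_id = readr::col_character(),
      sift_call = readr::col_character(),
      sift_score = readr::col_double(),
      polyphen_call = readr::col_character(),
      polyphen_score = readr::col_double(),
      revel_score = readr::col_double()
    ),
    na = c("", "NA", "N/A"),
    progress = FALSE
  )
  out <- tibble(
    sample_id = df$sample,
    gene = df$gene,
    chrom = df$chrom,
    pos = NA_integer_, ref = NA_character_, alt = NA_character_,
    vaf = df$vaf_pct / 100,
    depth = NA_real_,
    base_change = df$base_change,
    protein_change = df$protein_change,
    consequence = df$consequence,
    sift_score = df$sift_score,
    sift_call = ifelse(df$sift_call %in% "Del", "deleterious",
                       df$sift_call),
    polyphen_score = df$polyphen_score,
    polyphen_call = df$polyphen_call,
    revel_score = df$revel_score,
    cosmic_id = df$cosmic_id,
    gnomad_af = NA_real_, dbsnp_common_maf = NA_real_,
    artifact_flag = FALSE, duplicate_flag = FALSE,
    material = df$material
  )
  validate_variants(out)
}

#' Read / write per-target coverage tables
#'
#' Tab-separated with header: `sample_id`, `target_id`, `gene`, `chrom`,
#' `start`, `end`, `umi_depth`.
#'
#' @param path File path.
#' @return `read_coverage()` returns a coverage tibble.
#' @export
read_coverage <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      target_id = readr::col_character(),
      gene = readr::col_character(),
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      umi_depth = readr::col_double()
    ),
    progress = FALSE
  )
}

#' @rdname read_coverage
#' @param coverages A coverage tibble.
#' @export
write_coverage <- function(coverages, path) {
  readr::write_tsv(coverages, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata sheet
#'
#' Tab-separated with header; requires `sample_id`, and uses when present
#' `patient_id`, `material`, `timepoint`, `risk_group`, `assay`,
#' `cfdna_fraction`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) {
    abort("metadata needs a sample_id column")
  }
  df
}
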