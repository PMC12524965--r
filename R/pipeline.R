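#' Configuration for an end-to-end pipeline run
#'
#' Inputs may be in-memory tibbles or file paths (character scalars);
#' paths are loaded with the package readers. Only `variants` is
#' mandatory — the report tolerates samples with variants but no
#' coverage and vice versa.
#'
#' @param variants Variant tibble, VCF path, or published-table TSV path
#'   (dialect chosen by `variant_dialect`).
#' @param coverage Optional coverage tibble or TSV path (may hold many
#'   samples).
#' @param panel Optional panel tibble or BED path; defaults to
#'   [default_panel()].
#' @param metadata Optional sample sheet (tibble or TSV path).
#' @param germline Optional matched-germline variant tibble or VCF path.
#' @param variant_dialect Dialect for a `variants` path.
#' @param filter A [filter_config()].
#' @param driver_genes Driver gene set for classification; defaults to
#'   the panel's genes.
#' @param known_amplified Genes excluded from the coverage baseline.
#' @param trim_fraction Baseline trim fraction.
#' @param z_amp,z_gain CNV call thresholds.
#' @param seed Integer seed recorded in provenance.
#' @param out_dir Optional directory for intermediate and report files.
#' @return A `run_config` list.
#' @export
run_config <- function(variants, coverage = NULL, panel = NULL,
                       metadata = NULL, germline = NULL,
                       variant_dialect = c("vcf", "table1_tsv"),
                       filter = filter_config(), driver_genes = NULL,
                       known_amplified = character(),
                       trim_fraction = 0.05, z_amp = 5, z_gain = 2,
                       seed = 1L, out_dir = NULL) {
  variant_dialect <- match.arg(variant_dialect)
  for (nm in c("variants", "coverage", "metadata", "germline")) {
    x <- get(nm)
    if (is.character(x) && length(x) == 1 && !file.exists(x)) {
      abort(paste0(nm, " path does not exist: ", x))
    }
  }
  structure(
    list(variants = variants, coverage = coverage, panel = panel,
         metadata = metadata, germline = germline,
         variant_dialect = variant_dialect, filter = filter,
         driver_genes = driver_genes, known_amplified = known_amplified,
         trim_fraction = trim_fraction, z_amp = z_amp, z_gain = z_gain,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

load_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1) loader(x) else x
}

#' Run the full analysis pipeline
#'
#' Executes QC, the filtering cascade, classification, the reporting
#' threshold, driver summarisation, per-sample CNV calling, and — where
#' the metadata links ctDNA and tumour samples of one patient —
#' concordance and longitudinal trajectories. All stages are
#' deterministic; rerunning a config reproduces the report byte for
#' byte. With `out_dir` set, intermediates (filtered and classified
#' TSVs) and JSON reports are written there.
#'
#' @param cfg A [run_config()].
#' @return A `report_bundle` list: `qc`, `filtered`, `classified`,
#'   `reportable`, `driver_summary`, `cnv_calls`, `concordance`,
#'   `trajectories`, `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  variants <- load_input(cfg$variants, function(p) {
    read_variants(p, dialect = cfg$variant_dialect)
  })
  coverage <- load_input(cfg$coverage, read_coverage)
  metadata <- load_input(cfg$metadata, read_sample_metadata)
  germline <- load_input(cfg$germline, read_variants)
  panel <- cfg$panel %||% default_panel()
  if (is.character(panel)) panel <- read_panel_bed(panel)
  driver_genes <- cfg$driver_genes %||% panel_genes(panel)

  # stage 1: sample QC on cfDNA fraction, where known
  qc <- NULL
  if (!is.null(metadata) && "cfdna_fraction" %in% names(metadata)) {
    qc <- tibble(
      sample_id = metadata$sample_id,
      cfdna_fraction = metadata$cfdna_fraction,
      qc = qc_sample(metadata$cfdna_fraction, cfg$filter)
    )
    failed <- qc$sample_id[qc$qc == "fail"]
    variants <- variants[!variants$sample_id %in% failed, , drop = FALSE]
    if (!is.null(coverage)) {
      coverage <- coverage[!coverage$sample_id %in% failed, , drop = FALSE]
    }
  }

  # stage 2-3: filtering cascade, classification, reporting threshold
  filtered <- filter_variants(variants, cfg$filter, germline = germline,
                              keep_all = TRUE)
  retained <- filtered[filtered$filter == "PASS", , drop = FALSE]
  classified <- classify_variants(retained, driver_genes = driver_genes)
  reportable <- apply_reporting_threshold(classified, cfg$filter)
  meta_for_summary <- if (!is.null(metadata) &&
                            "material" %in% names(metadata)) metadata
  if (is.null(meta_for_summary) && !"material" %in% names(classified)) {
    # no sample sheet: assume plasma ctDNA, the tool's primary material
    warn("no material labels supplied; assuming all samples are ctDNA")
    classified$material <- "ctDNA_blood"
  }
  summary <- summarize_drivers(classified, metadata = meta_for_summary)

  # stage 4: per-sample CNV calls from coverage, where available
  cnv_calls <- NULL
  if (!is.null(coverage) && nrow(coverage) > 0) {
    cnv_calls <- purrr::map_dfr(unique(coverage$sample_id), function(s) {
      res <- detect_amplifications(
        coverage[coverage$sample_id == s, , drop = FALSE],
        known_amplified = cfg$known_amplified,
        trim_fraction = cfg$trim_fraction,
        z_amp = cfg$z_amp, z_gain = cfg$z_gain
      )
      mutate(res$calls, sample_id = s, .before = 1)
    })
  }

  # stage 5: concordance and trajectories for linked samples
  concordance <- NULL
  trajectories <- NULL
  if (!is.null(metadata) && all(c("patient_id", "material", "timepoint")
                                %in% names(metadata))) {
    rep_meta <- metadata[metadata$sample_id %in%
                           unique(c(reportable$sample_id,
                                    metadata$sample_id)), ]
    concordance <- purrr::map_dfr(unique(rep_meta$patient_id), function(p) {
      pm <- rep_meta[rep_meta$patient_id == p, ]
      purrr::map_dfr(intersect(timepoint_levels, unique(pm$timepoint)),
                     function(tp) {
        ids_ct <- pm$sample_id[pm$timepoint == tp &
                                 is_ctdna_material(pm$material)]
        ids_tu <- pm$sample_id[pm$timepoint == tp & pm$material == "tumour"]
        if (length(ids_ct) == 0 || length(ids_tu) == 0) return(NULL)
        res <- classify_concordance(
          reportable[reportable$sample_id %in% ids_ct, , drop = FALSE],
          reportable[reportable$sample_id %in% ids_tu, , drop = FALSE],
          metadata = pm
        )
        mutate(res$pairs, patient_id = p, timepoint = tp, .before = 1)
      })
    })
    trajectories <- purrr::map_dfr(unique(rep_meta$patient_id), function(p) {
      pm <- rep_meta[rep_meta$patient_id == p &
                       is_ctdna_material(rep_meta$material), ]
      if (length(unique(pm$timepoint)) < 2) return(NULL)
      tr <- vaf_trajectory(
        reportable[reportable$sample_id %in% pm$sample_id, , drop = FALSE],
        pm, reporting_vaf = cfg$filter$reporting_vaf
      )
      if (nrow(tr) == 0) return(NULL)
      mutate(tr, patient_id = p, .before = 1)
    })
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("liquidpanel")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    n_raw = nrow(variants), n_filtered = nrow(retained),
    n_reportable = nrow(reportable)
  )
  bundle <- structure(
    list(qc = qc, filtered = filtered, classified = classified,
         reportable = reportable, driver_summary = summary,
         cnv_calls = cnv_calls, concordance = concordance,
         trajectories = trajectories, provenance = provenance),
    class = "report_bundle"
  )
  if (!is.null(cfg$out_dir)) write_report_bundle(bundle, cfg$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("liquidpanel report\n")
  cat(sprintf("  raw calls %d -> filtered %d -> reportable %d\n",
              x$provenance$n_raw, x$provenance$n_filtered,
              x$provenance$n_reportable))
  print(x$driver_summary)
  if (!is.null(x$cnv_calls)) {
    amp <- x$cnv_calls[x$cnv_calls$status != "neutral", ]
    cat("  CNV calls:", nrow(amp), "non-neutral\n")
  }
  invisible(x)
}

serialize_summary <- function(s) {
  list(
    n_ctdna_samples_with_driver = s$n_ctdna_samples_with_driver,
    n_ctdna_driver_variants = s$n_ctdna_driver_variants,
    per_gene = s$per_gene,
    per_sample = s$per_sample,
    tier_counts = as.list(setNames(as.integer(s$tier_counts),
                                   names(s$tier_counts)))
  )
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  readr::write_tsv(bundle$filtered, file.path(out_dir, "filtered.tsv"),
                   progress = FALSE)
  cls <- bundle$classified
  cls$tier <- as.character(cls$tier)
  readr::write_tsv(cls, file.path(out_dir, "classified.tsv"),
                   progress = FALSE)
  wj(serialize_summary(bundle$driver_summary), "driver_summary.json")
  if (!is.null(bundle$cnv_calls)) {
    wj(bundle$cnv_calls[setdiff(names(bundle$cnv_calls), "per_target")],
       "cnv_calls.json")
  }
  if (!is.null(bundle$concordance) && nrow(bundle$concordance) > 0) {
    wj(bundle$concordance, "concordance.json")
  }
  if (!is.null(bundle$trajectories) && nrow(bundle$trajectories) > 0) {
    tr <- bundle$trajectories
    tr$series <- purrr::map(tr$series, as.list)
    wj(tr, "trajectories.json")
  }
  if (!is.null(bundle$qc)) wj(bundle$qc, "qc.json")
  wj(bundle$provenance, "provenance.json")
  invisible(out_dir)
}
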