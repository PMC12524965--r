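#' Droplet digital PCR partition counts
#'
#' One well's accepted droplets and the per-channel positive counts:
#' mutant (FAM-type) and wild-type (HEX/VIC-type) channels.
#'
#' @param n_total Number of accepted droplets (> 0).
#' @param n_mut_pos,n_wt_pos Positive droplets per channel.
#' @param droplet_volume Droplet volume in nanolitres (default 0.85, the
#'   conventional QX-200 partition volume).
#' @return A `droplet_counts` list.
#' @export
droplet_counts <- function(n_total, n_mut_pos, n_wt_pos,
                           droplet_volume = 0.85) {
  if (n_total <= 0) abort("n_total must be positive")
  if (n_mut_pos < 0 || n_mut_pos > n_total ||
      n_wt_pos < 0 || n_wt_pos > n_total) {
    abort("channel positives must lie in [0, n_total]")
  }
  if (droplet_volume <= 0) abort("droplet_volume must be positive")
  structure(
    list(n_total = as.integer(n_total),
         n_mut_pos = as.integer(n_mut_pos),
         n_wt_pos = as.integer(n_wt_pos),
         droplet_volume = droplet_volume),
    class = "droplet_counts"
  )
}

lambda_from_positive <- function(n_pos, n_total) {
  -log(1 - n_pos / n_total)
}

#' Poisson quantification of ddPCR droplet counts
#'
#' Under random partitioning, template copies per droplet are Poisson, so
#' the mean copies per droplet of a channel is
#' `lambda = -ln(1 - n_pos / n_total)`. Concentration is
#' `lambda / droplet volume` (copies/uL with the volume in nL), and the
#' mutant fractional abundance — the ddPCR analogue of VAF — is
#' `lambda_mut / (lambda_mut + lambda_wt)`. 95% confidence intervals come
#' from the exact binomial interval on the positive fraction propagated
#' through `-ln(1 - .)` (monotone, so endpoints map to endpoints). A
#' fully positive channel leaves lambda undefined (the sample must be
#' diluted); that is an error, not infinity.
#'
#' @param d A [droplet_counts()] object.
#' @param min_pos_droplets Minimum mutant-positive droplets to call the
#'   target detected (default 3).
#' @param conf_level Confidence level for the lambda intervals.
#' @return A `poisson_quant` list: `lambda_mut`, `lambda_wt`, `conc_mut`,
#'   `conc_wt` (copies/uL), `fractional_abundance`, `ci_mut`, `ci_wt`,
#'   `detected`.
#' @export
#' @examples
#' d <- droplet_counts(n_total = 20000, n_mut_pos = 12643, n_wt_pos = 396)
#' quantify_droplets(d)
quantify_droplets <- function(d, min_pos_droplets = 3, conf_level = 0.95) {
  stopifnot(inherits(d, "droplet_counts"))
  if (d$n_mut_pos == d$n_total || d$n_wt_pos == d$n_total) {
    abort(paste0(
      "a channel is saturated (all droplets positive): lambda is ",
      "undefined; dilute and repeat"
    ))
  }
  chan <- function(n_pos) {
    lambda <- lambda_from_positive(n_pos, d$n_total)
    ci_p <- binom.test(n_pos, d$n_total,
                       conf.level = conf_level)$conf.int
    list(lambda = lambda,
         conc = lambda / (d$droplet_volume * 1e-3),
         ci = -log(1 - ci_p))
  }
  mut <- chan(d$n_mut_pos)
  wt <- chan(d$n_wt_pos)
  total <- mut$lambda + wt$lambda
  structure(
    list(
      lambda_mut = mut$lambda, lambda_wt = wt$lambda,
      conc_mut = mut$conc, conc_wt = wt$conc,
      fractional_abundance = if (total > 0) mut$lambda / total else NA_real_,
      ci_mut = mut$ci, ci_wt = wt$ci,
      detected = d$n_mut_pos >= min_pos_droplets,
      counts = d
    ),
    class = "poisson_quant"
  )
}

#' @export
print.poisson_quant <- function(x, ...) {
  cat("ddPCR Poisson quantification\n")
  cat(sprintf("  mutant:    lambda %.4g (95%% CI %.4g-%.4g), %.4g copies/uL\n",
              x$lambda_mut, x$ci_mut[1], x$ci_mut[2], x$conc_mut))
  cat(sprintf("  wild-type: lambda %.4g (95%% CI %.4g-%.4g), %.4g copies/uL\n",
              x$lambda_wt, x$ci_wt[1], x$ci_wt[2], x$conc_wt))
  fa <- x$fractional_abundance
  cat(sprintf("  fractional abundance: %s\n",
              if (is.na(fa)) "undefined (no template)" else
                sprintf("%.3f", fa)))
  cat("  mutant detected:", x$detected, "\n")
  invisible(x)
}

#' Read a droplet-count CSV
#'
#' Long format, one row per well and channel: columns `well`, `channel`
#' (`mut` or `wt`), `n_total`, `n_pos`, and optionally `droplet_volume`.
#'
#' @param path CSV path.
#' @return A tibble of per-well [droplet_counts()] in a `counts` list
#'   column.
#' @export
read_droplet_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("well", "channel", "n_total", "n_pos")
  if (length(setdiff(needed, names(df))) > 0) {
    abort("droplet CSV needs columns: well, channel, n_total, n_pos")
  }
  if (any(!df$channel %in% c("mut", "wt"))) {
    abort("channel must be 'mut' or 'wt'")
  }
  purrr::map_dfr(unique(df$well), function(w) {
    rows <- df[df$well == w, ]
    mut <- rows[rows$channel == "mut", ]
    wt <- rows[rows$channel == "wt", ]
    if (nrow(mut) != 1 || nrow(wt) != 1) {
      abort(paste0("well ", w, " needs exactly one mut and one wt row"))
    }
    if (mut$n_total != wt$n_total) {
      abort(paste0("well ", w, ": channels disagree on n_total"))
    }
    vol <- if ("droplet_volume" %in% names(rows)) rows$droplet_volume[1] else 0.85
    tibble(
      well = w,
      counts = list(droplet_counts(mut$n_total, mut$n_pos, wt$n_pos,
                                   droplet_volume = vol))
    )
  })
}
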