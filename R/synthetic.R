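#' Ground-truth record for a simulated sample
#'
#' Bundles everything the simulators need to emit a panel dataset with a
#' known answer: tumour purity, the somatic clones present, gene
#' amplifications, germline SNPs and the low-VAF artifact rate. Parameter
#' recovery against this record is how the downstream stages are tested.
#'
#' @param purity Tumour fraction of the sample in \[0, 1\]. For ctDNA this
#'   is the ctDNA fraction of total cfDNA.
#' @param clones Tibble of somatic clones, one row per variant, with
#'   columns `gene`, `clonal_fraction` (fraction of tumour cells carrying
#'   the variant, in (0, 1\]), `copy_state` (`"het_diploid"` or
#'   `"hom_loh"`), and optionally `protein_change`, `base_change`, `pos`,
#'   `ref`, `alt` (fixed genomic key; defaults are assigned within the
#'   gene's panel targets), and `pathogenic` (logical, default `TRUE`;
#'   controls which in-silico score distribution is drawn from).
#' @param amplified_genes Named integer vector of tumour copy numbers for
#'   amplified genes, e.g. `c(MYCN = 50)`. Genes absent from the vector
#'   are copy-neutral (2).
#' @param germline_snps Either a count of heterozygous-or-homozygous
#'   germline SNPs to scatter over the panel (their population MAFs are
#'   drawn uniformly from \[0.01, 0.45\] under the record's seed) or a
#'   tibble with a `maf` column.
#' @param artifact_rate Expected number of low-VAF (<0.5%) artifact calls
#'   per panel target.
#' @param seed Integer seed making every simulator deterministic.
#' @param sample_id Label given to emitted records.
#' @param sex_chrx_copies Germline copy number of chrX (1 for XY, 2
#'   for XX); scales coverage of X-chromosomal targets.
#' @return A `simulation_truth` list.
#' @export
#' @examples
#' truth <- simulation_truth(
#'   purity = 0.57,
#'   clones = tibble::tibble(gene = "ALK", clonal_fraction = 1,
#'                           copy_state = "het_diploid")
#' )
simulation_truth <- function(purity, clones = NULL,
                             amplified_genes = integer(),
                             germline_snps = 0, artifact_rate = 0.02,
                             seed = 1L, sample_id = "S1",
                             sex_chrx_copies = 1) {
  if (!is.numeric(purity) || length(purity) != 1 || is.na(purity) ||
      purity < 0 || purity > 1) {
    abort("purity must be a single number in [0, 1]")
  }
  if (is.null(clones)) {
    clones <- tibble(gene = character(), clonal_fraction = numeric(),
                     copy_state = character())
  }
  clones <- as_tibble(clones)
  if (nrow(clones) > 0) {
    if (any(clones$clonal_fraction <= 0 | clones$clonal_fraction > 1)) {
      abort("clonal fractions must lie in (0, 1]")
    }
    if (any(!clones$copy_state %in% c("het_diploid", "hom_loh"))) {
      abort("copy_state must be 'het_diploid' or 'hom_loh'")
    }
  }
  if (!"pathogenic" %in% names(clones)) {
    clones$pathogenic <- rep(TRUE, nrow(clones))
  }
  if (length(amplified_genes) > 0 &&
      (any(amplified_genes < 0) || is.null(names(amplified_genes)))) {
    abort("amplified_genes must be a named vector of copy numbers >= 0")
  }
  if (is.numeric(germline_snps) && length(germline_snps) == 1 &&
      !is_tibble(germline_snps)) {
    n_snp <- as.integer(germline_snps)
    germline_snps <- withr::with_seed(
      seed, tibble(maf = round(runif(n_snp, 0.01, 0.45), 4))
    )
  }
  germline_snps <- as_tibble(germline_snps)
  if (nrow(germline_snps) > 0 && !"maf" %in% names(germline_snps)) {
    abort("germline_snps needs a 'maf' column")
  }
  if (artifact_rate < 0) abort("artifact_rate must be >= 0")
  structure(
    list(purity = purity, clones = clones,
         amplified_genes = amplified_genes,
         germline_snps = germline_snps, artifact_rate = artifact_rate,
         seed = as.integer(seed), sample_id = sample_id,
         sex_chrx_copies = sex_chrx_copies),
    class = "simulation_truth"
  )
}

# expected somatic VAF of a clone: purity x clonal fraction pushed through
# the copy-state mixing model (see vaf_from_purity)
expected_clone_vaf <- function(purity, clonal_fraction, copy_state) {
  f <- purity * clonal_fraction
  vaf_from_purity(f, copy_state)
}

draw_scores <- function(n, pathogenic, revel_missing_rate = 0) {
  # pathogenic and benign score ranges are disjoint by construction so
  # parameter-recovery tests can demand exact label recovery
  out <- tibble(
    sift_score = numeric(n), sift_call = character(n),
    polyphen_score = numeric(n), polyphen_call = character(n),
    revel_score = numeric(n), cosmic_id = NA_character_
  )
  for (i in seq_len(n)) {
    if (pathogenic[i]) {
      out$sift_score[i] <- round(runif(1, 0, 0.04), 2)
      out$sift_call[i] <- "deleterious"
      out$polyphen_score[i] <- round(runif(1, 0.9, 1), 3)
      out$polyphen_call[i] <- "PRD"
      out$revel_score[i] <- round(runif(1, 0.72, 0.99), 3)
      out$cosmic_id[i] <- sprintf("COSV%08d", sample.int(1e8, 1))
    } else {
      out$sift_score[i] <- round(runif(1, 0.2, 1), 2)
      out$sift_call[i] <- "tolerated"
      out$polyphen_score[i] <- round(runif(1, 0, 0.3), 3)
      out$polyphen_call[i] <- "B"
      out$revel_score[i] <- round(runif(1, 0, 0.5), 3)
    }
  }
  if (revel_missing_rate > 0) {
    drop <- pathogenic & runif(n) < revel_missing_rate
    out$revel_score[drop] <- NA_real_
  }
  out
}

random_base_pair <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate the post-calling annotated variant table of one sample
#'
#' Emulates what a UMI-aware targeted-panel caller reports after consensus
#' building: somatic clone variants at their purity- and copy-state-scaled
#' expected VAFs, germline SNPs near 50% or 100% with their population
#' frequencies annotated, and low-VAF artifact calls. Alt-read counts are
#' binomial at a lognormal per-target depth; a variant drawing zero alt
#' reads is not called and is absent from the table.
#'
#' @param truth A [simulation_truth()] record.
#' @param panel A panel tibble (see [default_panel()]).
#' @param mean_depth Mean UMI read depth of the panel (default 2228, a
#'   typical mid-output flow-cell yield for this panel chemistry).
#' @param depth_sdlog Lognormal sdlog of per-target depth variation.
#' @param revel_missing_rate Fraction of pathogenic variants whose REVEL
#'   score is withheld, to exercise the missing-score classification path.
#' @return A variant tibble (see [variant_columns]) with two extra
#'   ground-truth columns: `truth_class` (`somatic_driver`,
#'   `somatic_benign`, `germline_snp`, `artifact`) and `expected_vaf`.
#' @export
simulate_variant_table <- function(truth, panel, mean_depth = 2228,
                                   depth_sdlog = 0.5,
                                   revel_missing_rate = 0) {
  stopifnot(inherits(truth, "simulation_truth"))
  panel <- validate_panel(panel)
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    abort("mean_depth must be positive")
  }
  withr::with_seed(truth$seed, {
    meanlog <- log(mean_depth) - depth_sdlog^2 / 2
    draw_depth <- function(n) {
      pmax(1, round(rlnorm(n, meanlog = meanlog, sdlog = depth_sdlog)))
    }
    rows <- list()

    clones <- truth$clones
    if (nrow(clones) > 0) {
      missing_gene <- setdiff(clones$gene, panel$gene)
      if (length(missing_gene) > 0) {
        abort(paste0("clone gene(s) not on panel: ",
                     paste(missing_gene, collapse = ", ")))
      }
      # assign each clone a locus inside its gene's targets; clones of the
      # same gene occupy successive targets so keys never collide
      clones <- clones %>%
        group_by(.data$gene) %>%
        mutate(.slot = row_number()) %>%
        ungroup()
      tgt <- purrr::map_dfr(seq_len(nrow(clones)), function(i) {
        g <- panel[panel$gene == clones$gene[i], ]
        slot <- ((clones$.slot[i] - 1) %% nrow(g)) + 1
        g[slot, ]
      })
      bp <- random_base_pair(nrow(clones))
      pos <- if ("pos" %in% names(clones)) clones$pos else rep(NA, nrow(clones))
      pos <- ifelse(is.na(pos),
                    tgt$start + floor((tgt$end - tgt$start) / 2) + 1L, pos)
      ref <- if ("ref" %in% names(clones)) {
        ifelse(is.na(clones$ref), bp$ref, clones$ref)
      } else bp$ref
      alt <- if ("alt" %in% names(clones)) {
        ifelse(is.na(clones$alt), bp$alt, clones$alt)
      } else bp$alt
      evaf <- expected_clone_vaf(truth$purity, clones$clonal_fraction,
                                 clones$copy_state)
      depth <- draw_depth(nrow(clones))
      alt_n <- rbinom(nrow(clones), depth, evaf)
      scores <- draw_scores(nrow(clones), clones$pathogenic,
                            revel_missing_rate)
      rows$somatic <- tibble(
        sample_id = truth$sample_id, gene = clones$gene,
        chrom = tgt$chrom, pos = as.integer(pos), ref = ref, alt = alt,
        vaf = alt_n / depth, depth = depth,
        base_change = if ("base_change" %in% names(clones)) {
          clones$base_change
        } else sprintf("c.(%d%s>%s)", as.integer(pos), ref, alt),
        protein_change = if ("protein_change" %in% names(clones)) {
          clones$protein_change
        } else NA_character_,
        consequence = "missense",
        scores,
        gnomad_af = NA_real_, dbsnp_common_maf = NA_real_,
        artifact_flag = FALSE, duplicate_flag = FALSE,
        truth_class = ifelse(clones$pathogenic, "somatic_driver",
                             "somatic_benign"),
        expected_vaf = evaf,
        .alt_n = alt_n
      )
    }

    snps <- truth$germline_snps
    if (nrow(snps) > 0) {
      idx <- sample.int(nrow(panel), nrow(snps), replace = TRUE)
      tgt <- panel[idx, ]
      pos <- tgt$start +
        vapply(tgt$end - tgt$start, function(w) sample.int(w, 1), integer(1))
      bp <- random_base_pair(nrow(snps))
      hom <- runif(nrow(snps)) < snps$maf
      evaf <- ifelse(hom, 1, 0.5)
      depth <- draw_depth(nrow(snps))
      alt_n <- rbinom(nrow(snps), depth, evaf)
      scores <- draw_scores(nrow(snps), rep(FALSE, nrow(snps)))
      rows$germline <- tibble(
        sample_id = truth$sample_id, gene = tgt$gene,
        chrom = tgt$chrom, pos = as.integer(pos), ref = bp$ref, alt = bp$alt,
        vaf = alt_n / depth, depth = depth,
        base_change = sprintf("c.(%d%s>%s)", as.integer(pos), bp$ref, bp$alt),
        protein_change = NA_character_, consequence = "other",
        scores,
        gnomad_af = snps$maf, dbsnp_common_maf = snps$maf,
        artifact_flag = FALSE, duplicate_flag = FALSE,
        truth_class = "germline_snp", expected_vaf = evaf,
        .alt_n = alt_n
      )
    }

    n_art <- rpois(1, truth$artifact_rate * nrow(panel))
    if (n_art > 0) {
      idx <- sample.int(nrow(panel), n_art, replace = TRUE)
      tgt <- panel[idx, ]
      pos <- tgt$start +
        vapply(tgt$end - tgt$start, function(w) sample.int(w, 1), integer(1))
      bp <- random_base_pair(n_art)
      evaf <- runif(n_art, 5e-4, 4.9e-3)
      depth <- draw_depth(n_art)
      alt_n <- rbinom(n_art, depth, evaf)
      scores <- draw_scores(n_art, rep(FALSE, n_art))
      rows$artifact <- tibble(
        sample_id = truth$sample_id, gene = tgt$gene,
        chrom = tgt$chrom, pos = as.integer(pos), ref = bp$ref, alt = bp$alt,
        vaf = alt_n / depth, depth = depth,
        base_change = sprintf("c.(%d%s>%s)", as.integer(pos), bp$ref, bp$alt),
        protein_change = NA_character_, consequence = "other",
        scores,
        gnomad_af = NA_real_, dbsnp_common_maf = NA_real_,
        artifact_flag = TRUE, duplicate_flag = FALSE,
        truth_class = "artifact", expected_vaf = evaf,
        .alt_n = alt_n
      )
    }

    out <- bind_rows(rows)
    if (nrow(out) == 0) {
      out <- variant_table()
      out$truth_class <- character(0)
      out$expected_vaf <- numeric(0)
      return(out)
    }
    out <- out[out$.alt_n > 0, , drop = FALSE]  # zero alt reads: not called
    out$.alt_n <- NULL
    validate_variants(out)
  })
}

#' Simulate per-target UMI coverage for one sample
#'
#' Expected relative coverage of a gene with tumour copy number `C` in a
#' sample of purity `p` is `(2 (1 - p) + C p) / 2` of the copy-neutral
#' level; X-chromosomal targets are additionally scaled by the germline
#' chrX copy number over 2. Multiplicative lognormal noise with the given
#' coefficient of variation is applied per target.
#'
#' @inheritParams simulate_variant_table
#' @param noise_cv Coefficient of variation of per-target multiplicative
#'   noise (0 gives exact expected coverage).
#' @param seed Seed; defaults to the truth record's.
#' @return A coverage tibble: `sample_id`, `target_id`, `gene`, `chrom`,
#'   `start`, `end`, `umi_depth`.
#' @export
#' @examples
#' truth <- simulation_truth(purity = 0.3, amplified_genes = c(MYCN = 50))
#' cov <- simulate_coverage(truth, default_panel(), noise_cv = 0)
#' # MYCN fold change over neutral: (2 * 0.7 + 50 * 0.3) / 2 = 8.2
simulate_coverage <- function(truth, panel, mean_depth = 2228,
                              noise_cv = 0.1, seed = truth$seed) {
  stopifnot(inherits(truth, "simulation_truth"))
  panel <- validate_panel(panel)
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (mean_depth <= 0) abort("mean_depth must be positive")
  withr::with_seed(seed, {
    cn <- setNames(rep(2, length(panel_genes(panel))), panel_genes(panel))
    amp <- truth$amplified_genes[names(truth$amplified_genes) %in% names(cn)]
    cn[names(amp)] <- amp
    rel <- (2 * (1 - truth$purity) + cn[panel$gene] * truth$purity) / 2
    rel <- unname(rel)
    rel[panel$chrom == "chrX"] <- rel[panel$chrom == "chrX"] *
      truth$sex_chrx_copies / 2
    noise <- if (noise_cv == 0) {
      rep(1, nrow(panel))
    } else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      rlnorm(nrow(panel), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tibble(
      sample_id = truth$sample_id,
      target_id = panel$target_id, gene = panel$gene,
      chrom = panel$chrom, start = panel$start, end = panel$end,
      umi_depth = mean_depth * rel * noise
    )
  })
}

#' Simulate ddPCR droplet partitioning
#'
#' Each channel's positive-droplet count is binomial with success
#' probability `1 - exp(-lambda)`, the Poisson probability that a droplet
#' receives at least one template copy.
#'
#' @param lambda_wt,lambda_mut Mean copies per droplet for the wild-type
#'   and mutant channels.
#' @param n_droplets Number of accepted droplets.
#' @param seed Integer seed.
#' @param droplet_volume Droplet volume in nanolitres.
#' @return A [droplet_counts()] object.
#' @export
#' @examples
#' d <- simulate_droplets(lambda_wt = 0.02, lambda_mut = 1, seed = 7)
#' quantify_droplets(d)
simulate_droplets <- function(lambda_wt, lambda_mut, n_droplets = 20000,
                              seed = 1L, droplet_volume = 0.85) {
  if (lambda_wt < 0 || lambda_mut < 0) abort("lambda must be >= 0")
  if (n_droplets <= 0) abort("n_droplets must be positive")
  withr::with_seed(seed, {
    n_mut <- rbinom(1, n_droplets, 1 - exp(-lambda_mut))
    n_wt <- rbinom(1, n_droplets, 1 - exp(-lambda_wt))
    droplet_counts(n_total = n_droplets, n_mut_pos = n_mut,
                   n_wt_pos = n_wt, droplet_volume = droplet_volume)
  })
}

#' Clonal-evolution scenario: two ALK clones at diagnosis, one at relapse
#'
#' Generates the multi-sample pattern seen when a minor and a major ALK
#' clone coexist at diagnosis, single-site tumour biopsy captures only one
#' of them, treatment clears detectable disease, and the other clone
#' returns fixed at relapse: diagnosis ctDNA carries ALK R1275Q (minor
#' clone, expected VAF 2.85%) and F1174L (major clone, 28.5%); the
#' diagnostic tumour carries only R1275Q (32%); remission ctDNA has no
#' somatic signal; relapse ctDNA and tumour carry only F1174L (~98% in
#' plasma under loss of the wild-type allele, 46.1% heterozygous in the
#' metastatic tumour). Germline SNPs and low-VAF artifacts are included so
#' the full filtering cascade is exercised end to end.
#'
#' @param seed Integer seed.
#' @param panel Panel tibble.
#' @param mean_depth Mean UMI depth for the simulated variant tables.
#' @param n_germline_snps Germline SNPs per sample.
#' @param artifact_rate Artifact calls per panel target.
#' @return A list with `variants` (all samples stacked, ground-truth
#'   columns retained), `metadata` (sample sheet with patient, material,
#'   timepoint, assay and cfDNA fraction), `truths` (per-sample
#'   [simulation_truth()] records) and `expected` (the ground-truth
#'   concordance categories and trajectory labels).
#' @export
scenario_clonal_evolution <- function(seed = 1L, panel = default_panel(),
                                      mean_depth = 2228,
                                      n_germline_snps = 30,
                                      artifact_rate = 0.02) {
  alk <- panel[panel$gene == "ALK", ]
  if (nrow(alk) < 2) abort("panel needs at least two ALK targets")
  f1174l <- tibble(
    gene = "ALK", clonal_fraction = 1, copy_state = "het_diploid",
    pos = alk$start[1] + 100L, ref = "C", alt = "A",
    base_change = "c.(3522C>A)", protein_change = "p.(F1174L)"
  )
  r1275q <- tibble(
    gene = "ALK", clonal_fraction = 1, copy_state = "het_diploid",
    pos = alk$start[2] + 100L, ref = "G", alt = "A",
    base_change = "c.(3824G>A)", protein_change = "p.(R1275Q)"
  )
  sub_seeds <- withr::with_seed(seed, sample.int(1e6, 5))
  specs <- list(
    list(id = "P1_diag_ctDNA", purity = 0.57, timepoint = "diagnosis",
         material = "ctDNA_blood",
         clones = bind_rows(f1174l, mutate(r1275q, clonal_fraction = 0.1))),
    list(id = "P1_diag_tumour", purity = 0.64, timepoint = "diagnosis",
         material = "tumour", clones = r1275q),
    list(id = "P1_remission_ctDNA", purity = 0, timepoint = "remission",
         material = "ctDNA_blood", clones = f1174l),
    list(id = "P1_relapse_ctDNA", purity = 0.99, timepoint = "relapse",
         material = "ctDNA_blood",
         clones = mutate(f1174l, copy_state = "hom_loh")),
    list(id = "P1_relapse_tumour", purity = 0.922, timepoint = "relapse",
         material = "tumour", clones = f1174l)
  )
  truths <- purrr::map2(specs, sub_seeds, function(s, sd) {
    simulation_truth(
      purity = s$purity, clones = s$clones,
      germline_snps = n_germline_snps, artifact_rate = artifact_rate,
      seed = sd, sample_id = s$id
    )
  })
  variants <- purrr::map_dfr(truths, simulate_variant_table, panel = panel,
                             mean_depth = mean_depth)
  metadata <- purrr::map_dfr(specs, function(s) {
    tibble(sample_id = s$id, patient_id = "P1", material = s$material,
           timepoint = s$timepoint, risk_group = "high", assay = "tNGS",
           cfdna_fraction = 0.5)
  })
  key_f <- paste(alk$chrom[1], f1174l$pos, "C", "A", sep = ":")
  key_r <- paste(alk$chrom[2], r1275q$pos, "G", "A", sep = ":")
  expected <- list(
    n_diagnosis_ctdna_drivers = 2L,
    n_relapse_ctdna_drivers = 1L,
    n_remission_ctdna_drivers = 0L,
    diagnosis_shared_key = key_r,
    diagnosis_ctdna_only_key = key_f,
    trajectory_labels = tibble(
      key = c(key_f, key_r),
      protein_change = c("p.(F1174L)", "p.(R1275Q)"),
      label = c("lost_then_emergent", "lost")
    )
  )
  list(variants = variants, metadata = metadata, truths = truths,
       expected = expected)
}
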