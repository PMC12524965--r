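#' Default 42-gene neuroblastoma panel
#'
#' A targeted panel of 42 genes recurrently altered in neuroblastoma,
#' anchored on the canonical drivers (ALK, MYCN, TP53, PTPN11, RAS-MAPK
#' genes, chromatin remodellers) and padded with further genes of interest
#' to the configured panel size. Coordinates are schematic (one locus per
#' gene, non-overlapping targets), which is sufficient for coverage
#' simulation and z-score analysis; real panels supply their own BED.
#'
#' @param n_genes Panel size; the first `n_genes` of the built-in gene list
#'   are used (default 42, the full list).
#' @param targets_per_gene Number of tiled target regions per gene.
#' @param target_length Width of each target in bp.
#' @return A panel tibble with columns `target_id`, `gene`, `chrom`,
#'   `start`, `end` (0-based, half-open). X-chromosomal genes carry
#'   `chrom == "chrX"`.
#' @export
#' @examples
#' panel <- default_panel()
#' length(unique(panel$gene))
default_panel <- function(n_genes = 42, targets_per_gene = 8,
                          target_length = 250) {
  gene_chrom <- c(
    ALK = "chr2", MYCN = "chr2", TP53 = "chr17", PTPN11 = "chr12",
    KRAS = "chr12", NRAS = "chr1", CREBBP = "chr16", SMARCA4 = "chr19",
    NF1 = "chr17", ATM = "chr11", CHEK2 = "chr22", CDK4 = "chr12",
    MDM2 = "chr12", CCND1 = "chr11", FGFR1 = "chr8",
    ATRX = "chrX", DDX3X = "chrX", ARID1A = "chr1", ARID1B = "chr6",
    BARD1 = "chr2", BRAF = "chr7", CDKN2A = "chr9", EZH2 = "chr7",
    FGFR2 = "chr10", GATA3 = "chr10", HRAS = "chr11", IDH1 = "chr2",
    JAK2 = "chr9", KIT = "chr4", LIN28B = "chr6", MET = "chr7",
    MYC = "chr8", NTRK1 = "chr1", PHOX2B = "chr4", PIK3CA = "chr3",
    PTEN = "chr10", RET = "chr10", SMARCB1 = "chr22", SOS1 = "chr2",
    TERT = "chr5", TIAM1 = "chr21", TERC = "chr3"
  )
  if (n_genes < 1 || n_genes > length(gene_chrom)) {
    abort(paste0("n_genes must be between 1 and ", length(gene_chrom)))
  }
  stopifnot(targets_per_gene >= 1, target_length >= 1)
  genes <- names(gene_chrom)[seq_len(n_genes)]
  purrr::map_dfr(seq_along(genes), function(i) {
    gene <- genes[i]
    # schematic locus: 1 Mb apart per gene, targets tiled with 50 bp gaps
    base <- i * 1e6
    starts <- base + (seq_len(targets_per_gene) - 1) * (target_length + 50)
    tibble(
      target_id = sprintf("%s_t%02d", gene, seq_len(targets_per_gene)),
      gene = gene,
      chrom = unname(gene_chrom[gene]),
      start = as.integer(starts),
      end = as.integer(starts + target_length)
    )
  })
}

#' Genes of a panel
#'
#' @param panel A panel tibble (see [default_panel()]).
#' @return Character vector of unique gene symbols.
#' @export
panel_genes <- function(panel) unique(panel$gene)

#' X-chromosomal genes of a panel
#'
#' @inheritParams panel_genes
#' @return Gene symbols whose targets lie on chrX.
#' @export
panel_chrx_genes <- function(panel) unique(panel$gene[panel$chrom == "chrX"])

validate_panel <- function(panel) {
  panel <- as_tibble(panel)
  needed <- c("target_id", "gene", "chrom", "start", "end")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(panel$start >= panel$end)) abort("panel targets must have start < end")
  if (any(!nzchar(panel$chrom)) || any(is.na(panel$chrom))) {
    abort("panel targets need a chromosome")
  }
  if (anyDuplicated(panel$target_id)) abort("duplicate target_id in panel")
  # non-overlap within a gene
  by_gene <- split(panel, panel$gene)
  for (g in by_gene) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)] &
                             g$chrom[-1] == g$chrom[-nrow(g)])) {
      abort(paste0("overlapping targets within gene ", g$gene[1]))
    }
  }
  panel
}

#' Read / write a panel BED file
#'
#' BED3 plus two annotation columns (`gene`, `target_id`), tab-separated,
#' no header, 0-based half-open coordinates.
#'
#' @param path File path.
#' @return `read_panel_bed()` returns a panel tibble.
#' @export
read_panel_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene", "target_id"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), gene = readr::col_character(),
      target_id = readr::col_character()
    ),
    progress = FALSE
  )
  validate_panel(bed[c("target_id", "gene", "chrom", "start", "end")])
}

#' @rdname read_panel_bed
#' @param panel A panel tibble.
#' @export
write_panel_bed <- function(panel, path) {
  panel <- validate_panel(panel)
  readr::write_tsv(panel[c("chrom", "start", "end", "gene", "target_id")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
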