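# Small builders shared across test files.

# a clone tibble for simulation truths
clone <- function(gene = "ALK", clonal_fraction = 1,
                  copy_state = "het_diploid", pathogenic = TRUE, ...) {
  tibble::tibble(gene = gene, clonal_fraction = clonal_fraction,
                 copy_state = copy_state, pathogenic = pathogenic, ...)
}

# a fully-annotated pathogenic-looking variant row, overridable
driver_row <- function(...) {
  defaults <- list(
    sample_id = "S1", gene = "ALK", chrom = "chr2", pos = 29443695L,
    ref = "G", alt = "A", vaf = 0.25, depth = 2000,
    consequence = "missense", sift_score = 0, sift_call = "deleterious",
    polyphen_score = 1, polyphen_call = "PRD", revel_score = 0.885,
    cosmic_id = "COSV66555567"
  )
  do.call(variant_table, utils::modifyList(defaults, list(...)))
}

small_panel <- function() default_panel(targets_per_gene = 4)
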