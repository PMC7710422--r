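# Config builders for recovery and calibration runs. no_effects() empties
# every planted map so the generator produces a pure null cohort; the
# recovery builders plant exactly one effect under the stated study
# conditions.

no_effects <- function() {
  list(
    de_log2fc = NULL,
    cnv_dosage_slope = NULL,
    meth_effect = NULL,
    meth_expr_slope = NULL,
    mut_freq = NULL,
    pas_shift = tibble::tibble(
      gene = character(), pathway = character(), shift = numeric()
    ),
    drug_rho = tibble::tibble(
      gene = character(), drug = character(), rho = numeric()
    ),
    hazard_direction = NULL
  )
}

null_config <- function(seed, n_background_genes = 50L, layers, ...) {
  do.call(cohort_config, c(
    list(
      cancer_types = "BRCA", n_background_genes = n_background_genes,
      seed = seed, layers = layers, ...
    ),
    no_effects()
  ))
}

# One planted effect on top of an otherwise-null cohort.
planted_config <- function(seed, plant, layers, cancer_types = "BRCA", ...) {
  args <- no_effects()
  args[names(plant)] <- plant
  do.call(cohort_config, c(
    list(
      cancer_types = cancer_types, seed = seed, layers = layers, ...
    ),
    args
  ))
}

make_gsm <- function(values, genes, samples, semantics) {
  gene_sample_matrix(
    matrix(values,
      nrow = length(genes), byrow = TRUE,
      dimnames = list(genes, samples)
    ),
    semantics
  )
}

tumor_barcodes <- function(n, cancer = "BRCA") {
  sprintf("TCGA-%s-P%04d-01A", cancer, seq_len(n))
}

normal_barcodes <- function(n, cancer = "BRCA") {
  sprintf("TCGA-%s-P%04d-11A", cancer, seq_len(n))
}
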