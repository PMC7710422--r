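#' Differential promoter methylation (tumor vs normal)
#'
#' Two-sample Student's t-test (pooled variance) on gene-level beta values,
#' Benjamini-Hochberg FDR across genes. Direction is `hyper` when the
#' tumor-minus-normal mean beta difference is positive and the FDR gate is
#' met, `hypo` when negative, otherwise `ns`.
#'
#' @param beta a `beta` [gene_sample_matrix()] (gene-level values: promoter
#'   probes are assumed to have been collapsed, e.g. averaged, upstream).
#' @param tumor_samples,normal_samples column names of the two groups;
#'   each group needs >= 3 samples.
#' @param fdr_cutoff FDR gate (default 0.05).
#' @return a `meth_diff` tibble: `gene`, `mean_beta_tumor`,
#'   `mean_beta_normal`, `delta_beta`, `p_value`, `fdr`, `direction`.
#' @export
differential_methylation <- function(beta, tumor_samples, normal_samples,
                                     fdr_cutoff = 0.05) {
  stopifnot(inherits(beta, "gene_sample_matrix"))
  if (attr(beta, "semantics") != "beta") {
    stop("differential_methylation expects beta semantics", call. = FALSE)
  }
  if (length(tumor_samples) < 3L || length(normal_samples) < 3L) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  x <- unclass(beta)
  res <- purrr::map_dfr(rownames(x), function(g) {
    fit <- two_sample_t(x[g, tumor_samples], x[g, normal_samples],
      pooled = TRUE
    )
    tibble::tibble(
      gene = g,
      mean_beta_tumor = fit$mean_x,
      mean_beta_normal = fit$mean_y,
      delta_beta = fit$mean_x - fit$mean_y,
      p_value = fit$p_value
    )
  })
  res$fdr <- benjamini_hochberg(res$p_value)
  res$direction <- dplyr::case_when(
    res$delta_beta > 0 & res$fdr < fdr_cutoff ~ "hyper",
    res$delta_beta < 0 & res$fdr < fdr_cutoff ~ "hypo",
    .default = "ns"
  )
  new_result(res, "meth_diff")
}

#' Methylation / expression Spearman correlation on barcode-matched samples
#'
#' Samples are matched between the two matrices by exact barcode; per gene,
#' Spearman correlation (t-approximation p) between beta and log2
#' expression, Benjamini-Hochberg FDR across genes. Fewer than 3 matched
#' samples yields missing-value records rather than an error.
#'
#' @param beta a `beta` [gene_sample_matrix()].
#' @param expression a `raw_count` or `normalized_expression`
#'   [gene_sample_matrix()].
#' @return a `meth_correlation` tibble: `gene`, `rho`, `p_value`, `fdr`, `n`.
#' @export
methylation_expression_correlation <- function(beta, expression) {
  stopifnot(
    inherits(beta, "gene_sample_matrix"),
    inherits(expression, "gene_sample_matrix")
  )
  shared <- intersect(colnames(beta), colnames(expression))
  genes <- intersect(rownames(beta), rownames(expression))
  if (length(shared) < 3L) {
    res <- tibble::tibble(
      gene = genes, rho = NA_real_, p_value = NA_real_,
      fdr = NA_real_, n = length(shared)
    )
    return(new_result(res, "meth_correlation"))
  }
  b <- unclass(beta)[genes, shared, drop = FALSE]
  e <- log2(unclass(expression)[genes, shared, drop = FALSE] + 1)
  res <- purrr::map_dfr(genes, function(g) {
    dplyr::bind_cols(tibble::tibble(gene = g), spearman_test(b[g, ], e[g, ]))
  })
  res$fdr <- benjamini_hochberg(res$p_value)
  new_result(
    res[c("gene", "rho", "p_value", "fdr", "n")],
    "meth_correlation"
  )
}
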