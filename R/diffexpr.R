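#' Median-of-ratios size factors
#'
#' Library-size normalization for count matrices: each sample's factor is the
#' median, over genes with a positive geometric mean across samples, of the
#' ratio of its count to that geometric mean; factors are then rescaled to
#' geometric mean 1 so identical samples get factor 1.
#'
#' @param counts a `raw_count` [gene_sample_matrix()].
#' @return named positive numeric vector, one factor per sample.
#' @examples
#' m <- gene_sample_matrix(
#'   matrix(c(10, 20, 30, 20, 40, 60), 3,
#'     dimnames = list(c("g1", "g2", "g3"), c("A", "B"))
#'   ),
#'   "raw_count"
#' )
#' size_factors(m) # B is twice A
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "gene_sample_matrix"))
  if (attr(counts, "semantics") != "raw_count") {
    stop("size_factors expects raw_count semantics", call. = FALSE)
  }
  x <- unclass(counts)
  log_geo <- rowMeans(log(x))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    stop(
      "every gene contains a zero count; no positive geometric means. ",
      "Consider a pseudo-reference (e.g. add a pseudocount) upstream.",
      call. = FALSE
    )
  }
  f <- apply(x[usable, , drop = FALSE], 2, function(col) {
    stats::median(col / exp(log_geo[usable]))
  })
  f / exp(mean(log(f)))
}

#' Tumor-versus-normal differential expression
#'
#' Median-of-ratios normalization, log2 fold change of group means with a
#' 0.5 pseudocount, Welch two-sample t-test on `log2(normalized + 1)`, and
#' Benjamini-Hochberg FDR across the tested genes. A gene is called `up`
#' when `log2_fc >= log2(fc_cutoff)` (boundary inclusive) and `fdr <
#' fdr_cutoff`, `down` symmetrically, otherwise `ns`.
#'
#' @param counts a `raw_count` [gene_sample_matrix()].
#' @param tumor_samples,normal_samples column names of the two groups; each
#'   group needs >= 3 samples.
#' @param fc_cutoff fold-change gate (default 2).
#' @param fdr_cutoff FDR gate (default 0.05).
#' @return a `de_result` tibble: `gene`, `log2_fc`, `p_value`, `fdr`,
#'   `status`.
#' @export
differential_expression <- function(counts, tumor_samples, normal_samples,
                                    fc_cutoff = 2, fdr_cutoff = 0.05) {
  stopifnot(inherits(counts, "gene_sample_matrix"))
  if (length(tumor_samples) < 3L || length(normal_samples) < 3L) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  missing <- setdiff(c(tumor_samples, normal_samples), colnames(counts))
  if (length(missing) > 0L) {
    stop("sample(s) not in matrix: ", paste(utils::head(missing, 3L), collapse = ", "),
      call. = FALSE
    )
  }
  norm <- sweep(unclass(counts), 2, size_factors(counts), "/")
  lg <- log2(norm + 1)
  res <- purrr::map_dfr(rownames(norm), function(g) {
    t_vals <- norm[g, tumor_samples]
    n_vals <- norm[g, normal_samples]
    fit <- two_sample_t(lg[g, tumor_samples], lg[g, normal_samples])
    tibble::tibble(
      gene = g,
      log2_fc = log2((mean(t_vals) + 0.5) / (mean(n_vals) + 0.5)),
      p_value = fit$p_value
    )
  })
  res$fdr <- benjamini_hochberg(res$p_value)
  lfc_gate <- log2(fc_cutoff)
  res$status <- dplyr::case_when(
    res$log2_fc >= lfc_gate & res$fdr < fdr_cutoff ~ "up",
    res$log2_fc <= -lfc_gate & res$fdr < fdr_cutoff ~ "down",
    .default = "ns"
  )
  new_result(res, "de_result")
}

new_result <- function(x, subclass) {
  class(x) <- c(subclass, class(tibble::tibble()))
  x
}
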