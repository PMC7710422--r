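#' Gene-expression / drug-AUC association across cell lines
#'
#' For every (gene, drug) pair, correlation between expression and drug AUC
#' across the cell lines shared by the two matrices (pairwise-complete when
#' AUC has missing values). The headline statistic is Spearman's rho; a
#' Pearson variant is available via `method = "pearson"`. Each rho is
#' Fisher-Z transformed (`z = atanh(rho)`, rho clipped to +/-(1 - 1e-12)),
#' the p-value comes from the t-approximation, and family-wise significance
#' is Bonferroni at `alpha` two-tailed over all gene x drug pairs (i.e.
#' alpha/2 per tail, divided by the number of pairs). Direction follows the
#' resistance convention: positive rho means high expression is resistant
#' (higher AUC), negative means sensitive.
#'
#' @param expression a [gene_sample_matrix()], genes x cell lines.
#' @param auc a `drug_auc` [gene_sample_matrix()], drugs x cell lines.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha family-wise error rate (default 0.05).
#' @return a `drug_association` tibble: `gene`, `drug`, `rho`, `z`,
#'   `p_value`, `n`, `bonferroni_significant`, `direction`. Pairs with
#'   fewer than 3 complete observations are missing-value records.
#' @export
correlate_drug_expression <- function(expression, auc,
                                      method = c("spearman", "pearson"),
                                      alpha = 0.05) {
  stopifnot(
    inherits(expression, "gene_sample_matrix"),
    inherits(auc, "gene_sample_matrix")
  )
  method <- match.arg(method)
  shared <- intersect(colnames(expression), colnames(auc))
  if (length(shared) < 3L) {
    stop("fewer than 3 cell lines shared between expression and AUC",
      call. = FALSE
    )
  }
  e <- t(unclass(expression)[, shared, drop = FALSE])
  a <- t(unclass(auc)[, shared, drop = FALSE])
  rho <- stats::cor(e, a, method = method, use = "pairwise.complete.obs")
  n <- crossprod(!is.na(e), !is.na(a))
  res <- tidyr::crossing(
    gene = rownames(expression),
    drug = rownames(auc)
  ) |>
    dplyr::mutate(
      rho = rho[cbind(.data$gene, .data$drug)],
      n = as.integer(n[cbind(.data$gene, .data$drug)]),
      rho = dplyr::if_else(.data$n < 3L, NA_real_, .data$rho),
      z = atanh(pmin(pmax(.data$rho, -(1 - 1e-12)), 1 - 1e-12)),
      p_value = dplyr::if_else(
        .data$n >= 3L, spearman_p(.data$rho, .data$n), NA_real_
      ),
      bonferroni_significant = !is.na(.data$p_value) &
        .data$p_value < alpha / dplyr::n(),
      direction = dplyr::case_when(
        is.na(.data$rho) ~ NA_character_,
        .data$rho > 0 ~ "resistance",
        .default = "sensitivity"
      )
    )
  new_result(res, "drug_association")
}

#' Resampling null for a set of target gene-drug pairs
#'
#' Compares the mean absolute correlation of a designated target pair set
#' against the same-size statistic from pairs drawn at random: each
#' iteration samples `length(target pairs)` pairs uniformly without
#' replacement from all non-target pairs with a defined rho, and the
#' empirical p-value is `(1 + #{null >= observed}) / (1 + n_iterations)`.
#' Deterministic for a fixed seed.
#'
#' @param associations a `drug_association` tibble
#'   (see [correlate_drug_expression()]).
#' @param target_pairs data frame with columns `gene`, `drug`; all pairs
#'   must be present in `associations`.
#' @param n_iterations number of resampling iterations (>= 100).
#' @param seed integer RNG seed.
#' @return a `resampling_comparison` list: `observed_stat`, `null_stats`,
#'   `empirical_p`, `n_iterations`, `seed`, `target_pairs`.
#' @export
resampling_null <- function(associations, target_pairs, n_iterations = 1000L,
                            seed = 1L) {
  stopifnot(nrow(target_pairs) >= 1L, n_iterations >= 100L)
  key <- function(d) paste(d$gene, d$drug, sep = "\r")
  assoc_keys <- key(associations)
  target_keys <- key(target_pairs)
  if (!all(target_keys %in% assoc_keys)) {
    stop("target pair(s) absent from associations", call. = FALSE)
  }
  is_target <- assoc_keys %in% target_keys
  observed <- mean(abs(associations$rho[is_target]), na.rm = TRUE)
  pool <- associations$rho[!is_target & !is.na(associations$rho)]
  k <- length(target_keys)
  if (length(pool) < k) {
    stop("fewer non-target pairs than target pairs", call. = FALSE)
  }
  set.seed(seed)
  null_stats <- vapply(
    seq_len(n_iterations),
    function(i) mean(abs(sample(pool, k))),
    numeric(1)
  )
  structure(
    list(
      target_pairs = tibble::as_tibble(target_pairs[c("gene", "drug")]),
      observed_stat = observed,
      null_stats = null_stats,
      empirical_p = (1 + sum(null_stats >= observed)) / (1 + n_iterations),
      n_iterations = as.integer(n_iterations),
      seed = as.integer(seed)
    ),
    class = "resampling_comparison"
  )
}

#' @export
print.resampling_comparison <- function(x, ...) {
  cat(
    "<resampling_comparison> ", nrow(x$target_pairs), " target pair(s), ",
    "observed mean |rho| = ", format(x$observed_stat, digits = 3),
    ", empirical p = ", format(x$empirical_p, digits = 3),
    " (", x$n_iterations, " iterations)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
glance.resampling_comparison <- function(x, ...) {
  tibble::tibble(
    n_target_pairs = nrow(x$target_pairs),
    observed_stat = x$observed_stat,
    null_mean = mean(x$null_stats),
    empirical_p = x$empirical_p,
    n_iterations = x$n_iterations
  )
}

#' Count Bonferroni-significant drugs per gene
#'
#' @param associations a `drug_association` tibble.
#' @return tibble `gene`, `n_significant`, `drugs` (list-column of
#'   significant drugs sorted by |rho| descending).
#' @export
drugs_per_gene <- function(associations) {
  associations |>
    dplyr::arrange(dplyr::desc(abs(.data$rho))) |>
    dplyr::summarise(
      n_significant = sum(.data$bonferroni_significant, na.rm = TRUE),
      drugs = list(.data$drug[which(.data$bonferroni_significant)]),
      .by = "gene"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_significant), .data$gene)
}
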