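#' Median-split log-rank survival association
#'
#' Samples are split at the gene's median expression (strictly greater goes
#' high, ties low) and the two groups' overall survival is compared with the
#' standard two-group log-rank test (observed/expected hypergeometric
#' accumulation over distinct event times; chi-square with 1 df). The
#' verdict is `unfavorable` when the high-expression group has the larger
#' observed-minus-expected death count and p is below `alpha`, `favorable`
#' in the opposite case, else `ns`. All-censored cohorts return `ns` with a
#' warning.
#'
#' @param expression a [gene_sample_matrix()] over tumor samples.
#' @param clinical data frame with columns `barcode`, `time` (>= 0),
#'   `event` (1 death, 0 censored).
#' @param gene gene symbol to test.
#' @param alpha significance gate (default 0.05; per-gene calls, no
#'   multiplicity correction — see [survival_associations()] for an optional
#'   BH variant).
#' @param min_samples minimum samples with both expression and survival.
#' @return a `survival_association` one-row tibble: `gene`, `logrank_chi2`,
#'   `p_value`, `n`, `n_events`, `verdict`.
#' @export
logrank_median_split <- function(expression, clinical, gene, alpha = 0.05,
                                 min_samples = 10L) {
  stopifnot(
    inherits(expression, "gene_sample_matrix"),
    all(c("barcode", "time", "event") %in% names(clinical))
  )
  if (any(clinical$time < 0) || !all(clinical$event %in% c(0, 1))) {
    stop("clinical table needs time >= 0 and binary event", call. = FALSE)
  }
  shared <- intersect(colnames(expression), clinical$barcode)
  if (length(shared) < min_samples) {
    stop("fewer than ", min_samples, " samples with expression and survival",
      call. = FALSE
    )
  }
  clin <- clinical[match(shared, clinical$barcode), ]
  expr <- unclass(expression)[gene, shared]
  high <- median_split(expr)
  empty_result <- function(verdict) {
    new_result(
      tibble::tibble(
        gene = gene, logrank_chi2 = NA_real_, p_value = NA_real_,
        n = length(shared), n_events = sum(clin$event), verdict = verdict
      ),
      "survival_association"
    )
  }
  if (sum(clin$event) == 0L) {
    warning("all samples censored for gene ", gene, "; returning ns",
      call. = FALSE
    )
    return(empty_result("ns"))
  }
  if (all(high) || !any(high)) {
    warning("median split empties a group for gene ", gene, "; skipped",
      call. = FALSE
    )
    return(empty_result(NA_character_))
  }
  df <- data.frame(time = clin$time, event = clin$event, high = high)
  fit <- survival::survdiff(
    survival::Surv(time, event) ~ high,
    data = df, rho = 0
  )
  chi2 <- unname(fit$chisq)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  # fit$obs/exp rows follow sort order of the grouping factor: FALSE, TRUE
  excess_high <- fit$obs[2] - fit$exp[2]
  verdict <- dplyr::case_when(
    p >= alpha ~ "ns",
    excess_high > 0 ~ "unfavorable",
    .default = "favorable"
  )
  new_result(
    tibble::tibble(
      gene = gene, logrank_chi2 = chi2, p_value = p,
      n = length(shared), n_events = sum(clin$event), verdict = verdict
    ),
    "survival_association"
  )
}

#' Survival associations for a set of genes
#'
#' Runs [logrank_median_split()] per gene. By default calls are per-gene at
#' `alpha` with no multiplicity correction (mirroring per-gene
#' favorable/unfavorable landscape calls); `adjust = TRUE` instead gates the
#' verdict on Benjamini-Hochberg-adjusted p-values.
#'
#' @inheritParams logrank_median_split
#' @param genes gene symbols (default: all rows of `expression`).
#' @param adjust apply BH across genes before calling verdicts?
#' @return a `survival_association` tibble, one row per gene.
#' @export
survival_associations <- function(expression, clinical,
                                  genes = rownames(expression),
                                  alpha = 0.05, adjust = FALSE,
                                  min_samples = 10L) {
  res <- purrr::map_dfr(genes, function(g) {
    logrank_median_split(expression, clinical, g,
      alpha = alpha,
      min_samples = min_samples
    )
  })
  if (adjust) {
    padj <- benjamini_hochberg(res$p_value)
    res$fdr <- padj
    res$verdict <- dplyr::case_when(
      is.na(res$verdict) ~ res$verdict,
      is.na(padj) | padj >= alpha ~ "ns",
      .default = res$verdict
    )
  }
  new_result(res, "survival_association")
}
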