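#' Classify a gene-level copy-number call
#'
#' Thresholded gene-level calls use the conventional 5-level coding:
#' -2 homozygous deletion, -1 heterozygous deletion, 0 neutral,
#' +1 heterozygous amplification, +2 homozygous amplification.
#'
#' @param call integer vector with values in \{-2, -1, 0, 1, 2\}.
#' @return character vector of event categories (`"homo_del"`, `"hete_del"`,
#'   `"none"`, `"hete_amp"`, `"homo_amp"`).
#' @examples
#' classify_call(c(-2, 0, 2))
#' @export
classify_call <- function(call) {
  if (any(!call %in% c(-2, -1, 0, 1, 2))) {
    stop(
      "copy-number call outside {-2,-1,0,1,2}: ",
      paste(utils::head(unique(call[!call %in% -2:2]), 3L), collapse = ", "),
      call. = FALSE
    )
  }
  c("homo_del", "hete_del", "none", "hete_amp", "homo_amp")[call + 3]
}

#' Per-gene copy-number event percentages
#'
#' For each gene, the percentage of samples carrying each of the four event
#' categories. The display rule mirrors the landscape convention: a gene is
#' `displayed` only when its CNV burden exceeds `display_pct` percent
#' (strictly) — by default the union of all four categories is compared
#' against the threshold; `display_rule = "per_category"` instead keeps a
#' gene when any single category exceeds it.
#'
#' @param calls a `cnv_call` [gene_sample_matrix()].
#' @param display_pct display threshold in percent (default 5, strict `>`).
#' @param display_rule `"union"` (default) or `"per_category"`.
#' @return a `cnv_profile` tibble: `gene`, `pct_hete_amp`, `pct_hete_del`,
#'   `pct_homo_amp`, `pct_homo_del`, `n_samples`, `displayed`.
#' @export
event_percentages <- function(calls, display_pct = 5,
                              display_rule = c("union", "per_category")) {
  stopifnot(inherits(calls, "gene_sample_matrix"))
  display_rule <- match.arg(display_rule)
  x <- unclass(calls)
  if (ncol(x) < 1L) stop("need at least one sample", call. = FALSE)
  n <- ncol(x)
  pct <- function(code) unname(100 * rowSums(x == code, na.rm = TRUE) / n)
  res <- tibble::tibble(
    gene = rownames(x),
    pct_hete_amp = pct(1), pct_hete_del = pct(-1),
    pct_homo_amp = pct(2), pct_homo_del = pct(-2),
    n_samples = n
  )
  cat_cols <- c("pct_hete_amp", "pct_hete_del", "pct_homo_amp", "pct_homo_del")
  res$displayed <- if (display_rule == "union") {
    rowSums(as.matrix(res[cat_cols])) > display_pct
  } else {
    apply(as.matrix(res[cat_cols]) > display_pct, 1, any)
  }
  new_result(res, "cnv_profile")
}

#' Copy-number / expression Spearman correlation
#'
#' Per gene, Spearman correlation (average ranks, t-approximation p) between
#' the integer copy-number call and log2 expression across the samples shared
#' by the two matrices, with Benjamini-Hochberg FDR across genes. Genes with
#' fewer than 3 complete pairs or a constant margin yield a missing-value
#' record.
#'
#' @param calls a `cnv_call` [gene_sample_matrix()].
#' @param expression a `raw_count` or `normalized_expression`
#'   [gene_sample_matrix()]; counts are log2(x+1)-transformed internally
#'   (rank-based, so any monotone transform gives the same rho).
#' @return a `cnv_correlation` tibble: `gene`, `rho`, `p_value`, `fdr`, `n`.
#' @export
cnv_expression_correlation <- function(calls, expression) {
  stopifnot(
    inherits(calls, "gene_sample_matrix"),
    inherits(expression, "gene_sample_matrix")
  )
  shared <- intersect(colnames(calls), colnames(expression))
  if (length(shared) < 3L) {
    stop("fewer than 3 samples shared between calls and expression",
      call. = FALSE
    )
  }
  genes <- intersect(rownames(calls), rownames(expression))
  expr <- log2(unclass(expression)[genes, shared, drop = FALSE] + 1)
  cl <- unclass(calls)[genes, shared, drop = FALSE]
  res <- purrr::map_dfr(genes, function(g) {
    dplyr::bind_cols(
      tibble::tibble(gene = g),
      spearman_test(cl[g, ], expr[g, ])
    )
  })
  res$fdr <- benjamini_hochberg(res$p_value)
  new_result(
    res[c("gene", "rho", "p_value", "fdr", "n")],
    "cnv_correlation"
  )
}
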