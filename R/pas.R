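#' Normalize RPPA component levels
#'
#' Each component (row) is centered on its median across patients and
#' divided by its standard deviation (n-1 sample convention), giving
#' relative protein levels with median exactly 0 per component; the
#' operation is idempotent on its own output. Zero-variance components are
#' dropped with a warning.
#'
#' @param protein a `protein_level` [gene_sample_matrix()] with >= 2 samples.
#' @return a normalized `protein_level` [gene_sample_matrix()].
#' @export
normalize_rppa <- function(protein) {
  stopifnot(inherits(protein, "gene_sample_matrix"))
  x <- unclass(protein)
  if (ncol(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(
      "dropping zero-variance component(s): ",
      paste(rownames(x)[sds == 0], collapse = ", "),
      call. = FALSE
    )
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  meds <- apply(x, 1, stats::median)
  gene_sample_matrix((x - meds) / sds, "protein_level")
}

#' Per-sample pathway activity score
#'
#' The PAS of a sample is the sign-weighted mean of its normalized member
#' levels: activating members (+1) add, inhibitory members (-1) subtract,
#' divided by the number of members present in the matrix. Members absent
#' from the matrix are skipped; a pathway with no member present is an
#' error.
#'
#' @param normalized a normalized `protein_level` [gene_sample_matrix()]
#'   (see [normalize_rppa()]).
#' @param members a data frame with columns `component` and `sign` (one
#'   pathway's membership), e.g. one group of [hallmark_pathways()].
#' @param pathway pathway name used in error messages.
#' @return named numeric vector of scores, one per sample.
#' @export
pathway_score <- function(normalized, members, pathway = "pathway") {
  stopifnot(inherits(normalized, "gene_sample_matrix"))
  present <- members[members$component %in% rownames(normalized), ]
  if (nrow(present) == 0L) {
    stop("no member of '", pathway, "' present in the matrix", call. = FALSE)
  }
  x <- unclass(normalized)[present$component, , drop = FALSE]
  colSums(x * present$sign) / nrow(present)
}

#' Pathway-activity association with gene expression
#'
#' For every (gene, pathway) pair: samples shared between the expression and
#' RPPA matrices are split at the gene's median expression (strictly greater
#' goes high, ties low), and the pathway activity scores of the two groups
#' are compared by Student's t-test. FDR is Benjamini-Hochberg across all
#' gene x pathway tests of the call (one cancer type). Verdict is
#' `activation` when the high group's mean PAS exceeds the low group's and
#' the FDR gate is met, `inhibition` symmetrically, else `none`.
#'
#' @param expression a [gene_sample_matrix()] over tumor samples.
#' @param rppa a `protein_level` [gene_sample_matrix()] (raw; normalized
#'   internally).
#' @param pathways pathway definition tibble (`pathway`, `component`,
#'   `sign`), default [hallmark_pathways()].
#' @param genes genes to test (default: all rows of `expression`).
#' @param fdr_cutoff FDR gate (default 0.05).
#' @return a `pas_association` tibble: `gene`, `pathway`, `mean_pas_high`,
#'   `mean_pas_low`, `p_value`, `fdr`, `verdict`.
#' @export
pas_associations <- function(expression, rppa, pathways = hallmark_pathways(),
                             genes = rownames(expression),
                             fdr_cutoff = 0.05) {
  stopifnot(
    inherits(expression, "gene_sample_matrix"),
    inherits(rppa, "gene_sample_matrix")
  )
  shared <- intersect(colnames(expression), colnames(rppa))
  if (length(shared) < 6L) {
    stop("need at least 6 samples with both expression and RPPA",
      call. = FALSE
    )
  }
  norm <- normalize_rppa(rppa[, shared, drop = FALSE])
  pw_names <- unique(pathways$pathway)
  scores <- vapply(
    pw_names,
    function(p) {
      pathway_score(norm, pathways[pathways$pathway == p, ], p)
    },
    numeric(length(shared))
  )
  expr <- unclass(expression)[genes, shared, drop = FALSE]
  res <- purrr::map_dfr(genes, function(g) {
    high <- median_split(expr[g, ])
    if (all(high) || !any(high)) {
      warning("median split empties a group for gene ", g, "; skipped",
        call. = FALSE
      )
      return(NULL)
    }
    purrr::map_dfr(pw_names, function(p) {
      fit <- two_sample_t(scores[high, p], scores[!high, p], pooled = TRUE)
      tibble::tibble(
        gene = g, pathway = p,
        mean_pas_high = fit$mean_x, mean_pas_low = fit$mean_y,
        p_value = fit$p_value
      )
    })
  })
  res$fdr <- benjamini_hochberg(res$p_value)
  res$verdict <- dplyr::case_when(
    res$mean_pas_high > res$mean_pas_low & res$fdr < fdr_cutoff ~ "activation",
    res$mean_pas_high < res$mean_pas_low & res$fdr < fdr_cutoff ~ "inhibition",
    .default = "none"
  )
  new_result(res, "pas_association")
}

#' Cross-cancer pathway-activity summary and heatmap filter
#'
#' Aggregates per-cancer associations: the percentage of tested cancers in
#' which a (gene, pathway) pair is activated (`pct_activated`, the red
#' "pathway_a" share) or inhibited (`pct_inhibited`, "pathway_i"), the
#' number of cancers in which the pair is functional at all, and the heatmap
#' filter keeping pairs functional in at least `min_cancers` cancer types
#' (boundary inclusive).
#'
#' @param associations a `pas_association` tibble carrying a `cancer`
#'   column (e.g. bound over cancers by [run_all()]).
#' @param min_cancers heatmap filter threshold (default 5, `>=`).
#' @return a `pas_summary` tibble: `gene`, `pathway`, `pct_activated`,
#'   `pct_inhibited`, `functional_in`, `n_cancers`, `heatmap_kept`.
#' @export
pas_global_summary <- function(associations, min_cancers = 5) {
  stopifnot(all(c("gene", "pathway", "cancer", "verdict") %in% names(associations)))
  res <- associations |>
    dplyr::summarise(
      pct_activated = 100 * mean(.data$verdict == "activation"),
      pct_inhibited = 100 * mean(.data$verdict == "inhibition"),
      functional_in = sum(.data$verdict != "none"),
      n_cancers = dplyr::n_distinct(.data$cancer),
      .by = c("gene", "pathway")
    ) |>
    dplyr::mutate(heatmap_kept = .data$functional_in >= min_cancers)
  new_result(res, "pas_summary")
}
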