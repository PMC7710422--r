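#' Plot a differential-expression landscape
#'
#' Bubble heatmap of genes by cancer types: point size encodes |log2 FC|,
#' color the direction, hollow points are non-significant.
#'
#' @param object a `de_result` tibble with a `cancer` column (e.g.
#'   `tidy(report, "de")`).
#' @param genes optional subset of genes to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.de_result <- function(object, genes = NULL, ...) {
  d <- if (is.null(genes)) object else dplyr::filter(object, .data$gene %in% genes)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$cancer, y = .data$gene,
      size = abs(.data$log2_fc), color = .data$log2_fc,
      alpha = .data$status != "ns"
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient2(
      low = "#2166AC", mid = "grey85", high = "#B2182B",
      name = "log2 FC"
    ) +
    ggplot2::scale_alpha_manual(
      values = c(`TRUE` = 1, `FALSE` = 0.25),
      name = "FDR < cutoff"
    ) +
    ggplot2::scale_size_area(max_size = 6, name = "|log2 FC|") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot copy-number event percentages
#'
#' Stacked bars of the four event categories per gene (and cancer when a
#' `cancer` column is present).
#'
#' @param object a `cnv_profile` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cnv_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
    dplyr::starts_with("pct_"),
    names_to = "event", names_prefix = "pct_", values_to = "pct"
  )
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$gene, y = .data$pct, fill = .data$event)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of samples", fill = "CNV event") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("cancer" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$cancer))
  }
  p
}

#' Plot the cross-cancer pathway-activity summary
#'
#' Heatmap of gene x pathway cells colored by the net activation percentage
#' (activated minus inhibited share of cancers); cells passing the
#' >=min-cancers filter are outlined.
#'
#' @param object a `pas_summary` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pas_summary <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$pathway, y = .data$gene,
      fill = .data$pct_activated - .data$pct_inhibited
    )
  ) +
    ggplot2::geom_tile(
      ggplot2::aes(color = .data$heatmap_kept),
      linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white", high = "#B2182B",
      name = "% activated - % inhibited"
    ) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "black", `FALSE` = NA),
      name = "kept (functional in >= min cancers)"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot drug-expression associations
#'
#' Dot plot of gene x drug correlations; positive rho (resistance) red,
#' negative (sensitivity) blue, Bonferroni-significant pairs at full
#' opacity.
#'
#' @param object a `drug_association` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.drug_association <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, !is.na(.data$rho)),
    ggplot2::aes(
      x = .data$drug, y = .data$gene,
      size = abs(.data$rho), color = .data$rho,
      alpha = .data$bonferroni_significant
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient2(
      low = "#2166AC", mid = "grey85", high = "#B2182B", name = "rho"
    ) +
    ggplot2::scale_alpha_manual(
      values = c(`TRUE` = 1, `FALSE` = 0.2), name = "Bonferroni"
    ) +
    ggplot2::scale_size_area(max_size = 5, name = "|rho|") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
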