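#' Analysis thresholds for the landscape pipeline
#'
#' Every printed threshold of the landscape analysis as a named
#' configuration object: fold-change 2 and FDR 0.05 for differential
#' expression, FDR 0.05 for methylation and pathway calls, the strict >5%
#' copy-number display rule, the inclusive >=5-cancer pathway heatmap
#' filter, family-wise alpha 0.05 (two-tailed Bonferroni) for drug
#' associations, per-gene alpha 0.05 for survival, and 1000 resampling
#' iterations.
#'
#' @param fold_change,fdr,cnv_display_pct,pas_min_cancers,bonferroni_alpha,survival_alpha,resampling_iterations
#'   see description.
#' @return a named list of thresholds.
#' @export
landscape_thresholds <- function(fold_change = 2, fdr = 0.05,
                                 cnv_display_pct = 5, pas_min_cancers = 5,
                                 bonferroni_alpha = 0.05,
                                 survival_alpha = 0.05,
                                 resampling_iterations = 1000L) {
  list(
    fold_change = fold_change, fdr = fdr,
    cnv_display_pct = cnv_display_pct, pas_min_cancers = pas_min_cancers,
    bonferroni_alpha = bonferroni_alpha, survival_alpha = survival_alpha,
    resampling_iterations = as.integer(resampling_iterations)
  )
}

landscape_stages <- function() {
  c(
    "de", "cnv", "methylation", "mutation", "pas", "drug", "survival"
  )
}

stage_layers <- function() {
  list(
    de = "counts", cnv = c("cnv", "counts"),
    methylation = c("meth", "counts"), mutation = "maf",
    pas = c("rppa", "counts"), survival = c("clinical", "counts")
  )
}

#' Run the full multi-omic landscape over a cohort
#'
#' Orchestrates every analysis stage over a (typically synthetic) cohort
#' bundle: per-cancer differential expression, copy-number event profiles
#' and dosage correlation, differential methylation and
#' methylation-expression correlation, mutation summarization,
#' pathway-activity association plus the cross-cancer summary, cell-line
#' drug association, and survival association. Inputs are validated up
#' front: a missing layer for an enabled stage aborts before any stage runs.
#' Given a fixed cohort the report is deterministic.
#'
#' @param cohort an `omic_cohort` from [generate_cohort()] (or any list with
#'   the same shape).
#' @param stages which stages to run (default all).
#' @param thresholds a [landscape_thresholds()] list.
#' @param genes genes to analyze (default: the cohort's target genes plus
#'   background, i.e. every gene).
#' @return a `landscape_report`: `tables` (named list of result tibbles,
#'   each carrying a `cancer` column where applicable) and `metadata`
#'   (thresholds, seed, config hash, timestamp, package version).
#' @export
run_all <- function(cohort, stages = landscape_stages(),
                    thresholds = landscape_thresholds(),
                    genes = NULL) {
  stages <- match.arg(stages, landscape_stages(), several.ok = TRUE)
  cancers <- names(cohort$cohorts)
  # fail fast: every enabled stage must find its layers in every cancer
  need <- stage_layers()
  for (stage in intersect(stages, names(need))) {
    for (cancer in cancers) {
      absent <- setdiff(need[[stage]], names(cohort$cohorts[[cancer]]))
      if (length(absent) > 0L) {
        stop(
          "stage '", stage, "' enabled but layer(s) missing for ", cancer,
          ": ", paste(absent, collapse = ", "),
          call. = FALSE
        )
      }
    }
  }
  if ("drug" %in% stages && is.null(cohort$cell_lines)) {
    stop("stage 'drug' enabled but cell-line layer missing", call. = FALSE)
  }

  per_cancer <- function(f) {
    purrr::map_dfr(cancers, function(cn) {
      dplyr::mutate(f(cohort$cohorts[[cn]]), cancer = cn, .before = 1)
    })
  }
  groups_of <- function(layer) match_tumor_normal(layer)
  tables <- list()
  if ("de" %in% stages) {
    tables$de <- per_cancer(function(cc) {
      g <- groups_of(cc$counts)
      differential_expression(cc$counts, g$tumors, g$normals,
        fc_cutoff = thresholds$fold_change, fdr_cutoff = thresholds$fdr
      )
    })
  }
  if ("cnv" %in% stages) {
    tables$cnv_profile <- per_cancer(function(cc) {
      event_percentages(cc$cnv, display_pct = thresholds$cnv_display_pct)
    })
    tables$cnv_correlation <- per_cancer(function(cc) {
      cnv_expression_correlation(cc$cnv, cc$counts)
    })
  }
  if ("methylation" %in% stages) {
    tables$meth_diff <- per_cancer(function(cc) {
      g <- groups_of(cc$meth)
      differential_methylation(cc$meth, g$tumors, g$normals,
        fdr_cutoff = thresholds$fdr
      )
    })
    tables$meth_correlation <- per_cancer(function(cc) {
      methylation_expression_correlation(cc$meth, cc$counts)
    })
  }
  if ("mutation" %in% stages) {
    genes_of <- function(cc) {
      if (is.null(genes)) rownames(cc$counts %||% NULL) else genes
    }
    tables$mutation <- per_cancer(function(cc) {
      mutation_frequency(cc$maf, genes = genes_of(cc))
    })
    tables$mutation_classes <- per_cancer(function(cc) {
      mutation_class_spectrum(cc$maf)
    })
  }
  if ("pas" %in% stages) {
    tables$pas_association <- per_cancer(function(cc) {
      g <- groups_of(cc$counts)
      pas_associations(
        cc$counts[, g$tumors], cc$rppa,
        pathways = cohort$pathways,
        genes = if (is.null(genes)) rownames(cc$counts) else genes,
        fdr_cutoff = thresholds$fdr
      )
    })
    tables$pas_summary <- pas_global_summary(
      tables$pas_association,
      min_cancers = thresholds$pas_min_cancers
    )
  }
  if ("drug" %in% stages) {
    tables$drug <- correlate_drug_expression(
      cohort$cell_lines$expression, cohort$cell_lines$auc,
      alpha = thresholds$bonferroni_alpha
    )
  }
  if ("survival" %in% stages) {
    tables$survival <- per_cancer(function(cc) {
      g <- groups_of(cc$counts)
      survival_associations(
        cc$counts[, g$tumors], cc$clinical,
        genes = if (is.null(genes)) rownames(cc$counts) else genes,
        alpha = thresholds$survival_alpha
      )
    })
  }
  structure(
    list(
      tables = tables,
      metadata = list(
        stages = stages,
        thresholds = thresholds,
        seed = cohort$config$seed %||% NA_integer_,
        config_hash = rlang::hash(cohort$config),
        package_version = as.character(utils::packageVersion("panlandscape")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "landscape_report"
  )
}

#' @export
print.landscape_report <- function(x, ...) {
  cat("<landscape_report> tables:\n")
  for (nm in names(x$tables)) {
    cat("  ", format(nm, width = 18), nrow(x$tables[[nm]]), "rows\n")
  }
  invisible(x)
}

#' @export
glance.landscape_report <- function(x, ...) {
  tibble::tibble(
    n_tables = length(x$tables),
    n_cancers = dplyr::n_distinct(x$tables[[1]]$cancer %||% character()),
    seed = x$metadata$seed,
    config_hash = x$metadata$config_hash
  )
}

#' @export
#' @param x a `landscape_report`.
#' @param table which result table to extract.
#' @param ... unused.
#' @rdname run_all
tidy.landscape_report <- function(x, table = names(x$tables)[1], ...) {
  table <- rlang::arg_match(table, names(x$tables))
  tibble::as_tibble(x$tables[[table]])
}

#' Serialize / parse a landscape report
#'
#' `write_report()` writes each result table as a TSV plus a `metadata.json`
#' into a directory; `read_report()` parses them back. Numeric columns
#' round-trip exactly (shortest round-trip representation).
#'
#' @param report a `landscape_report`.
#' @param dir output directory (created if needed).
#' @return `write_report()` returns `dir` invisibly; `read_report()` a
#'   `landscape_report`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "landscape_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables)) {
    tab <- report$tables[[nm]]
    tab <- tab[!vapply(tab, is.list, TRUE)] # list-columns are derived views
    readr::write_tsv(tab, file.path(dir, paste0(nm, ".tsv")),
      na = "NA", progress = FALSE
    )
  }
  jsonlite::write_json(
    report$metadata,
    file.path(dir, "metadata.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
    simplifyVector = TRUE
  )
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  tables <- lapply(files, function(f) {
    raw <- readr::read_tsv(f,
      na = "NA", progress = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
    # exact strtod conversion: vroom's fast double parser can be one ulp off
    raw[] <- lapply(raw, function(col) {
      utils::type.convert(col, as.is = TRUE, na.strings = "NA")
    })
    raw
  })
  names(tables) <- sub("\\.tsv$", "", basename(files))
  structure(list(tables = tables, metadata = meta),
    class = "landscape_report"
  )
}

#' Score a landscape report against the planted truth
#'
#' For each stage with a significance concept, compares the report's calls
#' to the generator's planted-effect registry: `sensitivity` is the fraction
#' of planted effects called significant with the correct sign,
#' `false_discovery` the fraction of significant calls that land on
#' zero-effect entries, and `sign_accuracy` the fraction of significant
#' planted calls whose sign matches the plant. The mutation stage has no
#' significance test; its sensitivity is the fraction of planted
#' frequencies whose estimate falls within +/-7 percentage points of the
#' expected non-silent frequency (0.9 x planted under the generator's
#' variant-class mix), and its other scores are `NA`.
#'
#' @param report a `landscape_report` produced from the same cohort as
#'   `truth`.
#' @param truth the `truth` component of [generate_cohort()].
#' @return a tibble: `stage`, `sensitivity`, `false_discovery`,
#'   `sign_accuracy`, `n_planted`, `n_significant`.
#' @export
score_against_truth <- function(report, truth) {
  stopifnot(inherits(report, "landscape_report"))
  if (length(report$tables) == 0L) stop("empty report", call. = FALSE)
  rows <- list()
  score <- function(stage, calls, planted_keys, call_flag, sign_ok) {
    is_planted <- calls$.key %in% planted_keys
    sig <- call_flag & !is.na(call_flag)
    rows[[stage]] <<- tibble::tibble(
      stage = stage,
      sensitivity = if (any(is_planted)) {
        mean(sig[is_planted] & sign_ok[is_planted], na.rm = TRUE)
      } else {
        NA_real_
      },
      false_discovery = if (any(sig)) mean(!is_planted[sig]) else 0,
      sign_accuracy = if (any(sig & is_planted)) {
        mean(sign_ok[sig & is_planted], na.rm = TRUE)
      } else {
        NA_real_
      },
      n_planted = sum(is_planted),
      n_significant = sum(sig)
    )
  }

  tab <- report$tables
  if (!is.null(tab$de)) {
    d <- dplyr::left_join(
      dplyr::mutate(tab$de, .key = paste(.data$gene, .data$cancer)),
      dplyr::mutate(truth$de_log2fc, .key = paste(.data$gene, .data$cancer)),
      by = ".key"
    )
    planted <- d$.key[!is.na(d$log2fc) & d$log2fc != 0]
    check_universe(tab$de$gene, truth$de_log2fc$gene)
    score(
      "de", d, planted, d$status != "ns",
      sign(d$log2_fc) == sign(dplyr::coalesce(d$log2fc, 0))
    )
  }
  if (!is.null(tab$cnv_correlation)) {
    d <- dplyr::left_join(
      dplyr::mutate(tab$cnv_correlation, .key = paste(.data$gene, .data$cancer)),
      truth$cnv_dosage_slope,
      by = "gene"
    )
    planted <- d$.key[!is.na(d$slope) & d$slope != 0]
    score(
      "cnv", d, planted, d$fdr < 0.05,
      sign(d$rho) == sign(dplyr::coalesce(d$slope, 0))
    )
  }
  if (!is.null(tab$meth_diff)) {
    d <- dplyr::left_join(
      dplyr::mutate(tab$meth_diff, .key = paste(.data$gene, .data$cancer)),
      dplyr::mutate(truth$meth_effect, .key = paste(.data$gene, .data$cancer)),
      by = ".key"
    )
    planted <- d$.key[!is.na(d$delta_beta.y) & d$delta_beta.y != 0]
    score(
      "methylation", d, planted, d$direction != "ns",
      sign(d$delta_beta.x) == sign(dplyr::coalesce(d$delta_beta.y, 0))
    )
  }
  if (!is.null(tab$mutation)) {
    d <- dplyr::left_join(
      dplyr::mutate(tab$mutation, .key = paste(.data$gene, .data$cancer)),
      dplyr::mutate(truth$mut_freq, .key = paste(.data$gene, .data$cancer)),
      by = ".key"
    )
    planted <- !is.na(d$freq) & d$freq > 0
    recovered <- abs(d$frequency_pct - 90 * dplyr::coalesce(d$freq, 0)) <= 7
    rows$mutation <- tibble::tibble(
      stage = "mutation",
      sensitivity = if (any(planted)) mean(recovered[planted]) else NA_real_,
      false_discovery = NA_real_, sign_accuracy = NA_real_,
      n_planted = sum(planted), n_significant = NA_integer_
    )
  }
  if (!is.null(tab$pas_association)) {
    d <- dplyr::left_join(
      dplyr::mutate(tab$pas_association,
        .key = paste(.data$gene, .data$pathway, .data$cancer)
      ),
      dplyr::mutate(truth$pas_shift,
        .key = paste(.data$gene, .data$pathway, .data$cancer)
      ),
      by = ".key"
    )
    planted <- d$.key[!is.na(d$shift) & d$shift != 0]
    score(
      "pas", d, planted, d$verdict != "none",
      (d$verdict == "activation") == (dplyr::coalesce(d$shift, 0) > 0)
    )
  }
  if (!is.null(tab$drug)) {
    d <- dplyr::left_join(
      dplyr::mutate(tab$drug, .key = paste(.data$gene, .data$drug)),
      dplyr::mutate(truth$drug_rho,
        .key = paste(.data$gene, .data$drug),
        planted_rho = .data$rho
      )[c(".key", "planted_rho")],
      by = ".key"
    )
    planted <- d$.key[!is.na(d$planted_rho) & d$planted_rho != 0]
    score(
      "drug", d, planted, d$bonferroni_significant,
      sign(d$rho) == sign(dplyr::coalesce(d$planted_rho, 0))
    )
  }
  if (!is.null(tab$survival)) {
    d <- dplyr::left_join(
      dplyr::mutate(tab$survival, .key = paste(.data$gene, .data$cancer)),
      dplyr::mutate(truth$hazard_direction,
        .key = paste(.data$gene, .data$cancer)
      ),
      by = ".key"
    )
    planted <- d$.key[!is.na(d$direction)]
    score(
      "survival", d, planted, d$verdict %in% c("favorable", "unfavorable"),
      d$verdict == dplyr::coalesce(d$direction, "")
    )
  }
  dplyr::bind_rows(rows)
}

check_universe <- function(report_genes, truth_genes) {
  stray <- setdiff(truth_genes, report_genes)
  if (length(stray) > 0L) {
    stop("gene universe mismatch between report and truth: ",
      paste(utils::head(stray, 3L), collapse = ", "),
      call. = FALSE
    )
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
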