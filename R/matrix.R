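#' Gene-by-sample matrices with declared value semantics
#'
#' The pipeline moves every omic layer around as a plain numeric matrix
#' (genes in rows, samples or cell lines in columns) carrying a `semantics`
#' attribute that states what the numbers are. Validation is semantics-aware:
#' beta values must lie in \[0, 1\], copy-number calls in \{-2, -1, 0, 1, 2\},
#' raw counts must be non-negative integers.
#'
#' @param values numeric matrix (or coercible) with gene symbols as rownames
#'   and sample identifiers as colnames.
#' @param semantics one of `"raw_count"`, `"normalized_expression"`, `"beta"`,
#'   `"cnv_call"`, `"protein_level"`, `"drug_auc"`.
#' @return a `gene_sample_matrix`: a numeric matrix with a `semantics`
#'   attribute.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("TP53", "EGFR"), c("S1", "S2")))
#' gene_sample_matrix(m, "raw_count")
#' @export
gene_sample_matrix <- function(values, semantics) {
  semantics <- rlang::arg_match(semantics, gsm_semantics())
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  x <- structure(values,
    semantics = semantics,
    class = c("gene_sample_matrix", "matrix", "array")
  )
  validate_gsm(x)
}

#' @rdname gene_sample_matrix
#' @export
gsm_semantics <- function() {
  c(
    "raw_count", "normalized_expression", "beta", "cnv_call",
    "protein_level", "drug_auc"
  )
}

#' @export
`[.gene_sample_matrix` <- function(x, i, j, drop = FALSE) {
  y <- unclass(x)
  if ((nargs() - !missing(drop)) < 3L) { # linear indexing x[i]: plain vector
    return(if (missing(i)) y else y[i])
  }
  out <- if (missing(i) && missing(j)) {
    y
  } else if (missing(i)) {
    y[, j, drop = drop]
  } else if (missing(j)) {
    y[i, , drop = drop]
  } else {
    y[i, j, drop = drop]
  }
  if (is.matrix(out)) {
    structure(out,
      semantics = attr(x, "semantics"),
      class = c("gene_sample_matrix", "matrix", "array")
    )
  } else {
    out
  }
}

#' @export
print.gene_sample_matrix <- function(x, ...) {
  cat(
    "<gene_sample_matrix> ", nrow(x), " genes x ", ncol(x), " samples, ",
    "semantics: ", attr(x, "semantics"), "\n",
    sep = ""
  )
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

validate_gsm <- function(x) {
  sem <- attr(x, "semantics")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("gene_sample_matrix needs gene rownames and sample colnames",
      call. = FALSE
    )
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene symbols: ",
      paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample identifiers: ",
      paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
      call. = FALSE
    )
  }
  v <- x[!is.na(x)]
  bad <- switch(sem,
    beta = v < 0 | v > 1,
    cnv_call = !v %in% c(-2, -1, 0, 1, 2),
    raw_count = v < 0 | v != round(v),
    rep(FALSE, length(v))
  )
  if (any(bad)) {
    stop(
      sprintf(
        "%d value(s) violate '%s' semantics (first offender: %s)",
        sum(bad), sem, format(v[bad][1])
      ),
      call. = FALSE
    )
  }
  x
}

#' Read / write a gene-by-sample matrix as TSV
#'
#' Matrices are exchanged as dense tab-separated files: first column `gene`,
#' header row of sample identifiers, missing values written as `NA`. Writing
#' then reading reproduces values exactly (readr emits shortest round-trip
#' representations of doubles).
#'
#' @param path file path.
#' @param semantics declared value semantics, see [gene_sample_matrix()].
#' @return `read_matrix()` returns a [gene_sample_matrix()];
#'   `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path, semantics) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "NA", progress = FALSE
  )
  if (ncol(raw) < 2L || names(raw)[1] != "gene") {
    stop("expected a 'gene' first column followed by sample columns",
      call. = FALSE
    )
  }
  genes <- raw$gene
  vals <- as.matrix(raw[-1])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(
      sprintf(
        "non-numeric cell at row %d (gene %s), column %s: '%s'",
        bad[1, 1], genes[bad[1, 1]], colnames(vals)[bad[1, 2]],
        vals[bad[1, 1], bad[1, 2]]
      ),
      call. = FALSE
    )
  }
  dimnames(num) <- list(genes, colnames(vals))
  gene_sample_matrix(num, semantics)
}

#' @rdname read_matrix
#' @param x a [gene_sample_matrix()].
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "gene_sample_matrix"))
  out <- dplyr::bind_cols(
    tibble::tibble(gene = rownames(x)),
    tibble::as_tibble(unclass(x))
  )
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Long-format view of a gene-by-sample matrix
#'
#' @param x a [gene_sample_matrix()].
#' @param ... unused.
#' @return a tibble with columns `gene`, `sample`, `value`.
#' @export
tidy.gene_sample_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value")
}
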