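#' Parse TCGA-style sample barcodes
#'
#' Barcodes such as `TCGA-A1-A0SB-01A` are split at dashes: field 1 is the
#' project, field 3 the participant identifier, and the first two characters
#' of field 4 the numeric sample-type code. Codes 01-09 are tumor-derived,
#' 10-19 normal-derived (01 = primary tumor and 11 = solid tissue normal are
#' the codes used throughout this package); any trailing letter of field 4 is
#' the vial. Extra fields (portion, plate, center) are ignored. A tumor sample
#' and its matched normal share the participant identifier, which is how omic
#' layers are matched to each other.
#'
#' @param raw character vector of barcodes.
#' @return a tibble with one row per barcode: `barcode`, `project`,
#'   `participant`, `sample_code` (integer), `vial`, and `sample_type`
#'   (`"tumor"`, `"normal"` or `"other"`).
#' @examples
#' parse_barcode(c("TCGA-A1-A0SB-01A", "TCGA-A1-A0SB-11A"))
#' @export
parse_barcode <- function(raw) {
  stopifnot(is.character(raw))
  fields <- strsplit(raw, "-", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 4L)) {
    stop(
      "malformed barcode (need >= 4 dash-separated fields): ",
      paste(utils::head(raw[n_fields < 4L], 3L), collapse = ", "),
      call. = FALSE
    )
  }
  f4 <- vapply(fields, `[[`, "", 4L)
  code_chr <- substr(f4, 1L, 2L)
  if (any(!grepl("^[0-9]{2}$", code_chr))) {
    bad <- raw[!grepl("^[0-9]{2}$", code_chr)][1]
    stop("malformed sample-code field (need two leading digits): ", bad,
      call. = FALSE
    )
  }
  code <- as.integer(code_chr)
  tibble::tibble(
    barcode = raw,
    project = vapply(fields, `[[`, "", 1L),
    participant = vapply(fields, `[[`, "", 3L),
    sample_code = code,
    vial = ifelse(nchar(f4) > 2L, substr(f4, 3L, 3L), NA_character_),
    sample_type = dplyr::case_when(
      code >= 1L & code <= 9L ~ "tumor",
      code >= 10L & code <= 19L ~ "normal",
      .default = "other"
    )
  )
}

#' Split a cohort into tumor/normal samples and matched participants
#'
#' @param x a [gene_sample_matrix()] whose colnames are barcodes, or a
#'   character vector of barcodes.
#' @return a list with `tumors` and `normals` (barcode vectors) and `pairs`,
#'   a tibble of participants having both a tumor and a normal sample, with
#'   their barcodes. Zero matched pairs raises a warning, not an error.
#' @examples
#' match_tumor_normal(c("TCGA-A1-P1-01A", "TCGA-A1-P1-11A", "TCGA-A1-P2-01A"))
#' @export
match_tumor_normal <- function(x) {
  samples <- if (inherits(x, "gene_sample_matrix")) colnames(x) else x
  if (anyDuplicated(samples)) {
    stop("duplicated barcode(s): ",
      paste(unique(samples[duplicated(samples)]), collapse = ", "),
      call. = FALSE
    )
  }
  info <- parse_barcode(samples)
  tumors <- dplyr::filter(info, .data$sample_type == "tumor")
  normals <- dplyr::filter(info, .data$sample_type == "normal")
  pairs <- dplyr::inner_join(
    dplyr::distinct(tumors, .data$participant, tumor = .data$barcode),
    dplyr::distinct(normals, .data$participant, normal = .data$barcode),
    by = "participant"
  )
  if (nrow(pairs) == 0L) {
    warning("no matched tumor/normal participant pairs found", call. = FALSE)
  }
  list(
    tumors = tumors$barcode,
    normals = normals$barcode,
    pairs = pairs
  )
}
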