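#' Somatic mutation tables (MAF)
#'
#' A `maf_table` bundles somatic variant records with the full cohort sample
#' universe, so that samples without any mutation still enter frequency
#' denominators. Records keep every variant, including `Silent`; filtering is
#' a downstream choice.
#'
#' @param records a data frame with columns `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Variant_Classification`, `Reference_Allele`,
#'   `Tumor_Seq_Allele2`.
#' @param cohort_samples character vector of all sample barcodes in the
#'   cohort; every record's sample must be among them.
#' @return a `maf_table` object.
#' @export
maf_table <- function(records, cohort_samples) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(maf_required_columns(), names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required MAF column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_class <- setdiff(
    unique(records$Variant_Classification),
    maf_classifications()
  )
  if (length(bad_class) > 0L) {
    stop(
      "unknown Variant_Classification token(s): ",
      paste(bad_class, collapse = ", "),
      "; allowed: ", paste(maf_classifications(), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(cohort_samples)) {
    stop("duplicated cohort sample(s)", call. = FALSE)
  }
  orphan <- setdiff(records$Tumor_Sample_Barcode, cohort_samples)
  if (length(orphan) > 0L) {
    stop("record sample(s) not in cohort_samples: ",
      paste(utils::head(orphan, 3L), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      records = records[maf_required_columns()],
      cohort_samples = cohort_samples
    ),
    class = "maf_table"
  )
}

maf_required_columns <- function() {
  c(
    "Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
    "Reference_Allele", "Tumor_Seq_Allele2"
  )
}

#' Standard MAF variant-classification vocabulary
#' @return character vector of allowed classification tokens.
#' @export
maf_classifications <- function() {
  c(
    "Missense_Mutation", "Nonsense_Mutation", "Silent", "Frame_Shift_Del",
    "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
    "Nonstop_Mutation", "Translation_Start_Site"
  )
}

#' @export
print.maf_table <- function(x, ...) {
  cat(
    "<maf_table> ", nrow(x$records), " records, ",
    length(unique(x$records$Tumor_Sample_Barcode)), " mutated of ",
    length(x$cohort_samples), " cohort samples\n",
    sep = ""
  )
  print(utils::head(x$records))
  invisible(x)
}

#' @export
tidy.maf_table <- function(x, ...) x$records

#' @export
glance.maf_table <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records),
    n_genes = dplyr::n_distinct(x$records$Hugo_Symbol),
    n_mutated_samples = dplyr::n_distinct(x$records$Tumor_Sample_Barcode),
    n_cohort_samples = length(x$cohort_samples)
  )
}

#' Read / write a MAF file
#'
#' Tab-separated with at least the five standard columns (`Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`); extra columns are ignored on read.
#'
#' @param path file path.
#' @param cohort_samples full cohort sample universe (see [maf_table()]).
#' @return `read_maf()` returns a [maf_table()]; `write_maf()` returns
#'   `path` invisibly.
#' @export
read_maf <- function(path, cohort_samples) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  maf_table(raw, cohort_samples)
}

#' @rdname read_maf
#' @param x a [maf_table()].
#' @export
write_maf <- function(x, path) {
  stopifnot(inherits(x, "maf_table"))
  readr::write_tsv(x$records, path, progress = FALSE)
  invisible(path)
}
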