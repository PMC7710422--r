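#' Per-gene somatic mutation frequency
#'
#' A sample counts as mutated for a gene when it carries at least one
#' non-silent record for that gene (once per sample, however many variants);
#' the denominator is the full cohort universe, so samples with no mutations
#' dilute the frequency. `Silent` records can be counted too via
#' `include_silent = TRUE`. Output is ordered by descending frequency, then
#' gene name.
#'
#' @param maf a [maf_table()].
#' @param genes genes to summarize (a gene absent from the MAF gets
#'   frequency 0); defaults to all genes present.
#' @param include_silent count `Silent` variants toward frequency?
#' @return a `mutation_summary` tibble: `gene`, `n_mutated_samples`,
#'   `n_cohort_samples`, `frequency_pct`.
#' @export
mutation_frequency <- function(maf, genes = NULL, include_silent = FALSE) {
  stopifnot(inherits(maf, "maf_table"))
  if (length(maf$cohort_samples) == 0L) {
    stop("cohort_samples is empty", call. = FALSE)
  }
  if (is.null(genes)) genes <- sort(unique(maf$records$Hugo_Symbol))
  recs <- maf$records
  if (!include_silent) {
    recs <- dplyr::filter(recs, .data$Variant_Classification != "Silent")
  }
  counted <- recs |>
    dplyr::filter(.data$Hugo_Symbol %in% genes) |>
    dplyr::distinct(.data$Hugo_Symbol, .data$Tumor_Sample_Barcode) |>
    dplyr::count(gene = .data$Hugo_Symbol, name = "n_mutated_samples")
  res <- tibble::tibble(gene = genes) |>
    dplyr::left_join(counted, by = "gene") |>
    dplyr::mutate(
      n_mutated_samples = dplyr::coalesce(.data$n_mutated_samples, 0L),
      n_cohort_samples = length(maf$cohort_samples),
      frequency_pct = 100 * .data$n_mutated_samples / .data$n_cohort_samples
    ) |>
    dplyr::arrange(dplyr::desc(.data$frequency_pct), .data$gene)
  new_result(res, "mutation_summary")
}

#' Collapse a single-base substitution to its pyrimidine-context class
#'
#' Substitutions are reported in the six pyrimidine-reference classes
#' (C>A, C>G, C>T, T>A, T>C, T>G); purine-reference substitutions are
#' complemented (G>C becomes C>G, A>G becomes T>C, ...). Indels (`-` allele)
#' and multi-base alleles are `"non-SNV"`.
#'
#' @param ref,alt allele strings over the alphabet \{A, C, G, T, -\}.
#' @return character vector of classes.
#' @examples
#' snv_class(c("C", "G", "A"), c("G", "C", "-"))
#' @export
snv_class <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  ok <- grepl("^[ACGT-]+$", ref) & grepl("^[ACGT-]+$", alt)
  if (any(!ok)) {
    stop("invalid allele character in: ",
      paste(utils::head(paste(ref[!ok], alt[!ok], sep = ">"), 3L), collapse = ", "),
      call. = FALSE
    )
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep("non-SNV", length(ref))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  r <- ref[snv]
  a <- alt[snv]
  flip <- r %in% c("A", "G")
  r[flip] <- comp[r[flip]]
  a[flip] <- comp[a[flip]]
  out[snv] <- paste(r, a, sep = ">")
  out
}

#' Variant-classification and SNV-class spectra per gene
#'
#' `mutation_class_spectrum()` counts records by variant classification
#' (Silent retained with its own label); `snv_class_spectrum()` counts
#' single-base substitutions by pyrimidine-context class.
#'
#' @inheritParams mutation_frequency
#' @return tibbles `gene`, `classification`/`snv_class`, `n`.
#' @export
mutation_class_spectrum <- function(maf, genes = NULL) {
  stopifnot(inherits(maf, "maf_table"))
  recs <- maf$records
  if (!is.null(genes)) recs <- dplyr::filter(recs, .data$Hugo_Symbol %in% genes)
  dplyr::count(recs,
    gene = .data$Hugo_Symbol,
    classification = .data$Variant_Classification
  )
}

#' @rdname mutation_class_spectrum
#' @export
snv_class_spectrum <- function(maf, genes = NULL) {
  stopifnot(inherits(maf, "maf_table"))
  recs <- maf$records
  if (!is.null(genes)) recs <- dplyr::filter(recs, .data$Hugo_Symbol %in% genes)
  recs |>
    dplyr::mutate(
      snv_class = snv_class(.data$Reference_Allele, .data$Tumor_Seq_Allele2)
    ) |>
    dplyr::filter(.data$snv_class != "non-SNV") |>
    dplyr::count(gene = .data$Hugo_Symbol, .data$snv_class)
}

#' Per-sample variant burden by classification
#'
#' Counts records per (sample, classification), taking the input literally
#' (duplicated rows count twice). The output is cohort-complete: samples
#' with no records appear with a zero total, and counts over all samples and
#' classes sum to the number of records.
#'
#' @param maf a [maf_table()].
#' @return tibble `sample`, `classification`, `n` (classification `NA` with
#'   `n = 0` for unmutated samples).
#' @export
per_sample_summary <- function(maf) {
  stopifnot(inherits(maf, "maf_table"))
  counts <- dplyr::count(maf$records,
    sample = .data$Tumor_Sample_Barcode,
    classification = .data$Variant_Classification
  )
  silent_samples <- setdiff(maf$cohort_samples, counts$sample)
  dplyr::bind_rows(
    counts,
    tibble::tibble(
      sample = silent_samples, classification = NA_character_, n = 0L
    )
  ) |>
    dplyr::arrange(.data$sample, .data$classification)
}

#' Gene-by-sample classification matrix (oncoplot layout)
#'
#' One row per gene, one column per cohort sample; each cell holds the
#' sample's variant classification for that gene (`Multi_Hit` when several
#' distinct classes are present, `NA` when unmutated).
#'
#' @inheritParams mutation_frequency
#' @return character matrix genes x cohort samples.
#' @export
oncoplot_matrix <- function(maf, genes = NULL) {
  stopifnot(inherits(maf, "maf_table"))
  if (is.null(genes)) genes <- sort(unique(maf$records$Hugo_Symbol))
  cells <- maf$records |>
    dplyr::filter(.data$Hugo_Symbol %in% genes) |>
    dplyr::distinct(
      .data$Hugo_Symbol, .data$Tumor_Sample_Barcode,
      .data$Variant_Classification
    ) |>
    dplyr::summarise(
      value = if (dplyr::n() > 1L) "Multi_Hit" else .data$Variant_Classification[1],
      .by = c("Hugo_Symbol", "Tumor_Sample_Barcode")
    )
  out <- matrix(NA_character_,
    nrow = length(genes), ncol = length(maf$cohort_samples),
    dimnames = list(genes, maf$cohort_samples)
  )
  out[cbind(cells$Hugo_Symbol, cells$Tumor_Sample_Barcode)] <- cells$value
  out
}
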