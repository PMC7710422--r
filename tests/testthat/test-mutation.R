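make_toy_maf <- function() {
  cohort <- tumor_barcodes(4)
  records <- tibble::tibble(
    Hugo_Symbol = c("G", "G", "G", "G"),
    Tumor_Sample_Barcode = cohort[c(1, 2, 2, 3)],
    Variant_Classification = c(
      "Missense_Mutation", "Missense_Mutation", "Nonsense_Mutation", "Silent"
    ),
    Reference_Allele = c("C", "G", "A", "T"),
    Tumor_Seq_Allele2 = c("G", "C", "T", "C")
  )
  maf_table(records, cohort)
}

test_that("mutation frequency counts each sample once and excludes Silent by default", {
  maf <- make_toy_maf()
  # S1 missense, S2 missense+nonsense, S3 silent-only: 2 of 4 = 50%
  freq <- mutation_frequency(maf, genes = "G")
  expect_equal(freq$n_mutated_samples, 2L)
  expect_equal(freq$frequency_pct, 50)
  # silent included: S3 now counts -> 75%
  freq_s <- mutation_frequency(maf, genes = "G", include_silent = TRUE)
  expect_equal(freq_s$frequency_pct, 75)
  # absent gene: zero, not an error
  freq_a <- mutation_frequency(maf, genes = c("G", "ABSENT"))
  expect_equal(
    freq_a$frequency_pct[freq_a$gene == "ABSENT"], 0
  )
})

test_that("frequency edge cases: empty MAF, full saturation, record-order invariance", {
  cohort <- tumor_barcodes(3)
  empty <- maf_table(
    tibble::tibble(
      Hugo_Symbol = character(), Tumor_Sample_Barcode = character(),
      Variant_Classification = character(), Reference_Allele = character(),
      Tumor_Seq_Allele2 = character()
    ),
    cohort
  )
  expect_equal(mutation_frequency(empty, genes = "G")$frequency_pct, 0)

  full <- maf_table(
    tibble::tibble(
      Hugo_Symbol = "G", Tumor_Sample_Barcode = cohort,
      Variant_Classification = "Missense_Mutation",
      Reference_Allele = "C", Tumor_Seq_Allele2 = "T"
    ),
    cohort
  )
  expect_equal(mutation_frequency(full, genes = "G")$frequency_pct, 100)

  maf <- make_toy_maf()
  shuffled <- maf_table(maf$records[c(3, 1, 4, 2), ], maf$cohort_samples)
  expect_equal(
    mutation_frequency(shuffled, genes = "G"),
    mutation_frequency(maf, genes = "G")
  )
})

test_that("SNV classes collapse to the pyrimidine context", {
  expect_equal(snv_class("C", "G"), "C>G")
  expect_equal(snv_class("G", "C"), "C>G") # complement collapsing
  expect_equal(snv_class("G", "T"), "C>A")
  expect_equal(snv_class("G", "A"), "C>T")
  expect_equal(snv_class("A", "T"), "T>A")
  expect_equal(snv_class("A", "G"), "T>C")
  expect_equal(snv_class("A", "C"), "T>G")
  expect_equal(snv_class("A", "-"), "non-SNV")
  expect_equal(snv_class("AT", "A"), "non-SNV")
  expect_error(snv_class("N", "A"), "invalid allele")
  classes <- snv_class(
    c("C", "C", "C", "T", "T", "T"),
    c("A", "G", "T", "A", "C", "G")
  )
  expect_setequal(classes, c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
})

test_that("per-sample summaries conserve record counts and are cohort-complete", {
  maf <- make_toy_maf()
  summ <- per_sample_summary(maf)
  expect_equal(sum(summ$n), nrow(maf$records))
  expect_setequal(unique(summ$sample), maf$cohort_samples) # zero rows present
  expect_equal(summ$n[summ$sample == tumor_barcodes(4)[4]], 0L)
  # duplicated records count twice (input taken literally)
  dup <- maf_table(maf$records[c(1, 1), ], maf$cohort_samples)
  expect_equal(sum(per_sample_summary(dup)$n), 2L)
})

test_that("class spectra retain Silent and partition SNVs into the six classes", {
  maf <- make_toy_maf()
  spec <- mutation_class_spectrum(maf)
  expect_equal(sum(spec$n), nrow(maf$records))
  expect_true("Silent" %in% spec$classification)
  snv <- snv_class_spectrum(maf)
  expect_true(all(snv$snv_class %in% c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")))
  expect_equal(sum(snv$n), 4L) # all four toy records are single-base
})

test_that("oncoplot matrix marks multi-hit samples and leaves unmutated cells NA", {
  maf <- make_toy_maf()
  om <- oncoplot_matrix(maf)
  expect_equal(dim(om), c(1L, 4L))
  expect_equal(om["G", tumor_barcodes(4)[1]], "Missense_Mutation")
  expect_equal(om["G", tumor_barcodes(4)[2]], "Multi_Hit")
  expect_true(is.na(om["G", tumor_barcodes(4)[4]]))
})

test_that("recovery: planted mutation probability 0.3 is estimated within the binomial band at n=200", {
  hits <- vapply(1:20, function(i) {
    cfg <- planted_config(400L + i,
      plant = list(mut_freq = c(HIF1A = 0.3)),
      layers = "mutation", n_background_genes = 5L,
      n_tumor = 200L, n_normal = 3L, background_mut_freq = 0
    )
    co <- generate_cohort(cfg)
    est <- mutation_frequency(co$cohorts$BRCA$maf,
      genes = "HIF1A",
      include_silent = TRUE
    )$frequency_pct
    abs(est - 30) <= 7
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # the C>G class dominates the simulated substitution spectrum
  cfg <- planted_config(499L,
    plant = list(mut_freq = c(HIF1A = 0.5)),
    layers = "mutation", n_background_genes = 0L,
    n_tumor = 200L, n_normal = 3L
  )
  co <- generate_cohort(cfg)
  snv <- snv_class_spectrum(co$cohorts$BRCA$maf)
  expect_equal(snv$snv_class[which.max(snv$n)], "C>G")
})
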