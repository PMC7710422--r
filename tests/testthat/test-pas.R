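test_that("RPPA normalization centers on the median, scales by sd, and is idempotent", {
  samples <- tumor_barcodes(3)
  m <- make_gsm(c(1, 2, 3, 5, 5, 5), c("c1", "c2"), samples, "protein_level")
  expect_warning(norm <- normalize_rppa(m), "c2")
  expect_equal(rownames(norm), "c1") # constant component dropped
  expect_equal(unname(unclass(norm)["c1", ]), (c(1, 2, 3) - 2) / sd(c(1, 2, 3)))
  expect_equal(median(unclass(norm)["c1", ]), 0)

  # idempotence: median 0 and sample sd 1 after one pass
  set.seed(4)
  big <- make_gsm(rnorm(40), c("a", "b", "c", "d"), tumor_barcodes(10), "protein_level")
  once <- normalize_rppa(big)
  twice <- normalize_rppa(once)
  expect_equal(unclass(twice), unclass(once))
  expect_equal(apply(unclass(once), 1, median), c(a = 0, b = 0, c = 0, d = 0))
})

test_that("pathway scores are sign-weighted means over present members", {
  samples <- tumor_barcodes(2)
  m <- make_gsm(c(2, 1, 1, 1, 3, -1), c("c1", "c2", "c3"), samples, "protein_level")
  one <- pathway_score(m, tibble::tibble(component = "c1", sign = 1))
  expect_equal(unname(one), c(2, 1))
  # activating level and inhibitory level cancel
  two <- pathway_score(
    m, tibble::tibble(component = c("c1", "c2"), sign = c(1, -1))
  )
  expect_equal(unname(two), c((2 - 1) / 2, 0))
  # hand 2-sample 3-member oracle
  members <- tibble::tibble(component = c("c1", "c2", "c3"), sign = c(1, 1, -1))
  hand <- c((2 + 1 - 3) / 3, (1 + 1 - (-1)) / 3)
  expect_equal(unname(pathway_score(m, members)), hand)
  # absent members are skipped; all-absent is an error naming the pathway
  partial <- pathway_score(
    m, tibble::tibble(component = c("c1", "nope"), sign = c(1, 1))
  )
  expect_equal(unname(partial), c(2, 1))
  expect_error(
    pathway_score(m, tibble::tibble(component = "nope", sign = 1), "EMT"),
    "EMT"
  )
})

test_that("pathway scores are linear in levels and antisymmetric under sign flips", {
  set.seed(5)
  samples <- tumor_barcodes(6)
  vals <- matrix(rnorm(24), 4, dimnames = list(c("c1", "c2", "c3", "c4"), samples))
  m <- gene_sample_matrix(vals, "protein_level")
  m2 <- gene_sample_matrix(2 * vals, "protein_level")
  members <- tibble::tibble(component = c("c1", "c3", "c4"), sign = c(1, -1, 1))
  flipped <- dplyr::mutate(members, sign = -sign)
  expect_equal(pathway_score(m2, members), 2 * pathway_score(m, members))
  expect_equal(pathway_score(m, flipped), -pathway_score(m, members))
})

test_that("PAS association handles flat scores, small n, and recovers a planted shift", {
  # identical PAS across samples -> p = 1, verdict none
  samples <- tumor_barcodes(8)
  expr <- make_gsm(1:8, "HIF1A", samples, "normalized_expression")
  # components vary (so none is dropped) but their pathway score is constant
  vals <- rbind(c1 = c(1, 2, 1, 2, 1, 2, 1, 2), c2 = c(2, 1, 2, 1, 2, 1, 2, 1))
  colnames(vals) <- samples
  rppa <- gene_sample_matrix(vals, "protein_level")
  pw <- tibble::tibble(
    pathway = "EMT", component = c("c1", "c2"), sign = c(1, 1)
  )
  res <- pas_associations(expr, rppa, pathways = pw)
  expect_equal(res$p_value, 1)
  expect_equal(res$verdict, "none")

  expect_error(
    pas_associations(expr[, 1:5], rppa[, 1:5], pathways = pw),
    "at least 6"
  )

  cfg <- planted_config(606L,
    plant = list(pas_shift = tibble::tibble(
      gene = "HIF1A", pathway = "EMT", shift = 4
    )),
    layers = c("expression", "rppa"), n_background_genes = 0L,
    n_tumor = 40L, n_normal = 3L
  )
  co <- generate_cohort(cfg)
  g <- match_tumor_normal(co$cohorts$BRCA$counts)
  res <- pas_associations(
    co$cohorts$BRCA$counts[, g$tumors], co$cohorts$BRCA$rppa,
    pathways = co$pathways, genes = co$config$target_genes
  )
  hit <- res[res$gene == "HIF1A" & res$pathway == "EMT", ]
  expect_equal(hit$verdict, "activation")
  expect_gt(hit$mean_pas_high, hit$mean_pas_low)
})

test_that("the cross-cancer summary computes percentages and the inclusive >=5 filter", {
  assoc <- tidyr::crossing(
    gene = "HIF1A", pathway = "EMT",
    cancer = sprintf("C%02d", 1:10)
  )
  assoc$verdict <- c(rep("activation", 3), rep("none", 7))
  summ <- pas_global_summary(assoc)
  expect_equal(summ$pct_activated, 30)
  expect_equal(summ$pct_inhibited, 0)
  expect_false(summ$heatmap_kept)

  # functional in exactly 5 cancers -> kept (boundary inclusive)
  assoc$verdict <- c(rep("activation", 4), "inhibition", rep("none", 5))
  expect_true(pas_global_summary(assoc)$heatmap_kept)
  expect_equal(pas_global_summary(assoc)$functional_in, 5L)
  # functional in 4 -> dropped
  assoc$verdict <- c(rep("activation", 4), rep("none", 6))
  expect_false(pas_global_summary(assoc)$heatmap_kept)
})
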