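make_cell_line_pair <- function(expr_vals, auc_vals, n = length(expr_vals)) {
  lines <- sprintf("CL%02d", seq_len(n))
  list(
    expr = make_gsm(expr_vals, "EPAS1", lines, "normalized_expression"),
    auc = make_gsm(auc_vals, "drugA", lines, "drug_auc")
  )
}

test_that("monotone AUC-expression gives rho 1 and the resistance direction", {
  p <- make_cell_line_pair(1:6, c(2, 3, 5, 8, 9, 20))
  res <- correlate_drug_expression(p$expr, p$auc)
  expect_equal(res$rho, 1)
  expect_equal(res$direction, "resistance")
  expect_equal(res$p_value, 0)
  # anti-monotone -> sensitivity
  p2 <- make_cell_line_pair(1:6, rev(c(2, 3, 5, 8, 9, 20)))
  expect_equal(correlate_drug_expression(p2$expr, p2$auc)$direction, "sensitivity")
})

test_that("Fisher Z is atanh and invertible to 1e-10 over (-0.999, 0.999)", {
  set.seed(8)
  lines <- sprintf("CL%02d", 1:20)
  expr <- make_gsm(rnorm(20), "EPAS1", lines, "normalized_expression")
  auc <- make_gsm(rnorm(20), "drugA", lines, "drug_auc")
  res <- correlate_drug_expression(expr, auc)
  expect_equal(res$z, atanh(res$rho))
  expect_equal(tanh(res$z), res$rho, tolerance = 1e-10)
  rhos <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(tanh(atanh(rhos)), rhos, tolerance = 1e-10)
  # rho = 0 -> z = 0
  expect_equal(atanh(0), 0)
})

test_that("pairwise-complete handling and the <3-pair missing record", {
  lines <- sprintf("CL%02d", 1:6)
  expr <- make_gsm(1:6, "EPAS1", lines, "normalized_expression")
  auc_vals <- matrix(c(2, 3, 5, 8, 9, 20, 1, 2, NA, NA, NA, NA), 2,
    byrow = TRUE, dimnames = list(c("drugA", "drugB"), lines)
  )
  auc <- gene_sample_matrix(auc_vals, "drug_auc")
  res <- correlate_drug_expression(expr, auc)
  expect_equal(res$n[res$drug == "drugA"], 6L)
  expect_equal(res$n[res$drug == "drugB"], 2L)
  expect_true(is.na(res$rho[res$drug == "drugB"]))
  expect_false(res$bonferroni_significant[res$drug == "drugB"])
})

test_that("the Bonferroni gate corrects over all gene x drug pairs two-tailed", {
  set.seed(12)
  n_lines <- 50
  lines <- sprintf("CL%03d", seq_len(n_lines))
  genes <- c("EPAS1", "HIF1A")
  z <- matrix(rnorm(2 * n_lines), 2, dimnames = list(genes, lines))
  auc_vals <- rbind(
    drugA = 0.9 * z["EPAS1", ] + sqrt(1 - 0.81) * rnorm(n_lines),
    drugB = rnorm(n_lines)
  )
  colnames(auc_vals) <- lines
  res <- correlate_drug_expression(
    gene_sample_matrix(z, "normalized_expression"),
    gene_sample_matrix(auc_vals, "drug_auc")
  )
  # the planted pair passes p < 0.05 / 4; null pairs do not
  expect_true(res$bonferroni_significant[res$gene == "EPAS1" & res$drug == "drugA"])
  expect_identical(
    res$bonferroni_significant,
    !is.na(res$p_value) & res$p_value < 0.05 / 4
  )
  counts <- drugs_per_gene(res)
  expect_equal(counts$n_significant[counts$gene == "EPAS1"], 1L)
  expect_equal(counts$drugs[counts$gene == "EPAS1"][[1]], "drugA")
  expect_equal(counts$n_significant[counts$gene == "HIF1A"], 0L)
  # counts are invariant to association order
  expect_equal(
    drugs_per_gene(res[sample(nrow(res)), ])$n_significant,
    counts$n_significant[match(
      drugs_per_gene(res[sample(nrow(res)), ])$gene, counts$gene
    )]
  )
})

test_that("the Pearson variant is available alongside the Spearman default", {
  set.seed(13)
  lines <- sprintf("CL%02d", 1:30)
  ev <- rnorm(30)
  av <- 0.7 * ev + sqrt(0.51) * rnorm(30)
  expr <- make_gsm(ev, "EPAS1", lines, "normalized_expression")
  auc <- make_gsm(av, "drugA", lines, "drug_auc")
  rs <- correlate_drug_expression(expr, auc)$rho
  rp <- correlate_drug_expression(expr, auc, method = "pearson")$rho
  expect_equal(rp, cor(ev, av))
  expect_equal(rs, cor(ev, av, method = "spearman"))
})

test_that("the resampling null is deterministic, degenerate-safe, and calibrated on planted pairs", {
  set.seed(21)
  assoc <- tidyr::crossing(gene = sprintf("g%02d", 1:10), drug = sprintf("d%02d", 1:10))
  assoc$rho <- rnorm(100, 0, 0.1)
  targets <- tibble::tibble(gene = "g01", drug = c("d01", "d02", "d03"))
  r1 <- resampling_null(assoc, targets, n_iterations = 200L, seed = 5L)
  r2 <- resampling_null(assoc, targets, n_iterations = 200L, seed = 5L)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_equal(
    r1$empirical_p,
    (1 + sum(r1$null_stats >= r1$observed_stat)) / 201
  )

  # all correlations identical -> observed never exceeds the null -> p = 1
  flat <- assoc
  flat$rho <- 0.3
  expect_equal(
    resampling_null(flat, targets, n_iterations = 100L, seed = 1L)$empirical_p, 1
  )

  # planted |rho| 0.7 targets over a null background are extreme
  planted <- assoc
  planted$rho[planted$gene == "g01" & planted$drug %in% c("d01", "d02", "d03")] <- 0.7
  rp <- resampling_null(planted, targets, n_iterations = 1000L, seed = 2L)
  expect_lte(rp$empirical_p, 0.01)

  expect_error(
    resampling_null(assoc[1:4, ], tibble::tibble(gene = "g99", drug = "d99")),
    "absent"
  )
})
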