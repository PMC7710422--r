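test_that("copy-number calls map onto the five event categories", {
  expect_equal(
    classify_call(c(-2, -1, 0, 1, 2)),
    c("homo_del", "hete_del", "none", "hete_amp", "homo_amp")
  )
  expect_error(classify_call(3), "3")
  expect_error(classify_call(0.5), "0.5")
})

test_that("event percentages count categories and apply the strict >5% display rule", {
  samples <- tumor_barcodes(10)
  calls <- make_gsm(
    c(1, 1, rep(0, 8)), "HIF1A", samples, "cnv_call"
  )
  prof <- event_percentages(calls)
  expect_equal(prof$pct_hete_amp, 20)
  expect_equal(prof$pct_hete_del + prof$pct_homo_amp + prof$pct_homo_del, 0)
  expect_true(prof$displayed)

  all0 <- make_gsm(rep(0, 10), "HIF1A", samples, "cnv_call")
  prof0 <- event_percentages(all0)
  expect_equal(
    prof0$pct_hete_amp + prof0$pct_hete_del +
      prof0$pct_homo_amp + prof0$pct_homo_del, 0
  )
  expect_false(prof0$displayed)

  # exactly 5% total burden is NOT displayed (strict >5)
  s100 <- tumor_barcodes(100)
  at5 <- make_gsm(c(rep(1, 3), rep(-2, 2), rep(0, 95)), "HIF1A", s100, "cnv_call")
  expect_false(event_percentages(at5)$displayed)
  # ... but a single category above 5% is, under either rule
  at6 <- make_gsm(c(rep(1, 6), rep(0, 94)), "HIF1A", s100, "cnv_call")
  expect_true(event_percentages(at6)$displayed)
  expect_true(event_percentages(at6, display_rule = "per_category")$displayed)
  # per-category rule: 4% + 4% displays under union (8% > 5) but not per category
  mix <- make_gsm(c(rep(1, 4), rep(-1, 4), rep(0, 92)), "HIF1A", s100, "cnv_call")
  expect_true(event_percentages(mix)$displayed)
  expect_false(event_percentages(mix, display_rule = "per_category")$displayed)
})

test_that("event percentages are invariant to sample order and stable under cohort duplication", {
  set.seed(9)
  samples <- tumor_barcodes(40)
  vals <- matrix(sample(-2:2, 80, TRUE, prob = c(.05, .1, .6, .2, .05)), 2,
    dimnames = list(c("g1", "g2"), samples)
  )
  m <- gene_sample_matrix(vals, "cnv_call")
  shuffled <- gene_sample_matrix(vals[, sample(samples)], "cnv_call")
  pcts <- c("pct_hete_amp", "pct_hete_del", "pct_homo_amp", "pct_homo_del")
  expect_equal(event_percentages(m)[pcts], event_percentages(shuffled)[pcts])
  doubled <- vals[, rep(seq_len(40), 2)]
  colnames(doubled) <- c(samples, sub("01A$", "01B", samples))
  expect_equal(
    event_percentages(gene_sample_matrix(doubled, "cnv_call"))[pcts],
    event_percentages(m)[pcts]
  )
})

test_that("CNV-expression correlation recovers monotone dosage and handles degenerate calls", {
  samples <- tumor_barcodes(6)
  calls <- make_gsm(c(-2, -1, 0, 0, 1, 2, rep(0, 6)), c("g1", "g2"),
    samples, "cnv_call"
  )
  expr <- make_gsm(c(2, 4, 8, 16, 32, 64, rep(5, 6)), c("g1", "g2"),
    samples, "normalized_expression"
  )
  res <- cnv_expression_correlation(calls, expr)
  expect_equal(res$rho[res$gene == "g1"], spearman_brute(
    c(-2, -1, 0, 0, 1, 2), c(2, 4, 8, 16, 32, 64)
  )$rho)
  expect_gt(res$rho[res$gene == "g1"], 0.9)
  # constant calls (all zero) give a missing-result record, not a crash
  expect_true(is.na(res$rho[res$gene == "g2"]))
  expect_true(is.na(res$fdr[res$gene == "g2"]))
})

test_that("Spearman with the t-approximation matches the rank-then-Pearson oracle", {
  x <- c(3, 1, 4, 1, 5)
  y <- c(9, 2, 6, 5, 3)
  got <- spearman_test(x, y)
  oracle <- spearman_brute(x, y)
  expect_equal(got$rho, oracle$rho)
  expect_equal(got$p_value, oracle$p_value)
  # ties handled by average ranks on both routes
  xt <- c(1, 1, 2, 3, 3)
  got_t <- spearman_test(xt, y)
  oracle_t <- spearman_brute(xt, y)
  expect_equal(got_t$rho, oracle_t$rho)
  expect_equal(got_t$p_value, oracle_t$p_value)
})

test_that("recovery: planted dosage slope 0.5 at n=60 yields positive significant correlation", {
  cfg <- planted_config(202L,
    plant = list(cnv_dosage_slope = c(ARNT = 0.5)),
    layers = c("expression", "cnv"), n_background_genes = 30L,
    n_tumor = 60L, n_normal = 3L
  )
  co <- generate_cohort(cfg)
  res <- cnv_expression_correlation(co$cohorts$BRCA$cnv, co$cohorts$BRCA$counts)
  hit <- res[res$gene == "ARNT", ]
  expect_gt(hit$rho, 0)
  expect_lt(hit$fdr, 0.05)
})
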