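# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately re-derive each statistic from its textbook definition
# and never call the package functions they check.

# Benjamini-Hochberg step-up, straight from the definition:
# adj_(i) = min_{j >= i} min(1, m p_(j) / j) in sorted order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(
    seq_len(m),
    function(i) min(1, min(m * sorted[i:m] / seq(i, m))),
    numeric(1)
  )
  out <- numeric(m)
  out[o] <- adj
  out
}

# Spearman as rank-then-Pearson with average ranks, t-approximation p.
spearman_brute <- function(x, y) {
  r <- stats::cor(rank(x), rank(y), method = "pearson")
  n <- length(x)
  p <- if (abs(r) >= 1) {
    0
  } else {
    2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  }
  list(rho = r, p_value = p)
}

# Two-group log-rank by hypergeometric accumulation over distinct event
# times; returns chi-square and the observed-minus-expected excess of the
# TRUE group.
logrank_brute <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  O <- 0
  E <- 0
  V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chi2 = (O - E)^2 / V, excess = O - E, variance = V)
}

# Pooled (Student) and Welch two-sample t p-values from the textbook
# formulas.
student_t_brute <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(t), df = n1 + n2 - 2)
}

welch_t_brute <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  v1 <- stats::var(x) / n1
  v2 <- stats::var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df = df)
}
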