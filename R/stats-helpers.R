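#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around [stats::p.adjust()] that validates the input range,
#' preserves input order, and excludes `NA` entries from the number of tests
#' (an `NA` p-value, e.g. from a degenerate correlation, stays `NA` without
#' inflating the family size).
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return adjusted values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Spearman correlation with t-approximation p-value
#'
#' Average ranks for ties, pairwise-complete observations, and the
#' t-approximation p = 2 P(T_{n-2} >= |rho| sqrt((n-2)/(1-rho^2))). With
#' fewer than 3 complete pairs or a constant margin the result is a
#' missing-value record rather than an error.
#'
#' @param x,y numeric vectors of equal length.
#' @return one-row tibble: `rho`, `p_value`, `n` (complete pairs used).
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L || length(unique(x[ok])) < 2L || length(unique(y[ok])) < 2L) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(x[ok], y[ok], method = "spearman")
  tibble::tibble(rho = rho, p_value = spearman_p(rho, n), n = n)
}

spearman_p <- function(rho, n) {
  dplyr::if_else(
    abs(rho) >= 1, 0,
    2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2)
  )
}

# Two-sample t returning (statistic, p, mean_x, mean_y); handles the
# degenerate zero-variance case the way the DE contract states: equal
# constant groups give p = 1, different constants give p = 0.
two_sample_t <- function(x, y, pooled = FALSE) {
  mx <- mean(x)
  my <- mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (isTRUE(all.equal(mx, my))) 1 else 0
    return(list(statistic = NA_real_, p_value = p, mean_x = mx, mean_y = my))
  }
  fit <- stats::t.test(x, y, var.equal = pooled)
  list(
    statistic = unname(fit$statistic), p_value = fit$p.value,
    mean_x = mx, mean_y = my
  )
}

# Median split used by the PAS and survival stages: strictly greater than
# the median goes high, ties go low.
median_split <- function(values) {
  values > stats::median(values)
}
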