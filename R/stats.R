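# Statistical primitives used by the gating and significance stages.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the sup-difference of the two empirical CDFs and an asymptotic
#' two-sided p-value from the Kolmogorov distribution with the standard
#' small-sample effective-n correction
#' `lambda = (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D`,
#' `n_eff = n1 n2 / (n1 + n2)`.
#'
#' @param x,y Numeric samples (each of length >= 1).
#' @return List with `statistic` (D) and `p_value`.
#' @export
#' @examples
#' ks_test_2sample(c(10, 11, 12, 13), c(0, 0.1, 0.2, 0.3))
ks_test_2sample <- function(x, y) {
  x <- sort(x)
  y <- sort(y)
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  all_v <- sort(unique(c(x, y)))
  f1 <- vapply(all_v, function(v) sum(x <= v), numeric(1)) / n1
  f2 <- vapply(all_v, function(v) sum(y <= v), numeric(1)) / n2
  d <- max(abs(f1 - f2))
  n_eff <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d
  p <- kolmogorov_q(lambda)
  list(statistic = d, p_value = p)
}

# Complementary CDF of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 lambda^2).
kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
  min(1, max(0, 2 * sum(terms)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test of two samples
#'
#' Two-sided test with either the normal approximation (tie correction and
#' 0.5 continuity correction) or, when both samples are free of cross-ties
#' and `n1 * n2` is at most `exact_limit`, the exact null distribution of
#' the Mann-Whitney U statistic. Direction is reported as the sign of
#' `median(x) - median(y)`.
#'
#' @param x Patient-side sample (length >= 1).
#' @param y Background-side sample.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`); default
#'   `NULL` picks exact when feasible (no ties, `n1*n2 <= exact_limit`).
#' @param exact_limit Largest `n1*n2` for which the exact distribution is
#'   used when `exact = NULL`.
#' @return List with `statistic` (U for the `x` sample), `p_value`,
#'   `direction` (`"positive"`/`"negative"`) and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL, exact_limit = 10000) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  direction <- if (median(x) - median(y) >= 0) "positive" else "negative"
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  use_exact <- if (is.null(exact)) !ties && n1 * n2 <= exact_limit else exact
  if (use_exact && ties) {
    warning("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    # Exact two-sided p from the null distribution of U.
    p <- if (u > n1 * n2 / 2) {
      2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else if (u < n1 * n2 / 2) {
      2 * stats::pwilcox(u, n1, n2)
    } else {
      1
    }
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1,
                                 direction = direction,
                                 method = "approximate"))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    method <- "approximate"
  }
  list(statistic = u, p_value = min(1, p), direction = direction,
       method = method)
}

#' Exact two-sided binomial test
#'
#' Two-sided p-value defined as the total probability of all outcomes whose
#' point probability does not exceed that of the observed count (the
#' minimum-likelihood method).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability, strictly inside (0, 1); degenerate
#'   values yield p = 1 with a warning.
#' @return Two-sided p-value.
#' @export
binom_test_2sided <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, n >= 1)
  if (p0 <= 0 || p0 >= 1) {
    warning("degenerate null probability p0 = ", p0, "; returning p = 1")
    return(1)
  }
  pmf <- stats::dbinom(0:n, n, p0)
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}
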