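#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ties in the absolute differences receive
#' average ranks. For n <= `exact_max` the null distribution of the
#' positive-rank sum is computed exactly by convolution over the (doubled,
#' hence integer) ranks — valid with ties, equivalent to enumerating all
#' 2^n sign assignments. Above that, a normal approximation with the usual
#' tie correction of the variance is used (no continuity correction).
#'
#' @param a,b paired numeric vectors (e.g. absolute prediction errors of
#'   two methods on the same eyes).
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (positive-rank sum W+), `n` (non-zero
#'   pairs), `p_value`, and `method` ("exact" or "normal").
#' @export
wilcoxon_paired <- function(a, b, exact_max = 25) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, n = 0L, p_value = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])

  if (n <= exact_max) {
    # support of 2*W+ is 0..sum(2r); distribution by convolution:
    # each rank contributes 0 or 2r with probability 1/2
    r2 <- round(2 * r)
    total <- sum(r2)
    f <- c(1, rep(0, total))
    for (ri in r2) {
      g <- f / 2
      shifted <- c(rep(0, ri), f[seq_len(total + 1 - ri)]) / 2
      f <- g + shifted
    }
    w2 <- round(2 * w)
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = w, n = as.integer(n), p_value = p, method = method)
}

#' McNemar test with Yates' continuity correction
#'
#' Compares two paired dichotomous outcomes (e.g. "within +/-0.50 D" under
#' two methods). Only discordant pairs enter: b (first method only) and
#' c (second only); chi-squared = (max(|b - c| - 1, 0))^2 / (b + c) on one
#' degree of freedom. The Yates numerator is clamped at zero when
#' |b - c| < 1.
#'
#' @param within_a,within_b paired logical vectors.
#' @return list with `statistic`, `b`, `c`, `p_value`.
#' @export
mcnemar_yates <- function(within_a, within_b) {
  stopifnot(length(within_a) == length(within_b))
  b <- sum(within_a & !within_b)
  cc <- sum(!within_a & within_b)
  if (b + cc == 0) {
    warning("no discordant pairs; p = 1")
    return(list(statistic = 0, b = b, c = cc, p_value = 1))
  }
  stat <- max(abs(b - cc) - 1, 0)^2 / (b + cc)
  list(statistic = stat, b = b, c = cc,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Exact two-sided sign test on paired differences
#'
#' Zero differences are dropped; the count of positive differences is
#' tested against Binomial(n, 1/2).
#'
#' @param a,b paired numeric vectors, or `a` alone a vector of differences
#'   when `b` is NULL.
#' @return list with `positive`, `negative`, `p_value`.
#' @export
sign_test <- function(a, b = NULL) {
  d <- if (is.null(b)) a else a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("no non-zero differences; p = 1")
    return(list(positive = 0L, negative = 0L, p_value = 1))
  }
  pos <- sum(d > 0)
  list(positive = as.integer(pos), negative = as.integer(n - pos),
       p_value = stats::binom.test(pos, n, p = 0.5)$p.value)
}

#' Bonferroni adjustment
#'
#' p_adj = min(1, m * p). `m` defaults to the number of p-values supplied,
#' i.e. the family of simultaneous comparisons in the emitted table.
#'
#' @param p_values numeric vector of raw p-values.
#' @param m family size.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  pmin(1, m * p_values)
}
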