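# independent brute-force oracles for the paired statistical tests

# Wilcoxon signed-rank: enumerate all 2^n sign assignments of the ranks
wilcoxon_brute <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-12)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# exact binomial sign test (minimum-likelihood two-sided definition)
sign_brute <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] + 1e-12])
}
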