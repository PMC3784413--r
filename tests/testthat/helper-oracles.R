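# Independent oracles for the rank statistics: deliberately naive,
# separate code paths from the package implementation.

# Dunn z from first principles: pooled ranks, mean-rank difference, tie-
# corrected variance
dunn_oracle <- function(groups, i, j) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  r <- rank(x)
  N <- length(x)
  ties <- table(r)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  (mean(r[g == i]) - mean(r[g == j])) /
    sqrt(s2 * (1 / sum(g == i) + 1 / sum(g == j)))
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
wilcoxon_oracle_p <- function(a, b) {
  d <- (a - b)[(a - b) != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  min(1, 2 * min(mean(w_all <= w_obs + 1e-12), mean(w_all >= w_obs - 1e-12)))
}

random_small_instance <- function(k, sizes) {
  lapply(sizes, function(n) sample(1:5, n, replace = TRUE))
}
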