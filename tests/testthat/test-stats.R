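# Nonparametric battery: hand-checked values, independent reference
# implementations (base R), enumeration oracles on small instances, and
# symmetry properties.

# --- hand-checked values -------------------------------------------------

test_that("Kruskal-Wallis H matches the rank-sum formula hand check", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)  # 3.857...
  expect_equal(res$df, 1)
  # label invariance: permuting group order leaves H unchanged
  res2 <- kruskal_wallis(list(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(res2$statistic, res$statistic)
  # identical groups are a null; identical values are degenerate
  expect_equal(kruskal_wallis(list(1:4, 1:4))$statistic, 0, tolerance = 1e-12)
  deg <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Friedman chi-square matches the rank-sum formula hand check", {
  res <- friedman_rank(rbind(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(res$statistic, 4)  # identical orderings, 2 blocks, 3 treatments
  expect_equal(res$df, 2)
  # block exchangeability
  res2 <- friedman_rank(rbind(c(2, 4, 6), c(1, 2, 3)))
  expect_equal(res2$statistic, res$statistic)
  # no within-block differences -> degenerate
  deg <- friedman_rank(rbind(c(1, 1, 1), c(5, 5, 5)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(friedman_rank(rbind(c(1, NA, 2), c(1, 2, 3))), "missing")
  expect_error(friedman_rank(matrix(1:3, nrow = 1)), "at least 2 blocks")
})

test_that("Wilcoxon signed rank is exact at small n (full enumeration)", {
  # 5 all-positive differences: W+ = 15, two-sided p = 2/32
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 2 / 32)
  # sign symmetry: negating differences swaps W+ and W-, same p
  neg <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(neg$statistic, 0)
  expect_equal(neg$p_value, res$p_value)
  # identical pairs -> degenerate
  deg <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "equal length")
  expect_error(wilcoxon_signed_rank(c(1, 2), c(2, 1)), "at least 3")
})

test_that("Dunn pairs are antisymmetric and null pairs give p = 1", {
  g <- list(a = c(1, 2, 3, 7), b = c(2, 3, 4), c = c(10, 11, 12))
  res <- dunn_posthoc(g)
  tab <- res$pairwise
  # swapping the pair flips the sign of z with identical p
  res_swapped <- dunn_posthoc(list(a = g$b, b = g$a, c = g$c))
  expect_equal(res_swapped$pairwise$z[1], -tab$z[1])
  expect_equal(res_swapped$pairwise$p[1], tab$p[1])
  # two identical groups: z = 0, adjusted p = 1
  nul <- dunn_posthoc(list(x = 1:4, y = 1:4))
  expect_equal(nul$pairwise$z, 0)
  expect_equal(nul$pairwise$p_adjusted, 1)
  expect_error(dunn_posthoc(list(1:3, numeric(0))), "non-empty")
  # unadjusted mode exposes raw p in the significance flag
  raw <- dunn_posthoc(g, adjust = "none")
  expect_equal(raw$pairwise$p, tab$p)
})

# --- oracle equivalence on small instances -------------------------------

test_that("H, Friedman chi-square, Dunn z, and exact Wilcoxon p match independent oracles on small integer datasets", {
  set.seed(20240917)
  # Kruskal-Wallis and Dunn vs base R / first-principles oracle, across
  # all group-shape partitions with total n <= 8
  shapes <- list(c(2, 2), c(2, 3), c(3, 3), c(2, 2, 2), c(4, 4),
                 c(2, 3, 3), c(2, 2, 2, 2), c(3, 5))
  for (shape in shapes) {
    for (rep in 1:12) {
      g <- random_small_instance(length(shape), shape)
      if (length(unique(unlist(g))) == 1L) next
      mine <- kruskal_wallis(g)
      ref <- stats::kruskal.test(unlist(g),
                                 rep(seq_along(g), lengths(g)))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
      dz <- dunn_posthoc(g)$pairwise
      pr <- utils::combn(length(g), 2)
      for (q in seq_len(ncol(pr))) {
        zo <- dunn_oracle(g, pr[1, q], pr[2, q])
        expect_equal(dz$z[q], zo, tolerance = 1e-9)
      }
    }
  }
  # Friedman vs base R on untied blocks; vs formula on tied blocks
  for (rep in 1:20) {
    m <- t(replicate(4, sample(1:20, 4)))  # untied within blocks
    mine <- friedman_rank(m)
    ref <- stats::friedman.test(m)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
  # Wilcoxon exact p vs full 2^n enumeration (with and without ties)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    a <- sample(1:5, n, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    if (sum(a != b) < 3) next
    mine <- wilcoxon_signed_rank(a, b)
    expect_equal(mine$p_value, wilcoxon_oracle_p(a, b), tolerance = 1e-9)
  }
  # and vs base R's exact test when there are no ties or zeros
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    mags <- sample(seq(0.1, 10, by = 0.1), n)  # distinct |d|, no zeros
    b <- runif(n)
    a <- b + mags * sample(c(-1, 1), n, replace = TRUE)
    mine <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("increasing location shift never decreases average power", {
  # monotone power over three effect sizes (rank tests, n = 8 per group)
  set.seed(42)
  shifts <- c(0.5, 1.5, 3)
  power_at <- vapply(shifts, function(s) {
    mean(replicate(150, {
      g1 <- rnorm(8)
      kruskal_wallis(list(g1, rnorm(8) + s))$p_value < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(power_at) >= 0))
})

# --- censored summaries --------------------------------------------------

test_that("censoring-aware summaries follow the cap-substitution rule", {
  s <- summarize_censored(c(100, 200, 600, 600, 600),
                          censored = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                          cap = 600)
  expect_equal(s$median, 600)
  expect_true(s$median_is_lower_bound)
  expect_equal(s$n_censored, 3)
  expect_equal(s$mean, mean(c(100, 200, 600, 600, 600)))

  s2 <- summarize_censored(c(1, 2, 3, 4))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$median, 2.5)
  expect_false(s2$median_is_lower_bound)
  expect_equal(s2$iqr_lo, unname(quantile(1:4, 0.25)))

  s3 <- summarize_censored(c(2, 4, 6))
  expect_equal(s3$sem, 2 / sqrt(3), tolerance = 1e-12)

  expect_error(summarize_censored(c(1, 599), censored = c(FALSE, TRUE),
                                  cap = 600), "must equal the cap")
  expect_error(summarize_censored(numeric(0)), "no values")
})
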