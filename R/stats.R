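# Nonparametric battery implemented from the rank formulas, with exact
# small-sample behavior where the emulated analyses need it. Base R's
# kruskal.test / friedman.test / wilcox.test are treated as independent
# references in the test suite, not used here.

new_bw_test <- function(method, statistic, p_value, df = NA_real_,
                        n = NA_integer_, pairwise = NULL,
                        degenerate = FALSE, notes = NULL) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 df = df, n = n, pairwise = pairwise,
                 degenerate = degenerate, notes = notes),
            class = "bw_test")
}

#' @export
print.bw_test <- function(x, ...) {
  cat("<", x$method, ">\n  statistic = ", signif(x$statistic, 6),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", signif(x$p_value, 4),
      if (x$degenerate) " (degenerate input)", "\n", sep = "")
  if (!is.null(x$pairwise)) print.data.frame(x$pairwise, row.names = FALSE,
                                             digits = 4)
  invisible(x)
}

tie_sum <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

as_group_list <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("stats error: need a list of at least 2 groups")
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("stats error: every group must be non-empty")
  if (any(!vapply(groups, function(g) all(is.finite(g)), logical(1))))
    stop("stats error: values must be finite")
  groups
}

#' Kruskal-Wallis rank test for independent groups
#'
#' The omnibus comparison used for between-condition contrasts: the H
#' statistic on pooled ranks with the standard tie correction, referred to
#' a chi-square distribution with k - 1 degrees of freedom.
#'
#' H = 12 / (N(N+1)) * sum_j R_j^2 / n_j - 3(N+1), divided by
#' 1 - sum(t^3 - t) / (N^3 - N) over tie groups. When every observation is
#' identical the statistic is degenerate (H = 0, p = 1).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups,
#'   each non-empty).
#' @return A `bw_test` with the H statistic, df = k - 1, and p-value.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 3.857
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  x <- unlist(groups)
  n <- vapply(groups, length, integer(1))
  N <- length(x)
  r <- rank(x)
  rs <- split(r, rep(seq_len(k), n))
  H <- 12 / (N * (N + 1)) * sum(vapply(rs, sum, numeric(1))^2 / n) - 3 * (N + 1)
  D <- 1 - tie_sum(r) / (N^3 - N)
  if (D <= 0)
    return(new_bw_test("Kruskal-Wallis rank sum test", 0, 1, df = k - 1,
                       n = N, degenerate = TRUE,
                       notes = "all values identical"))
  H <- H / D
  new_bw_test("Kruskal-Wallis rank sum test", H,
              stats::pchisq(H, df = k - 1, lower.tail = FALSE),
              df = k - 1, n = N)
}

#' Dunn's post-hoc pairwise comparisons on mean ranks
#'
#' Pairwise z statistics on the mean pooled ranks with tie correction,
#' two-sided normal p-values, and family-wise Bonferroni adjustment over
#' all pairs (the usual convention following a significant omnibus test;
#' unadjusted p-values are always reported alongside).
#'
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3-t)/(12(N-1))) *
#' (1/n_i + 1/n_j)).
#'
#' @param groups List of numeric vectors, one per group.
#' @param alpha Significance level used to flag pairs (default 0.05).
#' @param adjust `"bonferroni"` (default) or `"none"`; the `significant`
#'   flag uses the selected mode.
#' @return A `bw_test` whose `pairwise` table has one row per pair with
#'   `z`, `p`, `p_adjusted`, and `significant`.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05,
                         adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- as_group_list(groups)
  k <- length(groups)
  nm <- names(groups) %||% paste0("group", seq_len(k))
  x <- unlist(groups)
  n <- vapply(groups, length, integer(1))
  N <- length(x)
  r <- rank(x)
  rbar <- vapply(split(r, rep(seq_len(k), n)), mean, numeric(1))
  s2 <- N * (N + 1) / 12 - tie_sum(r) / (12 * (N - 1))

  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_i = nm[i], group_j = nm[j], z = z, p = p,
               p_adjusted = min(1, p * m), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$significant <- (if (adjust == "bonferroni") tab$p_adjusted else tab$p) < alpha
  new_bw_test(paste0("Dunn's test (", adjust, ")"),
              statistic = max(abs(tab$z)), p_value = min(tab$p_adjusted),
              n = N, pairwise = tab)
}

#' Friedman rank test for complete blocks
#'
#' Within-block ranks (average ranks for ties), chi-square statistic with
#' k - 1 degrees of freedom and the standard tie correction
#' C = 1 - sum(t^3 - t) / (n k (k^2 - 1)). When all treatments are tied
#' within every block the statistic is degenerate (0, p = 1).
#'
#' @param block_matrix Numeric matrix, n blocks (rows) x k treatments
#'   (columns), complete (no missing cells), n >= 2, k >= 2.
#' @return A `bw_test` with the chi-square statistic, df = k - 1, and
#'   p-value.
#' @examples
#' friedman_rank(rbind(c(1, 2, 3), c(2, 4, 6)))  # chi-square = 4
#' @export
friedman_rank <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (any(!is.finite(m)))
    stop("stats error: block matrix has missing or non-finite cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("stats error: need at least 2 blocks and 2 treatments")
  r <- t(apply(m, 1L, rank))
  Rj <- colSums(r)
  chi <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  C <- 1 - sum(apply(m, 1L, function(row) tie_sum(rank(row)))) /
    (n * k * (k^2 - 1))
  if (C <= 0)
    return(new_bw_test("Friedman rank sum test", 0, 1, df = k - 1, n = n,
                       degenerate = TRUE,
                       notes = "treatments identical within every block"))
  chi <- chi / C
  new_bw_test("Friedman rank sum test", chi,
              stats::pchisq(chi, df = k - 1, lower.tail = FALSE),
              df = k - 1, n = n)
}

# Exact distribution of W+ over all 2^n sign assignments of the ranks of
# |d| (ranks may be tied halves; doubling makes them integers), as a
# probability vector over 0, 0.5, 1, ... , sum(r).
signed_rank_distribution <- function(r2) {
  # r2: integer vector of doubled ranks; dynamic-programming convolution
  total <- sum(r2)
  dp <- numeric(total + 1L)
  dp[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dp[seq_len(total + 1L - ri)])
    dp <- (dp + shifted) / 2
  }
  dp
}

#' Wilcoxon signed-rank test for paired samples
#'
#' The within-slice / within-animal comparison against its own control:
#' zero differences are dropped, absolute differences are ranked (average
#' ranks for ties), and the statistic is W+ (the sum of ranks of positive
#' differences). The p-value is exact -- computed by enumerating the
#' distribution of W+ over all 2^n sign assignments -- for n <= 15 after
#' dropping zeros, and otherwise uses the normal approximation with tie
#' correction and continuity correction. Two-sided.
#'
#' @param paired_a,paired_b Numeric vectors of equal length.
#' @return A `bw_test` with statistic W+ and the two-sided p-value.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))  # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("stats error: paired vectors must have equal length")
  d <- as.numeric(paired_a) - as.numeric(paired_b)
  if (any(!is.finite(d))) stop("stats error: differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(new_bw_test("Wilcoxon signed rank test", 0, 1, n = 0L,
                       degenerate = TRUE, notes = "all differences zero"))
  if (n < 3L)
    stop("stats error: need at least 3 nonzero differences (got ", n, ")")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])

  if (n <= 15L) {
    dp <- signed_rank_distribution(as.integer(round(2 * r)))
    i <- as.integer(round(2 * w_plus)) + 1L
    p <- min(1, 2 * min(sum(dp[seq_len(i)]), sum(dp[i:length(dp)])))
    method <- "Wilcoxon signed rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    sg <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_sum(r) / 48)
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sg
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed rank test (normal approximation)"
  }
  new_bw_test(method, w_plus, p, n = n)
}

#' Censoring-aware summary statistics
#'
#' Summaries used for truncated latency data: mean +/- SEM with censored
#' observations entering at the cap (matching how truncated latencies
#' enter reported means), median and interquartile range via
#' linear-interpolation quantiles (type 7), the censored count, and a flag
#' marking the median as a lower bound when more than half the
#' observations are censored.
#'
#' @param values Numeric vector of observed values (censored entries must
#'   equal `cap`).
#' @param censored Logical vector marking right-censored entries
#'   (default: none).
#' @param cap The censoring cap (default `Inf`).
#' @return A `bw_summary` list: `mean`, `sem`, `median`, `iqr_lo`,
#'   `iqr_hi`, `n`, `n_censored`, `median_is_lower_bound`.
#' @examples
#' summarize_censored(c(100, 200, 600, 600, 600),
#'                    censored = c(FALSE, FALSE, TRUE, TRUE, TRUE), cap = 600)
#' @export
summarize_censored <- function(values, censored = rep(FALSE, length(values)),
                               cap = Inf) {
  if (length(values) == 0L) stop("summary error: no values")
  if (length(censored) != length(values))
    stop("summary error: censored flags must match values in length")
  if (any(censored & values != cap))
    stop("summary error: censored entries must equal the cap (", cap, ")")
  if (any(values > cap + 1e-12))
    stop("summary error: values exceed the cap")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  n <- length(values)
  structure(
    list(mean = mean(values),
         sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
         median = q[2L], iqr_lo = q[1L], iqr_hi = q[3L],
         n = n, n_censored = sum(censored),
         median_is_lower_bound = sum(censored) > n / 2),
    class = "bw_summary")
}

#' @export
print.bw_summary <- function(x, ...) {
  cat("mean ", signif(x$mean, 5), " +/- ", signif(x$sem, 4), " (SEM), median ",
      signif(x$median, 5), if (x$median_is_lower_bound) " (lower bound)",
      " [IQR ", signif(x$iqr_lo, 5), "-", signif(x$iqr_hi, 5), "], n = ",
      x$n, " (", x$n_censored, " censored)\n", sep = "")
  invisible(x)
}
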