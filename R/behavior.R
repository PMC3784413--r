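# Analysis of the hidden-food olfactory assay with its motivation and
# motor controls, over the tidy tables written by the behavior simulator
# (or any tables with the same columns).

check_behavior_dataset <- function(dataset, need = c("latency", "intake", "weight")) {
  if (inherits(dataset, "bw_behavior_study") || is.list(dataset)) {
    missing <- setdiff(need, names(dataset))
    if (length(missing))
      stop("behavior error: dataset is missing table(s): ",
           paste(missing, collapse = ", "))
  } else stop("behavior error: expected a list of behavior tables")
  if ("latency" %in% need) {
    lat <- dataset$latency
    cols <- c("animal_id", "group", "week", "task", "latency_s", "censored")
    if (!all(cols %in% names(lat)))
      stop("behavior error: latency table needs columns ",
           paste(cols, collapse = ", "))
  }
  invisible(dataset)
}

#' Count hidden-food failures in one group-week cell
#'
#' A failure is a trial censored at the cap: the animal did not reach the
#' hidden food within the allowed time.
#'
#' @param records Latency data.frame (columns `group`, `week`, `task`,
#'   `censored`); only hidden-task rows are counted.
#' @param week,group Cell selectors.
#' @return Integer vector `c(failed, total)`.
#' @export
count_failures <- function(records, week, group) {
  cell <- records[records$week == week & records$group == group &
                    records$task == "hidden", , drop = FALSE]
  if (nrow(cell) == 0L)
    stop("behavior error: empty cell (week ", week, ", group ", group, ")")
  c(failed = sum(cell$censored), total = nrow(cell))
}

#' Weekly analysis of the hidden-food task
#'
#' Per test week: censoring-aware group summaries (median + IQR, failure
#' counts), the between-group comparison (two-group Kruskal-Wallis rank
#' test, equivalent to a rank-sum test), and the within-group comparison
#' of each later week against week 1 (Wilcoxon signed rank, paired by
#' animal).
#'
#' @param dataset A `bw_behavior_study` or list with a `latency` table.
#' @param alpha Significance level (default 0.05).
#' @param cap_s Censoring cap in seconds (default 600).
#' @return List with `weekly` (one row per week: summaries, failures,
#'   `p_between`, `significant`) and `within_group` (one row per group x
#'   later week: `p_vs_week1`).
#' @export
analyze_hidden_food <- function(dataset, alpha = 0.05, cap_s = 600) {
  check_behavior_dataset(dataset, need = "latency")
  lat <- dataset$latency[dataset$latency$task == "hidden", , drop = FALSE]
  weeks <- sort(unique(lat$week))
  groups <- c("vehicle", "abeta")
  for (w in weeks) for (g in groups)
    if (!any(lat$week == w & lat$group == g))
      stop("behavior error: missing cell (week ", w, ", group ", g, ")")

  weekly <- do.call(rbind, lapply(weeks, function(w) {
    cells <- lapply(groups, function(g)
      lat[lat$week == w & lat$group == g, , drop = FALSE])
    names(cells) <- groups
    sums <- lapply(cells, function(cc)
      summarize_censored(cc$latency_s, cc$censored, cap = cap_s))
    kw <- kruskal_wallis(lapply(cells, `[[`, "latency_s"))
    data.frame(
      week = w,
      median_vehicle = sums$vehicle$median,
      iqr_lo_vehicle = sums$vehicle$iqr_lo, iqr_hi_vehicle = sums$vehicle$iqr_hi,
      median_abeta = sums$abeta$median,
      iqr_lo_abeta = sums$abeta$iqr_lo, iqr_hi_abeta = sums$abeta$iqr_hi,
      median_abeta_lower_bound = sums$abeta$median_is_lower_bound,
      failed_vehicle = sums$vehicle$n_censored, n_vehicle = sums$vehicle$n,
      failed_abeta = sums$abeta$n_censored, n_abeta = sums$abeta$n,
      statistic = kw$statistic, p_between = kw$p_value,
      significant = !kw$degenerate && kw$p_value < alpha,
      stringsAsFactors = FALSE)
  }))

  within <- list()
  for (g in groups) {
    base <- lat[lat$week == weeks[1L] & lat$group == g, ]
    base <- base[order(base$animal_id), ]
    for (w in weeks[-1L]) {
      cur <- lat[lat$week == w & lat$group == g, ]
      cur <- cur[order(cur$animal_id), ]
      common <- intersect(base$animal_id, cur$animal_id)
      wt <- wilcoxon_signed_rank(
        cur$latency_s[match(common, cur$animal_id)],
        base$latency_s[match(common, base$animal_id)])
      within[[length(within) + 1L]] <- data.frame(
        group = g, week = w, statistic = wt$statistic,
        p_vs_week1 = wt$p_value,
        significant = !wt$degenerate && wt$p_value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  list(weekly = weekly, within_group = do.call(rbind, within))
}

#' Motivation and motor control comparisons
#'
#' Group comparisons for the control measurements that must be null for a
#' hidden-food deficit to be interpretable as olfactory: visible-food
#' latency (per feeding status), food intake at each measurement window,
#' and weekly weight gain. Each uses the same censoring-aware summaries
#' and the two-group Kruskal-Wallis rank test.
#'
#' @param dataset A `bw_behavior_study` or list with `latency`, `intake`,
#'   and `weight` tables.
#' @param alpha Significance level (default 0.05).
#' @param cap_s Censoring cap for latencies (default 600).
#' @return Data.frame with one row per control comparison: `comparison`,
#'   `stratum`, `statistic`, `p`, `significant`.
#' @export
analyze_controls <- function(dataset, alpha = 0.05, cap_s = 600) {
  check_behavior_dataset(dataset)
  rows <- list()
  add <- function(comparison, stratum, values_by_group) {
    kw <- kruskal_wallis(values_by_group)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, stratum = stratum,
      statistic = kw$statistic, p = kw$p_value,
      significant = !kw$degenerate && kw$p_value < alpha,
      stringsAsFactors = FALSE)
  }

  vis <- dataset$latency[dataset$latency$task == "visible", , drop = FALSE]
  if (nrow(vis) == 0L)
    stop("behavior error: missing table: visible-food latencies")
  strata <- unique(vis$feeding %||% "fed")
  for (s in strata) {
    sub <- if (is.null(vis$feeding)) vis else vis[vis$feeding == s, ]
    add("visible_food_latency", s,
        split(sub$latency_s, factor(sub$group, levels = c("vehicle", "abeta"))))
  }
  for (w in sort(unique(dataset$intake$window_min))) {
    sub <- dataset$intake[dataset$intake$window_min == w, ]
    add("food_intake", paste0(w, "_min"),
        split(sub$grams, factor(sub$group, levels = c("vehicle", "abeta"))))
  }
  for (w in sort(unique(dataset$weight$week))) {
    sub <- dataset$weight[dataset$weight$week == w, ]
    add("weight_gain", paste0("week_", w),
        split(sub$pct_of_baseline, factor(sub$group, levels = c("vehicle", "abeta"))))
  }
  do.call(rbind, rows)
}

#' Full behavioral report with the olfactory-deficit interpretation guard
#'
#' Runs [analyze_hidden_food()] and [analyze_controls()] and applies the
#' interpretation rule of the assay: a significant hidden-food group
#' effect is reported as an olfactory deficit only when the same
#' dataset's visible-food, intake, and weight comparisons are all
#' non-significant (otherwise a motivational or motor confound cannot be
#' excluded).
#'
#' @param dataset A `bw_behavior_study` or equivalent list of tables.
#' @param alpha Significance level (default 0.05).
#' @param cap_s Censoring cap in seconds (default 600).
#' @return A `bw_behavior_report` list: `hidden`, `controls`,
#'   `hidden_effect_weeks` (weeks with a significant group difference),
#'   `controls_clean`, and `olfactory_deficit`.
#' @export
behavior_report <- function(dataset, alpha = 0.05, cap_s = 600) {
  hidden <- analyze_hidden_food(dataset, alpha = alpha, cap_s = cap_s)
  controls <- analyze_controls(dataset, alpha = alpha, cap_s = cap_s)
  effect_weeks <- hidden$weekly$week[hidden$weekly$significant]
  controls_clean <- !any(controls$significant)
  structure(
    list(hidden = hidden, controls = controls,
         hidden_effect_weeks = effect_weeks,
         controls_clean = controls_clean,
         olfactory_deficit = length(effect_weeks) > 0 && controls_clean),
    class = "bw_behavior_report")
}

#' @export
print.bw_behavior_report <- function(x, ...) {
  cat("<behavior report>\n")
  cat("hidden-food group effect in week(s): ",
      if (length(x$hidden_effect_weeks)) paste(x$hidden_effect_weeks, collapse = ", ")
      else "none", "\n", sep = "")
  cat("controls clean (visible/intake/weight all non-significant): ",
      x$controls_clean, "\n", sep = "")
  cat("interpretation: ",
      if (x$olfactory_deficit) "olfactory deficit"
      else "no attributable olfactory deficit", "\n", sep = "")
  invisible(x)
}
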