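#' Design of a simulated hidden-food olfactory behavioral study
#'
#' Describes the generative model of the behavioral experiment: two groups
#' (vehicle- vs amyloid-beta-injected animals) tested weekly for the
#' latency to find a hidden piece of chocolate, right-censored at a 600 s
#' cap; a visible-food task (stratified by feeding status) and food-intake
#' and weight-gain measurements as motivation/motor controls that carry no
#' group effect. Latencies are lognormal before censoring: the emulated
#' assay reports only means and medians, so the family is a package
#' choice, chosen because latency data are positive and right-skewed.
#'
#' Default location parameters reproduce the emulated study's printed
#' cell means: vehicle latencies stay near 2 min every week, while the
#' treated group is unimpaired at week 1 and has most of its distribution
#' above the cap from week 2 on.
#'
#' @param n_per_group Named integer vector `c(vehicle = ..., abeta = ...)`
#'   (default 10 and 9; each must be at least 2).
#' @param weeks Integer vector of test weeks (default 1:4).
#' @param latency_location Matrix of log-scale locations (log-seconds),
#'   rows named by group, columns by week, for the hidden-food task.
#' @param latency_scale Log-scale spread (sdlog) of latencies, > 0.
#' @param cap_s Censoring cap in seconds (default 600; `Inf` disables
#'   censoring).
#' @param visible_location Log-scale location of visible-food latencies
#'   (no group effect; default log(20) s).
#' @param visible_scale Log-scale spread of visible-food latencies.
#' @param intake_means Named vector of mean grams eaten in the 30- and
#'   120-min windows, `c(min30 = ..., min120 = ...)` (no group effect).
#' @param intake_sd Standard deviation of intake (g).
#' @param weight_gain_slope Mean weekly weight gain in percent of baseline
#'   body weight (no group effect).
#' @param weight_sd Standard deviation of the weekly weight measurements
#'   (percentage points).
#' @param seed Integer seed.
#'
#' @return A `bw_behavior_design` list.
#' @export
behavior_design <- function(n_per_group = c(vehicle = 10, abeta = 9),
                            weeks = 1:4,
                            latency_location = NULL,
                            latency_scale = 0.9,
                            cap_s = 600,
                            visible_location = log(20),
                            visible_scale = 0.5,
                            intake_means = c(min30 = 3.5, min120 = 11),
                            intake_sd = 1,
                            weight_gain_slope = 4.5,
                            weight_sd = 2,
                            seed = 1L) {
  if (is.null(names(n_per_group)) ||
      !all(c("vehicle", "abeta") %in% names(n_per_group)))
    stop("behavior design error: n_per_group must be named with 'vehicle' and 'abeta'")
  if (any(n_per_group < 2))
    stop("behavior design error: n_per_group must be >= 2")
  if (latency_scale <= 0 || visible_scale <= 0)
    stop("behavior design error: scale parameters must be positive")
  if (cap_s <= 0)
    stop("behavior design error: cap_s must be positive")
  if (is.null(latency_location)) {
    latency_location <- rbind(
      vehicle = rep(log(110), length(weeks)),
      abeta   = c(log(130), log(620), log(650), log(900))[seq_along(weeks)]
    )
    colnames(latency_location) <- weeks
  }
  if (!all(is.finite(latency_location)))
    stop("behavior design error: latency_location must be finite")
  structure(
    list(n_per_group = n_per_group, weeks = weeks,
         latency_location = latency_location, latency_scale = latency_scale,
         cap_s = cap_s, visible_location = visible_location,
         visible_scale = visible_scale, intake_means = intake_means,
         intake_sd = intake_sd, weight_gain_slope = weight_gain_slope,
         weight_sd = weight_sd, seed = as.integer(seed)),
    class = "bw_behavior_design"
  )
}

#' Simulate a complete hidden-food behavioral study
#'
#' Draws hidden-food latencies (lognormal, right-censored at the cap with
#' the censored flag set), visible-food latencies stratified by feeding
#' status (fed / food-deprived, no group effect), and per-animal
#' food-intake and weight-gain control tables (no group effect). Seeded
#' and reproducible: the same design yields identical tables.
#'
#' @param design A [behavior_design()].
#' @return A `bw_behavior_study`: list of data.frames `latency`
#'   (animal_id, group, week, task, feeding, latency_s, censored),
#'   `intake` (animal_id, group, window_min, grams) and `weight`
#'   (animal_id, group, week, pct_of_baseline).
#' @export
simulate_behavior_study <- function(design) {
  stopifnot(inherits(design, "bw_behavior_design"))
  set.seed(design$seed)
  groups <- c("vehicle", "abeta")
  ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(design$n_per_group[[g]]))))
  grp <- rep(groups, times = design$n_per_group[groups])

  draw_cell <- function(meanlog, sdlog, n) {
    raw <- stats::rlnorm(n, meanlog, sdlog)
    cens <- raw > design$cap_s
    data.frame(latency_s = pmin(raw, design$cap_s), censored = cens)
  }

  lat <- list()
  for (w in seq_along(design$weeks)) {
    for (g in groups) {
      sel <- grp == g
      cell <- draw_cell(design$latency_location[g, w], design$latency_scale,
                        sum(sel))
      lat[[length(lat) + 1L]] <- data.frame(
        animal_id = ids[sel], group = g, week = design$weeks[w],
        task = "hidden", feeding = "fed", cell, stringsAsFactors = FALSE)
    }
  }
  # visible-food control task, stratified by feeding status (deprived in
  # week 3, fed in week 4 as in the emulated design); no group effect
  vis_weeks <- utils::tail(design$weeks, 2)
  feedings <- c("deprived", "fed")
  for (i in seq_along(vis_weeks)) {
    for (g in groups) {
      sel <- grp == g
      cell <- draw_cell(design$visible_location, design$visible_scale, sum(sel))
      lat[[length(lat) + 1L]] <- data.frame(
        animal_id = ids[sel], group = g, week = vis_weeks[i],
        task = "visible", feeding = feedings[i], cell, stringsAsFactors = FALSE)
    }
  }
  latency <- do.call(rbind, lat)
  rownames(latency) <- NULL

  intake <- do.call(rbind, lapply(names(design$intake_means), function(wn) {
    data.frame(animal_id = ids, group = grp,
               window_min = as.integer(sub("min", "", wn)),
               grams = pmax(0, stats::rnorm(length(ids),
                                            design$intake_means[[wn]],
                                            design$intake_sd)),
               stringsAsFactors = FALSE)
  }))
  rownames(intake) <- NULL

  weight <- do.call(rbind, lapply(design$weeks, function(w) {
    data.frame(animal_id = ids, group = grp, week = w,
               pct_of_baseline = 100 + design$weight_gain_slope * w +
                 stats::rnorm(length(ids), 0, design$weight_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(weight) <- NULL

  structure(list(latency = latency, intake = intake, weight = weight,
                 design = design),
            class = "bw_behavior_study")
}
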