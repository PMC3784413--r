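#' Describe how each condition attenuates network power
#'
#' An attenuation model assigns every condition a plateau power gain (the
#' multiplicative factor the expected power spectral density approaches
#' while that condition persists) together with onset and washout kinetics.
#' The model is the ground truth the simulator realizes: all effect sizes
#' of the emulated experiments are power ratios, so attenuation acts on
#' power (sample amplitudes are scaled by the square root of the gain).
#'
#' Plateau gains may be age-dependent: pass either a named numeric vector
#' (one gain per condition, any age) or a data.frame with columns
#' `condition`, `age_weeks`, `gain`.
#'
#' @param plateau_gain Named numeric vector (names are condition labels) or
#'   data.frame with columns `condition`, `age_weeks`, `gain`. Gains must
#'   lie in \[0, 1.2\]; `inverse_abeta` must be exactly 1 (inactive
#'   peptide) and `lidocaine` at most 0.05 (near-total suppression).
#' @param onset_halftime_min Halftime (minutes) of the exponential approach
#'   of the gain toward its plateau when a drug epoch begins. The default
#'   17 min places the 30 nM time-course near its observed anchors
#'   (about 73% of control at 15 min and 62% at 25 min of exposure for a
#'   0.40 plateau). Use 0 for an instantaneous step.
#' @param washout_halftime_min Halftime (minutes) of the relaxation of the
#'   gain back toward 1 during washout epochs.
#'
#' @return A `bw_attenuation` model object.
#' @examples
#' attenuation_model(c(control = 1, abeta_30nM = 0.40, washout = 1))
#' @export
attenuation_model <- function(plateau_gain,
                              onset_halftime_min = 17,
                              washout_halftime_min = 15) {
  if (!is.finite(onset_halftime_min) || onset_halftime_min < 0)
    stop("attenuation error: onset_halftime_min must be a nonnegative finite number")
  if (!is.finite(washout_halftime_min) || washout_halftime_min < 0)
    stop("attenuation error: washout_halftime_min must be a nonnegative finite number")

  if (is.data.frame(plateau_gain)) {
    need <- c("condition", "age_weeks", "gain")
    if (!all(need %in% names(plateau_gain)))
      stop("attenuation error: plateau_gain data.frame needs columns ",
           paste(need, collapse = ", "))
    tab <- plateau_gain[, need]
  } else {
    if (is.null(names(plateau_gain)) || any(names(plateau_gain) == ""))
      stop("attenuation error: plateau_gain vector must be named by condition")
    tab <- data.frame(condition = names(plateau_gain), age_weeks = NA_real_,
                      gain = as.numeric(plateau_gain), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(tab$condition, condition_labels())
  if (length(unknown))
    stop("attenuation error: unknown condition label(s): ",
         paste(unknown, collapse = ", "))
  if (any(!is.finite(tab$gain)) || any(tab$gain < 0) || any(tab$gain > 1.2))
    stop("attenuation error: plateau gains must lie in [0, 1.2]")
  if (any(tab$condition == "inverse_abeta" & tab$gain != 1))
    stop("attenuation error: inverse_abeta plateau gain must be exactly 1")
  if (any(tab$condition == "lidocaine" & tab$gain > 0.05))
    stop("attenuation error: lidocaine plateau gain must be <= 0.05")

  structure(
    list(plateau = tab,
         onset_halftime_min = onset_halftime_min,
         washout_halftime_min = washout_halftime_min),
    class = "bw_attenuation"
  )
}

# Look up the plateau gain for one condition at a given age.
resolve_plateau <- function(model, condition, age_weeks = NA_real_) {
  tab <- model$plateau
  hit <- tab$condition == condition &
    (is.na(tab$age_weeks) | (!is.na(age_weeks) & tab$age_weeks == age_weeks))
  if (!any(hit))
    stop("attenuation error: no plateau gain defined for condition '",
         condition, "'", if (!is.na(age_weeks)) paste0(" at age ", age_weeks, " weeks"))
  tab$gain[which(hit)[1L]]
}

#' Realize a piecewise-exponential power gain envelope from a timeline
#'
#' Translates a condition timeline plus an attenuation model into the
#' ground-truth gain envelope g(t): g = 1 throughout control epochs; within
#' a drug epoch the gain decays exponentially from its value at epoch entry
#' toward the condition's plateau with halftime `onset_halftime_min`;
#' during washout it relaxes toward 1 with `washout_halftime_min`. The
#' envelope is continuous at epoch boundaries (each epoch starts from the
#' previous epoch's exit gain).
#'
#' @param timeline A [condition_timeline()].
#' @param model An [attenuation_model()].
#' @param age_weeks Animal age in weeks, used to resolve age-dependent
#'   plateau gains (may be `NA` for age-independent models).
#'
#' @return A `bw_envelope`: data.frame of epochs with columns `condition`,
#'   `start_min`, `end_min`, `entry_gain`, `target_gain`, `halftime_min`.
#'   Evaluate it with [gain_at()].
#' @examples
#' tl <- condition_timeline(c("control", "abeta_30nM"), c(20, 60))
#' env <- build_gain_envelope(tl, attenuation_model(
#'   c(control = 1, abeta_30nM = 0.40), onset_halftime_min = 10))
#' gain_at(env, c(20, 30, 80))  # 1 at entry, 0.70 ten minutes in
#' @export
build_gain_envelope <- function(timeline, model, age_weeks = NA_real_) {
  stopifnot(inherits(model, "bw_attenuation"))
  timeline <- as_bw_timeline(timeline)

  n <- nrow(timeline)
  entry <- target <- halftime <- numeric(n)
  g_exit <- 1
  for (i in seq_len(n)) {
    cond <- timeline$condition[i]
    dur <- timeline$end_min[i] - timeline$start_min[i]
    if (cond == "control") {
      entry[i] <- 1; target[i] <- 1; halftime[i] <- Inf
    } else if (cond == "washout") {
      entry[i] <- g_exit; target[i] <- 1
      halftime[i] <- model$washout_halftime_min
    } else {
      entry[i] <- g_exit
      target[i] <- resolve_plateau(model, cond, age_weeks)
      halftime[i] <- model$onset_halftime_min
    }
    g_exit <- epoch_gain(dur, entry[i], target[i], halftime[i])
  }
  env <- data.frame(
    condition = timeline$condition,
    start_min = timeline$start_min,
    end_min = timeline$end_min,
    entry_gain = entry,
    target_gain = target,
    halftime_min = halftime,
    stringsAsFactors = FALSE
  )
  class(env) <- c("bw_envelope", "data.frame")
  env
}

# Gain after `dt` minutes inside one epoch.
epoch_gain <- function(dt, entry, target, halftime) {
  if (!is.finite(halftime)) return(rep_len(entry, length(dt)))
  if (halftime == 0) return(ifelse(dt > 0, target, entry))
  target + (entry - target) * 2^(-dt / halftime)
}

#' Evaluate a gain envelope at arbitrary times
#'
#' @param envelope A `bw_envelope` from [build_gain_envelope()], or any
#'   data.frame with the same columns (used when replaying ground truth
#'   from a recording manifest).
#' @param t_min Numeric vector of times in minutes. Times before the first
#'   epoch evaluate to the first epoch's entry gain; times at or beyond the
#'   last epoch's end evaluate to the last epoch's exit gain.
#'
#' @return Numeric vector of dimensionless power gains.
#' @export
gain_at <- function(envelope, t_min) {
  idx <- findInterval(t_min, envelope$start_min)
  idx[idx < 1L] <- 1L
  dt <- pmax(0, pmin(t_min, envelope$end_min[idx]) - envelope$start_min[idx])
  g <- numeric(length(t_min))
  for (i in unique(idx)) {
    sel <- idx == i
    g[sel] <- epoch_gain(dt[sel], envelope$entry_gain[i],
                         envelope$target_gain[i], envelope$halftime_min[i])
  }
  g
}

#' Build a constant (flat) gain envelope over a timeline
#'
#' Convenience for null experiments and ground-truth recovery tests: every
#' epoch holds the same constant gain (step envelopes with
#' `onset_halftime_min = 0` can be built with [build_gain_envelope()]).
#'
#' @param timeline A [condition_timeline()].
#' @param gain Constant dimensionless power gain (default 1).
#' @return A `bw_envelope`.
#' @export
flat_gain_envelope <- function(timeline, gain = 1) {
  timeline <- as_bw_timeline(timeline)
  if (!is.finite(gain) || gain < 0)
    stop("attenuation error: gain must be nonnegative and finite")
  env <- data.frame(
    condition = timeline$condition,
    start_min = timeline$start_min,
    end_min = timeline$end_min,
    entry_gain = gain,
    target_gain = gain,
    halftime_min = Inf,
    stringsAsFactors = FALSE
  )
  class(env) <- c("bw_envelope", "data.frame")
  env
}
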