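#' Condition labels understood by the simulator and analysis pipeline
#'
#' The experimental conditions an epoch of a recording timeline can carry:
#' the drug-free baseline (`control`), bath application of amyloid-beta
#' oligomers at three concentrations (`abeta_3nM`, `abeta_10nM`,
#' `abeta_30nM`), the reversed-sequence control peptide (`inverse_abeta`),
#' drug washout (`washout`), and the activity-abolishing sodium-channel
#' blocker (`lidocaine`).
#'
#' @return Character vector of valid condition labels.
#' @export
condition_labels <- function() {
  c("control", "abeta_3nM", "abeta_10nM", "abeta_30nM",
    "inverse_abeta", "washout", "lidocaine")
}

#' Build an experiment timeline of contiguous condition epochs
#'
#' A timeline describes which experimental condition the bath is in as a
#' function of recording time. Epochs must be contiguous, non-overlapping,
#' and start with a `control` baseline, mirroring the usual slice protocol
#' (a 15-20 min control recording followed by drug epochs).
#'
#' @param conditions Character vector of condition labels
#'   (see [condition_labels()]).
#' @param durations_min Numeric vector of epoch durations in minutes
#'   (same length as `conditions`).
#' @param start_min Start time of the first epoch in minutes (default 0).
#'
#' @return A `bw_timeline`: data.frame with columns `condition`,
#'   `start_min`, `end_min` and one row per epoch.
#' @examples
#' condition_timeline(c("control", "abeta_30nM", "washout"), c(20, 60, 60))
#' @export
condition_timeline <- function(conditions, durations_min, start_min = 0) {
  if (length(conditions) != length(durations_min) || length(conditions) == 0L)
    stop("timeline error: 'conditions' and 'durations_min' must be non-empty and of equal length")
  unknown <- setdiff(conditions, condition_labels())
  if (length(unknown))
    stop("timeline error: unknown condition label(s): ", paste(unknown, collapse = ", "))
  if (any(!is.finite(durations_min)) || any(durations_min <= 0))
    stop("timeline error: epoch durations must be positive and finite")
  if (conditions[1L] != "control")
    stop("timeline error: the first epoch must be 'control'")
  ends <- start_min + cumsum(durations_min)
  tl <- data.frame(
    condition = conditions,
    start_min = c(start_min, ends[-length(ends)]),
    end_min   = ends,
    stringsAsFactors = FALSE
  )
  class(tl) <- c("bw_timeline", "data.frame")
  tl
}

# Validate a timeline-shaped data.frame (used when reading manifests).
as_bw_timeline <- function(df) {
  need <- c("condition", "start_min", "end_min")
  if (!all(need %in% names(df)))
    stop("timeline error: expected columns ", paste(need, collapse = ", "))
  df <- df[order(df$start_min), need, drop = FALSE]
  condition_timeline(df$condition, df$end_min - df$start_min,
                     start_min = df$start_min[1L])
}

timeline_duration_min <- function(timeline) {
  max(timeline$end_min)
}

#' @export
print.bw_timeline <- function(x, ...) {
  cat("<experiment timeline> ", nrow(x), " epoch(s), ",
      timeline_duration_min(x), " min total\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
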