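#' Time-course of normalized full-band power
#'
#' Per scheduled segment at or after drug onset, the band power
#' (full 1-50 Hz range by default) normalized to the reference-condition
#' baseline: the mean band power of the last
#' `n_condition_segments_averaged` segments that end before onset within
#' the reference condition. Times are reported in minutes from drug onset.
#'
#' Onset defaults to the end of the first epoch carrying
#' `reference_condition`; for single-epoch recordings (e.g. long-recording
#' stability controls) pass `onset_min` explicitly to split the baseline
#' from the observation period within the same condition.
#'
#' @param recording A `bw_recording`.
#' @param schedule A [segment_schedule()].
#' @param reference_condition Condition used as the 100% baseline
#'   (default `"control"`).
#' @param onset_min Time of drug onset in minutes (default: end of the
#'   first reference epoch).
#' @param band A [band()] to integrate (default full 1-50 Hz).
#' @return A `bw_timecourse`: data.frame with columns `time_min` (minutes
#'   from onset), `condition`, and `normalized_power` (% of baseline).
#' @export
power_time_course <- function(recording, schedule = segment_schedule(),
                              reference_condition = "control",
                              onset_min = NULL,
                              band = bulbwave::band("full", 1, 50)) {
  segments <- extract_segments(recording, schedule)
  conds <- vapply(segments, function(s) s$condition %||% NA_character_,
                  character(1))
  if (!any(conds == reference_condition, na.rm = TRUE))
    stop("time-course error: reference condition '", reference_condition,
         "' has no whole segments")
  if (is.null(onset_min)) {
    ep <- which(recording$timeline$condition == reference_condition)[1L]
    if (is.na(ep))
      stop("time-course error: reference condition '", reference_condition,
           "' not present in the timeline")
    onset_min <- recording$timeline$end_min[ep]
  }

  pw <- vapply(segments, function(s) {
    band_power(periodogram_hamming(s, recording$sampling_rate,
                                   f_min = band$lo, f_max = band$hi), band)
  }, numeric(1))
  starts <- vapply(segments, `[[`, numeric(1), "start_min")

  base_idx <- which(conds == reference_condition &
                      starts + schedule$segment_length_s / 60 <= onset_min + 1e-9)
  nn <- schedule$n_condition_segments_averaged
  if (length(base_idx) < nn)
    stop("time-course error: reference condition '", reference_condition,
         "' has ", length(base_idx), " baseline segment(s) before onset; ",
         nn, " required")
  baseline <- mean(pw[utils::tail(base_idx, nn)])

  obs <- which(starts >= onset_min - 1e-9)
  tc <- data.frame(time_min = starts[obs] - onset_min,
                   condition = conds[obs],
                   normalized_power = normalize_power(pw[obs], baseline),
                   stringsAsFactors = FALSE)
  class(tc) <- c("bw_timecourse", "data.frame")
  attr(tc, "onset_min") <- onset_min
  attr(tc, "band") <- band$name
  tc
}

#' Full spectral analysis of a cohort of recordings
#'
#' For each recording: the condition-averaged spectrum of every condition
#' (last-two-segment average), its integrated absolute power per band, the
#' power normalized to the same band's control value (control = 100%), and
#' the condition's peak frequency. Cohort cells are summarized as
#' mean +/- SEM.
#'
#' @param recordings List of `bw_recording` objects sharing the same
#'   timeline structure (same condition sequence and epoch boundaries).
#' @param schedule A [segment_schedule()].
#' @param bands Named list of [band()]s (default [default_bands()]).
#' @param f_min,f_max Spectrum range in Hz.
#' @return A `bw_cohort` list with `per_recording` (one row per recording
#'   x condition x band: `recording`, `condition`, `band`,
#'   `absolute_power`, `normalized_power`, `peak_frequency`) and `summary`
#'   (mean, sem, n per condition x band; SEM is `NA` for n = 1).
#' @export
analyze_cohort <- function(recordings, schedule = segment_schedule(),
                           bands = default_bands(), f_min = 1, f_max = 50) {
  if (length(recordings) == 0L) stop("cohort error: no recordings")
  tls <- lapply(recordings, function(r) r$timeline)
  ref <- tls[[1L]]
  same <- vapply(tls, function(t)
    identical(t$condition, ref$condition) &&
      isTRUE(all.equal(t$start_min, ref$start_min)) &&
      isTRUE(all.equal(t$end_min, ref$end_min)), logical(1))
  if (!all(same))
    stop("cohort error: recordings have heterogeneous timelines")

  rows <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    rec_id <- rec$subject_meta$slice_id %||% sprintf("recording%02d", i)
    segments <- extract_segments(rec, schedule)
    conds <- unique(ref$condition)
    specs <- lapply(conds, function(cn)
      condition_spectrum(rec, cn, schedule, f_min = f_min, f_max = f_max,
                         segments = segments))
    names(specs) <- conds
    ctrl_bp <- vapply(bands, function(b) band_power(specs[["control"]], b),
                      numeric(1))
    for (cn in conds) {
      bp <- vapply(bands, function(b) band_power(specs[[cn]], b), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        recording = rec_id, condition = cn,
        band = vapply(bands, `[[`, character(1), "name"),
        absolute_power = bp,
        normalized_power = normalize_power(bp, ctrl_bp),
        peak_frequency = peak_frequency(specs[[cn]]),
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL

  agg <- function(v) c(mean = mean(v),
                       sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                             else NA_real_,
                       n = length(v))
  key <- interaction(per$condition, per$band, drop = TRUE)
  summ <- do.call(rbind, lapply(split(per, key), function(d) {
    s <- agg(d$normalized_power)
    p <- agg(d$peak_frequency)
    data.frame(condition = d$condition[1L], band = d$band[1L],
               mean_normalized = s[["mean"]], sem_normalized = s[["sem"]],
               mean_peak_hz = p[["mean"]], sem_peak_hz = p[["sem"]],
               n = as.integer(s[["n"]]), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_recording = per, summary = summ,
                 schedule = schedule),
            class = "bw_cohort")
}

#' @export
print.bw_cohort <- function(x, ...) {
  cat("<cohort spectral analysis> ",
      length(unique(x$per_recording$recording)), " recording(s)\n", sep = "")
  print.data.frame(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
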