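#' Segment schedule for spectral analysis
#'
#' The classical analysis schedule for long slice recordings: one segment
#' of `segment_length_s` seconds is taken every `period_min` minutes, and
#' per experimental condition the spectra of the last
#' `n_condition_segments_averaged` whole segments are averaged.
#'
#' @param segment_length_s Segment length in seconds (default 20).
#' @param period_min Segment cadence in minutes (default 5).
#' @param n_condition_segments_averaged Number of trailing segments
#'   averaged per condition (default 2).
#' @return A `bw_schedule` list.
#' @export
segment_schedule <- function(segment_length_s = 20, period_min = 5,
                             n_condition_segments_averaged = 2) {
  if (segment_length_s <= 0)
    stop("schedule error: segment_length_s must be positive")
  if (period_min * 60 < segment_length_s)
    stop("schedule error: period_min * 60 must be >= segment_length_s")
  if (n_condition_segments_averaged < 1)
    stop("schedule error: n_condition_segments_averaged must be >= 1")
  structure(list(segment_length_s = segment_length_s, period_min = period_min,
                 n_condition_segments_averaged = n_condition_segments_averaged),
            class = "bw_schedule")
}

#' Cut a recording into scheduled analysis segments
#'
#' Segments start at t = 0, period, 2 x period, ... from the beginning of
#' the recording and have exactly `segment_length_s` seconds. A segment is
#' assigned to a condition only if it lies wholly inside that condition's
#' epoch; segments straddling an epoch boundary (or extending past the end
#' of the recording) carry `NA` and are excluded from condition averages.
#'
#' @param recording A `bw_recording`.
#' @param schedule A [segment_schedule()].
#' @return A list of segments, each a list with `samples`, `start_s`,
#'   `start_min`, `condition`, and `epoch` (epoch row index or `NA`).
#' @export
extract_segments <- function(recording, schedule = segment_schedule()) {
  stopifnot(inherits(recording, "bw_recording"))
  fs <- recording$sampling_rate
  seg_n <- round(schedule$segment_length_s * fs)
  n <- length(recording$samples)
  if (n < seg_n)
    stop("segment error: recording (", round(n / fs, 2),
         " s) is shorter than one segment (", schedule$segment_length_s, " s)")
  step_n <- round(schedule$period_min * 60 * fs)
  starts <- seq(0L, n - seg_n, by = step_n)
  tl <- recording$timeline
  lapply(starts, function(s0) {
    start_s <- s0 / fs
    end_s <- start_s + schedule$segment_length_s
    ep <- which(tl$start_min * 60 <= start_s + 1e-9 &
                  end_s <= tl$end_min * 60 + 1e-9)
    ep <- if (length(ep)) ep[1L] else NA_integer_
    list(samples = recording$samples[(s0 + 1L):(s0 + seg_n)],
         start_s = start_s, start_min = start_s / 60,
         condition = if (is.na(ep)) NA_character_ else tl$condition[ep],
         epoch = ep)
  })
}

#' Hamming-windowed periodogram of one segment
#'
#' Computes a single full-segment periodogram with a Hamming taper,
#' corrected by the window's mean square power so that the integral of the
#' returned (one-sided) power spectral density over all frequencies equals
#' the segment's variance (Parseval, within about 1% for broadband
#' segments). The segment mean is removed before tapering. Frequency
#' resolution is 1/duration (0.05 Hz for 20-s segments); the spectrum is
#' returned restricted to `[f_min, f_max]`.
#'
#' @param segment Numeric vector of samples (uV), or a segment from
#'   [extract_segments()].
#' @param sampling_rate Sampling rate in Hz (taken from the segment's
#'   recording when a plain vector is not supplied).
#' @param f_min,f_max Frequency range to retain, in Hz (defaults 1 and 50).
#' @return A `bw_spectrum`: list with `freqs` (Hz), `power` (uV^2/Hz) and
#'   `provenance`.
#' @examples
#' fs <- 1000; t <- seq(0, 20 - 1/fs, by = 1/fs)
#' sp <- periodogram_hamming(sin(2 * pi * 10 * t), fs)
#' sp$freqs[which.max(sp$power)]  # 10 Hz
#' @export
periodogram_hamming <- function(segment, sampling_rate, f_min = 1, f_max = 50) {
  prov <- list()
  if (is.list(segment)) {
    prov <- list(start_s = segment$start_s, condition = segment$condition)
    segment <- segment$samples
  }
  x <- as.numeric(segment)
  n <- length(x)
  if (n < 2L) stop("spectrum error: segment too short")
  ny <- sampling_rate / 2
  if (f_max > ny + 1e-9)
    stop("spectrum error: f_max (", f_max, " Hz) exceeds the Nyquist frequency (",
         ny, " Hz)")
  if (f_min < 0 || f_min >= f_max)
    stop("spectrum error: need 0 <= f_min < f_max")

  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  x <- (x - mean(x)) * w
  X <- stats::fft(x)
  k <- 0:(n %/% 2)                      # one-sided bins
  pw <- Mod(X[k + 1L])^2 / (sampling_rate * sum(w^2))
  dbl <- rep(2, length(k))
  dbl[1L] <- 1
  if (n %% 2 == 0) dbl[length(k)] <- 1  # Nyquist bin not doubled
  pw <- pw * dbl
  freqs <- k * sampling_rate / n

  keep <- freqs >= f_min - 1e-9 & freqs <= f_max + 1e-9
  structure(list(freqs = freqs[keep], power = pw[keep],
                 provenance = c(prov, list(n = n, sampling_rate = sampling_rate,
                                           f_min = f_min, f_max = f_max))),
            class = "bw_spectrum")
}

#' @export
print.bw_spectrum <- function(x, ...) {
  cat("<power spectrum> ", length(x$freqs), " bins, ",
      min(x$freqs), "-", max(x$freqs), " Hz, resolution ",
      signif(diff(x$freqs[1:2]), 3), " Hz\n", sep = "")
  invisible(x)
}

#' Condition-averaged power spectrum
#'
#' Bin-wise arithmetic mean of the periodograms of the last
#' `n_condition_segments_averaged` whole segments assigned to a condition.
#'
#' @param recording A `bw_recording`.
#' @param condition Condition label to average.
#' @param schedule A [segment_schedule()].
#' @param f_min,f_max Frequency range passed to [periodogram_hamming()].
#' @param segments Optional precomputed result of [extract_segments()]
#'   (avoids re-slicing long recordings).
#' @return A `bw_spectrum` with segment provenance.
#' @export
condition_spectrum <- function(recording, condition,
                               schedule = segment_schedule(),
                               f_min = 1, f_max = 50, segments = NULL) {
  if (is.null(segments)) segments <- extract_segments(recording, schedule)
  conds <- vapply(segments, function(s) s$condition %||% NA_character_,
                  character(1))
  idx <- which(!is.na(conds) & conds == condition)
  nn <- schedule$n_condition_segments_averaged
  if (length(idx) < nn)
    stop("spectrum error: condition '", condition, "' has ", length(idx),
         " whole segment(s); ", nn, " required")
  idx <- utils::tail(idx, nn)
  specs <- lapply(segments[idx], periodogram_hamming,
                  sampling_rate = recording$sampling_rate,
                  f_min = f_min, f_max = f_max)
  pw <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
  structure(list(freqs = specs[[1L]]$freqs, power = pw,
                 provenance = list(
                   condition = condition,
                   segment_start_s = vapply(segments[idx], `[[`, numeric(1),
                                            "start_s"),
                   n_segments = length(idx))),
            class = "bw_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a frequency band
#'
#' @param name Band name.
#' @param lo,hi Band edges in Hz (`lo < hi`).
#' @return A `bw_band` list.
#' @export
band <- function(name, lo, hi) {
  if (!(lo < hi)) stop("band error: need lo < hi (got ", lo, ", ", hi, ")")
  structure(list(name = name, lo = lo, hi = hi), class = "bw_band")
}

#' The canonical OB analysis bands
#'
#' Theta 2-12 Hz, beta 13-35 Hz, gamma 35-50 Hz, and the full 1-50 Hz
#' range. The band definitions leave a 12-13 Hz gap and share the 35 Hz
#' edge; with trapezoidal integration on a common frequency grid the
#' shared edge contributes half its bin to each neighbor, so contiguous
#' band powers add exactly.
#'
#' @return Named list of [band()] objects.
#' @export
default_bands <- function() {
  list(theta = band("theta", 2, 12),
       beta = band("beta", 13, 35),
       gamma = band("gamma", 35, 50),
       full = band("full", 1, 50))
}

#' Integrate a power spectrum over a band
#'
#' Trapezoidal integral of the PSD over the band, in uV^2.
#'
#' @param spectrum A `bw_spectrum`.
#' @param band A [band()].
#' @return Integrated band power (uV^2), nonnegative.
#' @export
band_power <- function(spectrum, band) {
  f <- spectrum$freqs
  if (band$lo < min(f) - 1e-9 || band$hi > max(f) + 1e-9)
    stop("band error: band '", band$name, "' [", band$lo, ", ", band$hi,
         "] Hz lies outside the spectrum range [", min(f), ", ", max(f), "] Hz")
  keep <- f >= band$lo - 1e-9 & f <= band$hi + 1e-9
  if (sum(keep) < 2L)
    stop("band error: band '", band$name, "' covers fewer than 2 frequency bins")
  pracma::trapz(f[keep], spectrum$power[keep])
}

#' Normalize a band power to its control value
#'
#' The control band power is arbitrarily set to 100%; a test power is
#' reported as `100 * test / control`.
#'
#' @param test_power Band power of the test condition (uV^2).
#' @param control_power Band power of the control condition (uV^2), > 0.
#' @return Normalized power in percent of control.
#' @export
normalize_power <- function(test_power, control_power) {
  if (any(!is.finite(control_power)) || any(control_power <= 0))
    stop("normalization error: control_power must be positive")
  100 * test_power / control_power
}

#' Peak frequency of a spectrum
#'
#' Frequency of the bin with maximal power; ties are broken toward the
#' lowest frequency. An all-zero spectrum has no defined peak and returns
#' `NA`.
#'
#' @param spectrum A `bw_spectrum`.
#' @return Peak frequency in Hz, or `NA_real_` for an all-zero spectrum.
#' @export
peak_frequency <- function(spectrum) {
  if (length(spectrum$power) == 0L)
    stop("spectrum error: empty spectrum")
  if (all(spectrum$power == 0)) return(NA_real_)
  spectrum$freqs[which.max(spectrum$power)]
}
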