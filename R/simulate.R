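#' Parameters of the synthetic LFP generator
#'
#' The generative model for the spontaneous olfactory bulb (OB) field
#' potential is a stationary Gaussian process whose one-sided power
#' spectral density is a 1/f^alpha background (flattening below
#' `background_floor_hz`) plus a Lorentzian resonance centered at
#' `peak_freq`, shaped by first-order highpass/lowpass responses that
#' emulate the recording amplifier's analog filters. This reproduces the
#' broadband 1-50 Hz activity with a single spectral peak near 12-16 Hz
#' seen in OB slices; it makes no claim about the biophysics behind it.
#'
#' @param sampling_rate Sampling rate in Hz (default 3000, the low end of
#'   the usual 3-9 kHz digitization range, kept for desk-scale runtimes).
#' @param peak_freq Resonance center in Hz (default 13.3, the typical
#'   control peak frequency of OB slice activity).
#' @param resonance_bandwidth Full width at half maximum of the resonance
#'   in Hz (default 3).
#' @param resonance_fraction Fraction of total signal variance carried by
#'   the resonance (default 0.6; the remainder is broadband background).
#' @param one_over_f_exponent Spectral slope alpha of the background
#'   (default 1, classical pink background).
#' @param background_floor_hz Frequency below which the background
#'   flattens instead of diverging (default 2 Hz).
#' @param base_amplitude Root-mean-square amplitude of the unattenuated
#'   signal in microvolts (default 30).
#' @param highpass_cutoff Analog highpass corner in Hz (default 0.5).
#' @param lowpass_cutoff Analog lowpass corner in Hz (default 1500).
#' @param seed Integer seed for reproducible traces, or `NULL`.
#'
#' @return A `bw_sim_params` list.
#' @export
simulation_params <- function(sampling_rate = 3000,
                              peak_freq = 13.3,
                              resonance_bandwidth = 3,
                              resonance_fraction = 0.6,
                              one_over_f_exponent = 1,
                              background_floor_hz = 2,
                              base_amplitude = 30,
                              highpass_cutoff = 0.5,
                              lowpass_cutoff = 1500,
                              seed = NULL) {
  if (sampling_rate < 2 * lowpass_cutoff)
    stop("simulation error: sampling_rate must be at least twice lowpass_cutoff")
  if (peak_freq <= 1 || peak_freq >= 50)
    stop("simulation error: peak_freq must lie strictly between 1 and 50 Hz")
  if (base_amplitude <= 0)
    stop("simulation error: base_amplitude must be positive")
  if (resonance_fraction < 0 || resonance_fraction > 1)
    stop("simulation error: resonance_fraction must lie in [0, 1]")
  if (resonance_bandwidth <= 0)
    stop("simulation error: resonance_bandwidth must be positive")
  structure(
    list(sampling_rate = sampling_rate, peak_freq = peak_freq,
         resonance_bandwidth = resonance_bandwidth,
         resonance_fraction = resonance_fraction,
         one_over_f_exponent = one_over_f_exponent,
         background_floor_hz = background_floor_hz,
         base_amplitude = base_amplitude,
         highpass_cutoff = highpass_cutoff,
         lowpass_cutoff = lowpass_cutoff,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "bw_sim_params"
  )
}

# Unnormalized one-sided PSD shape at frequencies f >= 0, including the
# amplifier filter responses (first-order analog magnitudes).
psd_shape <- function(params, f) {
  bg <- pmax(f, params$background_floor_hz)^(-params$one_over_f_exponent)
  hw <- params$resonance_bandwidth / 2
  res <- 1 / (1 + ((f - params$peak_freq) / hw)^2) +
         1 / (1 + ((f + params$peak_freq) / hw)^2)  # mirrored lobe keeps symmetry
  # normalize the two components to unit integral on a fixed fine grid so
  # resonance_fraction is an exact variance fraction
  ny <- params$sampling_rate / 2
  grid <- seq(0, ny, by = min(0.05, params$resonance_bandwidth / 20))
  bg_g <- pmax(grid, params$background_floor_hz)^(-params$one_over_f_exponent)
  res_g <- 1 / (1 + ((grid - params$peak_freq) / hw)^2) +
           1 / (1 + ((grid + params$peak_freq) / hw)^2)
  filt <- function(x) {
    h <- (x / params$highpass_cutoff)^2 / (1 + (x / params$highpass_cutoff)^2)
    l <- 1 / (1 + (x / params$lowpass_cutoff)^2)
    h * l
  }
  i_bg <- pracma::trapz(grid, bg_g * filt(grid))
  i_res <- pracma::trapz(grid, res_g * filt(grid))
  shape <- (1 - params$resonance_fraction) * bg / i_bg +
    params$resonance_fraction * res / i_res
  shape * filt(f)
}

#' Theoretical one-sided power spectral density of the generator
#'
#' The exact generative PSD that [simulate_recording()] realizes (before
#' any gain attenuation), in microvolts squared per Hz. Useful as an oracle
#' for spectral-estimation tests: the integral over \[0, Nyquist\] equals
#' `base_amplitude^2` up to grid discretization.
#'
#' @param params A [simulation_params()] object.
#' @param freqs Frequencies (Hz) at which to evaluate the PSD.
#' @return Numeric vector of PSD values (uV^2/Hz).
#' @export
simulation_psd <- function(params, freqs) {
  stopifnot(inherits(params, "bw_sim_params"))
  params$base_amplitude^2 * psd_shape(params, freqs)
}

#' Simulate one olfactory bulb slice recording
#'
#' Draws a stationary Gaussian trace with the generative spectrum of
#' `params` by frequency-domain synthesis (white Gaussian noise shaped by
#' the square root of the target PSD on a fast FFT grid, then truncated to
#' the requested duration), and applies the time-varying power gain of
#' `envelope` by scaling instantaneous amplitude with the square root of
#' the gain. Identical parameters and seed yield a bit-identical trace.
#'
#' @param params A [simulation_params()] object.
#' @param envelope A `bw_envelope` gain envelope (its epochs define the
#'   recording's condition timeline).
#' @param duration_min Recording duration in minutes; must cover the
#'   envelope's timeline (default: exactly the timeline duration).
#' @param subject_meta Optional named list describing the preparation
#'   (e.g. species, age_weeks, slice_id).
#'
#' @return A `bw_recording`: list with `samples` (uV), `sampling_rate`,
#'   `timeline`, `subject_meta`, and `ground_truth` (the envelope).
#' @examples
#' tl <- condition_timeline(c("control", "abeta_30nM"), c(2, 2))
#' p <- simulation_params(sampling_rate = 200, lowpass_cutoff = 100, seed = 1)
#' rec <- simulate_recording(p, flat_gain_envelope(tl, 1))
#' @export
simulate_recording <- function(params, envelope, duration_min = NULL,
                               subject_meta = list()) {
  stopifnot(inherits(params, "bw_sim_params"))
  tl_end <- max(envelope$end_min)
  if (is.null(duration_min)) duration_min <- tl_end
  if (duration_min < tl_end)
    stop("simulation error: duration_min (", duration_min,
         ") is shorter than the envelope timeline (", tl_end, " min)")

  fs <- params$sampling_rate
  n <- round(duration_min * 60 * fs)
  if (!is.null(params$seed)) set.seed(params$seed)

  # synthesis length: next 5-smooth integer >= n for a fast FFT
  m <- stats::nextn(n, c(2, 3, 5))
  f_fold <- pmin(seq_len(m) - 1L, m - (seq_len(m) - 1L)) * (fs / m)
  # two-sided PSD; scale so the synthesized variance is base_amplitude^2
  s2 <- simulation_psd(params, f_fold) / 2
  g <- sqrt(s2 * fs)
  rm(s2, f_fold)
  w <- stats::rnorm(m)
  x <- stats::fft(w)
  rm(w)
  x <- x * g
  rm(g)
  x <- Re(stats::fft(x, inverse = TRUE)) / m
  x <- x[seq_len(n)]

  t_min <- (seq_len(n) - 1L) / fs / 60
  x <- x * sqrt(gain_at(envelope, t_min))

  timeline <- condition_timeline(
    envelope$condition, envelope$end_min - envelope$start_min,
    start_min = envelope$start_min[1L])

  structure(
    list(samples = x, sampling_rate = fs, timeline = timeline,
         subject_meta = subject_meta, ground_truth = envelope,
         params = params),
    class = "bw_recording"
  )
}

#' @export
print.bw_recording <- function(x, ...) {
  cat("<OB recording> ", length(x$samples), " samples @ ", x$sampling_rate,
      " Hz (", round(length(x$samples) / x$sampling_rate / 60, 2),
      " min), ", nrow(x$timeline), " epoch(s)\n", sep = "")
  invisible(x)
}

#' Derive reproducible per-entity seeds from one master seed
#'
#' Deterministic counter-based derivation (multiplicative congruential
#' step modulo the Mersenne prime 2^31 - 1) so that cohorts, behavioral
#' studies, and replicates each consume an independent, reproducible seed.
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of `n` seeds in \[1, 2^31 - 2\].
#' @export
derive_seeds <- function(master_seed, n) {
  m <- 2147483647
  s <- (abs(as.numeric(master_seed)) %% (m - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% m
    out[i] <- s
  }
  as.integer(out)
}

#' Simulate a cohort of slice recordings
#'
#' Generates `n_slices` independent recordings per design entry, with
#' per-slice seeds derived deterministically from `seed` and the ground
#' truth envelope attached to each recording. A lognormal between-slice
#' amplitude scatter emulates preparation-to-preparation differences in
#' absolute power (it cancels in normalized, within-slice quantities).
#'
#' @param design A list of design entries, each a list with elements
#'   `n_slices`, `params` ([simulation_params()]), `timeline`
#'   ([condition_timeline()]), `model` ([attenuation_model()]), and
#'   optionally `age_weeks` and `label`. A single entry may be passed
#'   directly.
#' @param seed Master integer seed.
#' @param amplitude_scatter Standard deviation (log scale) of the
#'   between-slice amplitude factor (default 0.2; 0 disables scatter).
#'
#' @return List of `bw_recording` objects.
#' @export
simulate_cohort <- function(design, seed, amplitude_scatter = 0.2) {
  if (!is.null(design$params)) design <- list(design)
  if (length(design) == 0L)
    stop("cohort error: empty design")
  n_total <- sum(vapply(design, function(d) as.integer(d$n_slices), integer(1)))
  if (any(vapply(design, function(d) d$n_slices < 1, logical(1))))
    stop("cohort error: each design entry needs n_slices >= 1")
  seeds <- derive_seeds(seed, 2L * n_total)

  out <- list()
  k <- 0L
  for (d in design) {
    age <- if (is.null(d$age_weeks)) NA_real_ else d$age_weeks
    env <- build_gain_envelope(d$timeline, d$model, age_weeks = age)
    for (j in seq_len(d$n_slices)) {
      k <- k + 1L
      p <- d$params
      p$seed <- seeds[k]
      if (amplitude_scatter > 0) {
        set.seed(seeds[n_total + k])
        p$base_amplitude <- p$base_amplitude *
          stats::rlnorm(1, 0, amplitude_scatter)
      }
      meta <- list(species = "mouse", age_weeks = age,
                   slice_id = sprintf("%s_slice%02d",
                                      if (is.null(d$label)) "cohort" else d$label, j),
                   seed = seeds[k])
      out[[k]] <- simulate_recording(p, env, subject_meta = meta)
    }
  }
  out
}

#' Ready-made simulation presets for the emulated slice experiments
#'
#' Returns the design (parameters, timeline, attenuation model, cohort
#' size) for one of the emulated experiments:
#' * `"stability"`: 7 slices recorded 181 min under control conditions
#'   only (baseline = first 20 min); the long-recording null.
#' * `"inverse"`: 6 slices, 20 min control then 60 min of the reversed
#'   sequence peptide (plateau gain 1, a null by construction).
#' * `"age3"`, `"age6"`, `"age8"`: 7 slices, 20 min control then
#'   sequential 1-h applications of 3, 10, and 30 nM amyloid-beta with
#'   age-specific plateau gains.
#' * `"washout"`: 7 slices, 20 min control, 1 h of 30 nM amyloid-beta
#'   (plateau 0.401), then 1 h washout.
#' * `"lidocaine"`: 7 slices, 20 min control then 30 min lidocaine
#'   (plateau 0.02, near-total suppression).
#'
#' @param name Preset name.
#' @param sampling_rate Optional sampling-rate override in Hz (the
#'   companion `lowpass_cutoff` is reduced to the Nyquist frequency when
#'   needed), useful for desk-scale runs.
#' @return A design list usable with [simulate_cohort()].
#' @export
sim_preset <- function(name = c("stability", "inverse", "age3", "age6",
                                "age8", "washout", "lidocaine"),
                       sampling_rate = NULL) {
  name <- match.arg(name)
  mk_params <- function(peak) {
    if (is.null(sampling_rate)) return(simulation_params(peak_freq = peak))
    simulation_params(sampling_rate = sampling_rate, peak_freq = peak,
                      lowpass_cutoff = min(1500, sampling_rate / 2))
  }
  # age-specific plateau gains for sequential amyloid-beta applications
  plateaus <- data.frame(
    condition = rep(c("abeta_3nM", "abeta_10nM", "abeta_30nM"), times = 3),
    age_weeks = rep(c(3, 6, 8), each = 3),
    gain = c(0.967, 0.804, 0.532,
             0.932, 0.542, 0.441,
             0.652, 0.546, 0.468)
  )
  switch(name,
    stability = list(
      label = "stability", n_slices = 7, age_weeks = 8,
      params = mk_params(13.3),
      timeline = condition_timeline("control", 181),
      model = attenuation_model(c(control = 1)),
      baseline_end_min = 20),
    inverse = list(
      label = "inverse", n_slices = 6, age_weeks = 8,
      params = mk_params(13.3),
      timeline = condition_timeline(c("control", "inverse_abeta"), c(20, 60)),
      model = attenuation_model(c(control = 1, inverse_abeta = 1))),
    age3 = list(
      label = "age3", n_slices = 7, age_weeks = 3,
      params = mk_params(12.4),
      timeline = condition_timeline(
        c("control", "abeta_3nM", "abeta_10nM", "abeta_30nM"),
        c(20, 60, 60, 60)),
      model = attenuation_model(plateaus)),
    age6 = list(
      label = "age6", n_slices = 7, age_weeks = 6,
      params = mk_params(13.3),
      timeline = condition_timeline(
        c("control", "abeta_3nM", "abeta_10nM", "abeta_30nM"),
        c(20, 60, 60, 60)),
      model = attenuation_model(plateaus)),
    age8 = list(
      label = "age8", n_slices = 7, age_weeks = 8,
      params = mk_params(16.4),
      timeline = condition_timeline(
        c("control", "abeta_3nM", "abeta_10nM", "abeta_30nM"),
        c(20, 60, 60, 60)),
      model = attenuation_model(plateaus)),
    washout = list(
      label = "washout", n_slices = 7, age_weeks = 8,
      params = mk_params(13.3),
      timeline = condition_timeline(c("control", "abeta_30nM", "washout"),
                                    c(20, 60, 60)),
      model = attenuation_model(c(control = 1, abeta_30nM = 0.401, washout = 1))),
    lidocaine = list(
      label = "lidocaine", n_slices = 7, age_weeks = 8,
      params = mk_params(13.3),
      timeline = condition_timeline(c("control", "lidocaine"), c(20, 30)),
      model = attenuation_model(c(control = 1, lidocaine = 0.02)))
  )
}
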