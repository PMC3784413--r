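# Spectral core: segment scheduling, Hamming periodogram calibration
# (Parseval), band integration, normalization, and peak frequency.

test_that("segments follow the 20 s / 5 min schedule and respect epoch boundaries", {
  # 60-min single-condition recording -> 12 segments at minutes 0,5,...,55
  tl <- condition_timeline("control", 60)
  rec <- simulate_recording(fast_params(seed = 1, fs = 100),
                            flat_gain_envelope(tl, 1))
  segs <- extract_segments(rec, segment_schedule())
  expect_length(segs, 12)
  expect_equal(vapply(segs, `[[`, numeric(1), "start_min"), seq(0, 55, by = 5))
  expect_true(all(vapply(segs, function(s) length(s$samples), integer(1)) ==
                    20 * 100))

  # exactly one segment from a 20-s recording
  tl1 <- condition_timeline("control", 20 / 60)
  rec1 <- simulate_recording(fast_params(seed = 2, fs = 100),
                             flat_gain_envelope(tl1, 1))
  expect_length(extract_segments(rec1, segment_schedule()), 1)
  expect_error(extract_segments(
    simulate_recording(fast_params(seed = 3, fs = 100),
                       flat_gain_envelope(condition_timeline("control", 10 / 60), 1)),
    segment_schedule()), "shorter than one segment")
})

test_that("segments are assigned to conditions only when wholly inside an epoch", {
  # epoch boundary at 17 min: the 15-min segment belongs to the first
  # epoch and no segment straddles the boundary (enumeration oracle)
  tl <- condition_timeline(c("control", "abeta_30nM"), c(17, 23))
  rec <- simulate_recording(fast_params(seed = 4, fs = 100),
                            flat_gain_envelope(tl, 1))
  segs <- extract_segments(rec, segment_schedule())
  got <- data.frame(start = vapply(segs, `[[`, numeric(1), "start_min"),
                    cond = vapply(segs, `[[`, character(1), "condition"))
  # oracle: enumerate segment intervals against epochs
  expected <- sapply(got$start, function(s) {
    if (s + 20 / 60 <= 17) "control" else if (s >= 17) "abeta_30nM" else NA
  })
  expect_equal(got$cond, as.vector(expected))
  expect_equal(got$cond[got$start == 15], "control")
})

test_that("Hamming periodogram is Parseval-calibrated and resolves 0.05 Hz", {
  set.seed(99)
  fs <- 3000
  for (i in 1:3) {
    x <- rnorm(20 * fs)
    sp <- periodogram_hamming(x, fs, f_min = 0, f_max = fs / 2)
    expect_equal(band_power(sp, band("all", 0, fs / 2)), stats::var(x),
                 tolerance = 0.01)
  }
  sp <- periodogram_hamming(rnorm(20 * 1000), 1000)
  expect_equal(diff(sp$freqs[1:2]), 0.05)
  expect_true(all(sp$freqs >= 1 & sp$freqs <= 50))
  expect_true(all(sp$power >= 0))
})

test_that("pure sinusoid concentrates its variance at its frequency", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  sp <- periodogram_hamming(sin(2 * pi * 10 * t), fs)
  expect_equal(peak_frequency(sp), 10)
  expect_equal(band_power(sp, band("full", 1, 50)), 0.5, tolerance = 0.01)
  # almost all mass within +/- 0.5 Hz of the tone
  expect_gt(band_power(sp, band("peak", 9.5, 10.5)) /
              band_power(sp, band("full", 1, 50)), 0.99)
})

test_that("constant segments give an all-zero spectrum and an undefined peak", {
  sp <- periodogram_hamming(rep(3.7, 2000), 100)
  expect_true(all(sp$power == 0))
  expect_true(is.na(peak_frequency(sp)))
})

test_that("scaling a segment by k scales every power value by k^2 exactly", {
  set.seed(5)
  x <- rnorm(2000)
  a <- periodogram_hamming(x, 100)
  b <- periodogram_hamming(3 * x, 100)
  expect_equal(b$power, 9 * a$power, tolerance = 1e-9)
})

test_that("band powers add across contiguous bands and reject out-of-range bands", {
  set.seed(6)
  sp <- periodogram_hamming(rnorm(20 * 500), 500)
  pieces <- band_power(sp, band("theta", 2, 12)) +
    band_power(sp, band("gap", 12, 13)) +
    band_power(sp, band("beta", 13, 35)) +
    band_power(sp, band("gamma", 35, 50))
  expect_equal(pieces, band_power(sp, band("span", 2, 50)), tolerance = 1e-9)
  # trapezoid against an independent implementation
  expect_equal(band_power(sp, band("theta", 2, 12)),
               trap_ref(sp$freqs[sp$freqs >= 2 - 1e-9 & sp$freqs <= 12 + 1e-9],
                        sp$power[sp$freqs >= 2 - 1e-9 & sp$freqs <= 12 + 1e-9]),
               tolerance = 1e-12)
  expect_error(band_power(sp, band("high", 40, 80)), "outside the spectrum")
  expect_error(band("bad", 12, 2), "lo < hi")
})

test_that("flat spectra integrate to bandwidth times level", {
  sp <- structure(list(freqs = seq(1, 50, by = 0.05),
                       power = rep(2, length(seq(1, 50, by = 0.05))),
                       provenance = list()), class = "bw_spectrum")
  expect_equal(band_power(sp, band("theta", 2, 12)), 20)
  expect_equal(peak_frequency(sp), 1)  # ties break to the lowest frequency
})

test_that("normalization sets control to 100% and validates its input", {
  expect_equal(normalize_power(50, 100), 50)
  expect_equal(normalize_power(123.4, 123.4), 100)
  expect_equal(normalize_power(0, 10), 0)
  expect_error(normalize_power(10, 0), "positive")
  expect_error(normalize_power(10, -2), "positive")
})

test_that("condition spectra average the last n segments bin-wise", {
  rec <- step_gain_recording(0.25, seed = 31, drug_min = 25)
  segs <- extract_segments(rec, segment_schedule())
  conds <- vapply(segs, `[[`, character(1), "condition")
  drug_idx <- which(conds == "abeta_30nM")
  expect_gte(length(drug_idx), 4)
  # provenance bookkeeping: only the last two drug segments contribute
  cs <- condition_spectrum(rec, "abeta_30nM")
  last2 <- utils::tail(drug_idx, 2)
  expect_equal(cs$provenance$segment_start_s,
               vapply(segs[last2], `[[`, numeric(1), "start_s"))
  manual <- lapply(segs[last2], periodogram_hamming,
                   sampling_rate = rec$sampling_rate)
  expect_equal(cs$power, (manual[[1]]$power + manual[[2]]$power) / 2,
               tolerance = 1e-12)
  # averaging identical spectra is idempotent; means are bin-wise
  sp1 <- manual[[1]]
  expect_equal((sp1$power + sp1$power) / 2, sp1$power)
  expect_error(condition_spectrum(rec, "washout"), "washout")
})

test_that("f_max beyond Nyquist is rejected", {
  expect_error(periodogram_hamming(rnorm(100), 80, f_max = 50), "Nyquist")
})
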