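# The synthetic LFP generator: reproducibility, generative-spectrum
# fidelity, gain scaling, and cohort bookkeeping.

test_that("identical seeds give bit-identical traces, different seeds differ", {
  tl <- condition_timeline("control", 2)
  env <- flat_gain_envelope(tl, 1)
  a <- simulate_recording(fast_params(seed = 7), env)
  b <- simulate_recording(fast_params(seed = 7), env)
  c <- simulate_recording(fast_params(seed = 8), env)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("zero gain yields an identically zero trace; duration must cover the timeline", {
  tl <- condition_timeline("control", 2)
  env <- flat_gain_envelope(tl, 0)
  rec <- simulate_recording(fast_params(seed = 1), env)
  expect_true(all(rec$samples == 0))
  expect_error(simulate_recording(fast_params(seed = 1),
                                  flat_gain_envelope(tl, 1), duration_min = 1),
               "shorter than")
})

test_that("realized variance and spectrum match the generative model", {
  # variance ~ base_amplitude^2, and the 1-50 Hz periodogram peak sits at
  # the resonance frequency (Monte-Carlo over 5 seeds)
  tl <- condition_timeline("control", 21)
  env <- flat_gain_envelope(tl, 1)
  peaks <- numeric(5)
  vars <- numeric(5)
  for (i in 1:5) {
    rec <- simulate_recording(fast_params(seed = 100 + i), env)
    vars[i] <- stats::var(rec$samples)
    cs <- condition_spectrum(rec, "control")
    peaks[i] <- peak_frequency(cs)
  }
  expect_equal(mean(vars), 30^2, tolerance = 0.1)
  expect_lt(abs(mean(peaks) - 13.3), 2)
})

test_that("envelope power gain scales band power proportionally", {
  # late/early integrated 1-50 Hz power ratio ~ step gain (variance oracle)
  ratios <- sapply(1:6, function(i) {
    rec <- step_gain_recording(0.25, seed = 200 + i)
    segs <- extract_segments(rec, segment_schedule())
    pw <- vapply(segs, function(s)
      band_power(periodogram_hamming(s, rec$sampling_rate), band("full", 1, 50)),
      numeric(1))
    conds <- vapply(segs, `[[`, character(1), "condition")
    mean(pw[conds == "abeta_30nM"]) / mean(pw[conds == "control"])
  })
  expect_equal(mean(ratios), 0.25, tolerance = 0.1)
})

test_that("frequency-uniform gain preserves the theoretical spectrum shape", {
  p <- fast_params()
  f <- seq(1, 50, by = 0.05)
  s <- simulation_psd(p, f)
  # single interior maximum at the resonance center
  expect_equal(f[which.max(s)], 13.3, tolerance = 0.1)
  # broadband: power everywhere in 1-50 Hz, spanning < 3 orders of magnitude
  expect_true(all(s > 0))
  expect_lt(max(s) / min(s), 1000)
})

test_that("simulate_cohort derives distinct per-slice seeds and reproduces bit-identically", {
  d <- list(n_slices = 4, params = fast_params(),
            timeline = two_epoch_timeline(),
            model = attenuation_model(c(control = 1, abeta_30nM = 0.5)),
            age_weeks = 8, label = "test")
  c1 <- simulate_cohort(d, seed = 11)
  c2 <- simulate_cohort(d, seed = 11)
  expect_length(c1, 4)
  seeds <- vapply(c1, function(r) r$subject_meta$seed, integer(1))
  expect_equal(length(unique(seeds)), 4)
  expect_true(all(seeds > 0 & seeds < 2^31))
  for (i in 1:4) expect_identical(c1[[i]]$samples, c2[[i]]$samples)
  # identical timelines across slices; ground truth attached
  for (r in c1) {
    expect_equal(r$timeline$condition, c("control", "abeta_30nM"))
    expect_s3_class(r$ground_truth, "bw_envelope")
  }
  expect_error(simulate_cohort(list(), seed = 1), "empty design")
})

test_that("derive_seeds is deterministic and in the 32-bit range", {
  s1 <- derive_seeds(123, 50)
  s2 <- derive_seeds(123, 50)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 <= 2^31 - 2))
  expect_false(any(duplicated(s1)))
  expect_false(identical(derive_seeds(124, 50), s1))
})
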