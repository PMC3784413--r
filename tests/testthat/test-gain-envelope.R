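# Ground-truth gain envelopes: piecewise-exponential kinetics, continuity,
# and label/plateau validation.

test_that("an all-control timeline yields the identity envelope", {
  tl <- condition_timeline("control", 120)
  env <- build_gain_envelope(tl, attenuation_model(c(control = 1)))
  expect_equal(gain_at(env, c(0, 1, 60, 119.9, 120)), rep(1, 5))
})

test_that("drug-epoch gain follows the closed-form exponential approach", {
  tl <- condition_timeline(c("control", "abeta_30nM"), c(20, 60))
  env <- build_gain_envelope(
    tl, attenuation_model(c(control = 1, abeta_30nM = 0.40),
                          onset_halftime_min = 10))
  # one halftime into the epoch: halfway between entry (1) and plateau
  expect_equal(gain_at(env, 30), 1 - 0.5 * (1 - 0.40))
  # closed form vs numeric integration of dg/dt = -(ln 2 / h) (g - plateau)
  h <- 10; plateau <- 0.40
  dt <- 1e-4
  tt <- seq(0, 40, by = dt)
  g_num <- 1
  for (i in seq_len(length(tt) - 1))
    g_num <- g_num - dt * log(2) / h * (g_num - plateau)
  expect_equal(gain_at(env, 60), g_num, tolerance = 1e-6)
})

test_that("envelope is continuous at epoch boundaries and washout relaxes to 1", {
  tl <- condition_timeline(c("control", "abeta_30nM", "washout"), c(20, 60, 120))
  env <- build_gain_envelope(
    tl, attenuation_model(c(control = 1, abeta_30nM = 0.40, washout = 1),
                          onset_halftime_min = 10, washout_halftime_min = 15))
  eps <- 1e-9
  for (b in c(20, 80)) {
    expect_equal(gain_at(env, b - eps), gain_at(env, b + eps), tolerance = 1e-6)
  }
  # long washout recovers toward 1 monotonically
  g <- gain_at(env, seq(80, 200, by = 5))
  expect_true(all(diff(g) > 0))
  expect_equal(gain_at(env, 200), 1, tolerance = 1e-2)
})

test_that("lidocaine-style plateau drives the gain toward zero monotonically", {
  tl <- condition_timeline(c("control", "lidocaine"), c(10, 300))
  env <- build_gain_envelope(
    tl, attenuation_model(c(control = 1, lidocaine = 0), onset_halftime_min = 5))
  g <- gain_at(env, seq(10, 310, by = 10))
  expect_true(all(diff(g) <= 0))
  expect_lt(gain_at(env, 310), 1e-10)
})

test_that("within a drug epoch the gain is non-increasing toward its plateau", {
  tl <- condition_timeline(c("control", "abeta_10nM"), c(20, 90))
  env <- build_gain_envelope(
    tl, attenuation_model(c(control = 1, abeta_10nM = 0.55)))
  g <- gain_at(env, seq(20, 110, by = 1))
  expect_true(all(diff(g) <= 0))
  expect_true(all(g >= 0.55))
})

test_that("invalid labels, plateaus, and halftimes are rejected", {
  tl <- condition_timeline(c("control", "abeta_30nM"), c(20, 60))
  expect_error(build_gain_envelope(tl, attenuation_model(c(control = 1))),
               "no plateau gain")
  expect_error(attenuation_model(c(control = 1, bogus = 0.5)),
               "unknown condition")
  expect_error(attenuation_model(c(control = 1), onset_halftime_min = -1),
               "nonnegative")
  expect_error(attenuation_model(c(inverse_abeta = 0.9)), "exactly 1")
  expect_error(attenuation_model(c(lidocaine = 0.5)), "<= 0.05")
  expect_error(attenuation_model(c(abeta_30nM = 1.5)), "\\[0, 1.2\\]")
  expect_error(condition_timeline(c("abeta_30nM", "control"), c(10, 10)),
               "first epoch")
})

test_that("age-dependent plateau tables resolve by condition and age", {
  tab <- data.frame(condition = rep("abeta_30nM", 2), age_weeks = c(3, 8),
                    gain = c(0.53, 0.47))
  m <- attenuation_model(tab, onset_halftime_min = 0)
  tl <- condition_timeline(c("control", "abeta_30nM"), c(20, 60))
  e3 <- build_gain_envelope(tl, m, age_weeks = 3)
  e8 <- build_gain_envelope(tl, m, age_weeks = 8)
  expect_equal(gain_at(e3, 50), 0.53)
  expect_equal(gain_at(e8, 50), 0.47)
  expect_error(build_gain_envelope(tl, m, age_weeks = 6), "no plateau gain")
})
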