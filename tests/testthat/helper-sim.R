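# Shared fixtures: small, fast simulation setups used across tests.
# Desk-scale rates (<= 1 kHz) keep unit tests quick; the generative model
# is identical at every rate.

fast_params <- function(seed = NULL, fs = 500, peak = 13.3) {
  simulation_params(sampling_rate = fs, peak_freq = peak,
                    lowpass_cutoff = fs / 2, seed = seed)
}

# control + one drug epoch, short but long enough for two whole segments
# per condition under the default 20 s / 5 min schedule
two_epoch_timeline <- function(control_min = 20, drug_min = 15,
                               drug = "abeta_30nM") {
  condition_timeline(c("control", drug), c(control_min, drug_min))
}

# step-gain recording: control at gain 1, drug epoch at constant gain g
step_gain_recording <- function(gain, seed, fs = 500, control_min = 20,
                                drug_min = 15) {
  tl <- two_epoch_timeline(control_min, drug_min)
  model <- attenuation_model(c(control = 1, abeta_30nM = gain),
                             onset_halftime_min = 0)
  env <- build_gain_envelope(tl, model)
  simulate_recording(fast_params(seed = seed, fs = fs), env)
}

# independent trapezoid for oracle checks
trap_ref <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
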