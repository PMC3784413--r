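---
title: "Methods: models, estimators, and design choices in bulbwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and design choices in bulbwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bulbwave` quantifies the suppression of spontaneous olfactory bulb (OB)
network activity by bath-applied amyloid-beta oligomers in slice
recordings, and the associated loss of olfactory ability after
intrabulbar injection. Raw recordings of this kind are rarely public, so
the package pairs the analysis chain with a generative model of the data
it consumes; this vignette describes both, the parameters that matter,
and the choices made where the underlying experimental description
leaves the design open.

## 1. The generative LFP model

The spontaneous granule-cell-layer field potential is modeled as a
stationary Gaussian process with one-sided power spectral density

S(f) = A^2 [ (1 - q) B(f) / I_B + q R(f) / I_R ] H_hp(f) H_lp(f),

where

* B(f) = max(f, f_floor)^(-alpha) is a 1/f^alpha background that
  flattens below `background_floor_hz` (default 2 Hz) instead of
  diverging;
* R(f) is a Lorentzian resonance of full width `resonance_bandwidth`
  (default 3 Hz) centered at `peak_freq` (default 13.3 Hz, the typical
  control peak of OB slice activity);
* q = `resonance_fraction` (default 0.6) is the fraction of total
  variance carried by the resonance; I_B and I_R normalize both shapes
  to unit integral;
* H_hp and H_lp are first-order analog-style magnitude responses at
  0.5 Hz and 1.5 kHz, emulating the recording amplifier's filters;
* A = `base_amplitude` (default 30 uV RMS, a typical low-voltage slice
  LFP scale) fixes the total variance.

The slice data being emulated show only that the activity is broadband
over 1-50 Hz with a single peak in the low-beta range; the particular
spectral family is a package choice, exposed through
`simulation_params()` and documented by `simulation_psd()`, which
returns the exact generative PSD and serves as the oracle in the test
suite. Defaults were fixed once so that the simulated spectra reproduce
the qualitative features of the emulated recordings: a clear
interior peak near 13 Hz (the resonance peak stands roughly 4-5x above
the low-frequency background, so the noisy periodogram argmax lands near
it), smooth broadband power across all three analysis bands, and no
structure the analysis could exploit beyond that.

Traces are synthesized in the frequency domain: white Gaussian noise is
shaped by sqrt(S) on a 5-smooth FFT grid at least as long as the
recording, transformed back, and truncated. This is exact (the realized
process has PSD S), fast at the tens of millions of samples a 3-h
recording at 3 kHz requires, and reproducible: the trace is a
deterministic function of the parameters and seed. The default sampling
rate is 3 kHz, the low end of the 3-9 kHz digitization range used for
such recordings; since the analysis band ends at 50 Hz, desk-scale runs
(tests, examples) use 200-1000 Hz, which leaves every analysis quantity
unchanged.

### Attenuation as ground truth

All effect sizes in this literature are power ratios, so drug action is
modeled as a multiplicative gain g(t) on expected power; sample
amplitudes are scaled by sqrt(g(t)). `attenuation_model()` assigns each
condition a plateau gain (optionally per age) and two kinetic constants;
`build_gain_envelope()` turns a condition timeline into a
piecewise-exponential envelope: g = 1 in control, exponential approach
from the epoch-entry value to the plateau with halftime
`onset_halftime_min` in drug epochs, relaxation to 1 with
`washout_halftime_min` during washout, continuous at boundaries.

The exponential family is a modeling convenience; what is anchored to
the emulated experiments are the plateau values (e.g. the age x
concentration table of the sequential-application presets: 0.967/0.804/
0.532 at 3 weeks, 0.932/0.542/0.441 at 6 weeks, 0.652/0.546/0.468 at 8
weeks, and 0.401 for the single 30 nM application) and the onset
time-course anchors: the 30 nM effect is visible by 15 min (~76% of
control) and pronounced by 25 min (~59%). A single exponential cannot
pass through both anchors exactly for a 0.40 plateau; the default
halftime of 17 min minimizes the squared error (giving 72.5% and 61.7%)
and was fixed a priori from those anchors. A consequence worth knowing:
after a 1-h epoch the gain still sits ~0.05 above its plateau
(0.452 for a 0.40 plateau), which is why ground-truth recovery tests in
this package use step envelopes (`onset_halftime_min = 0`) when the
quantity of interest is the plateau itself.

Between-slice variability of absolute power is not constrained by the
emulated reports (only normalized quantities are printed);
`simulate_cohort()` applies a lognormal amplitude scatter (sd 0.2 on the
log scale) chosen once as a realistic preparation-to-preparation spread.
It cancels exactly in all normalized quantities; cohort SEMs of
normalized power instead arise from segment-level spectral estimation
noise (roughly 8-10% per segment for the default spectrum), which
reproduces the order of the SEMs such experiments report (~2-11% with
n = 6-7).

## 2. The spectral estimators

`extract_segments()` takes one segment of `segment_length_s = 20` s
every `period_min = 5` min, starting at t = 0; a segment belongs to a
condition only if it lies wholly inside that condition's epoch, so no
segment ever straddles a drug transition. `condition_spectrum()`
averages the periodograms of the last two whole segments of each
condition bin-wise.

Each segment gets a single full-length Hamming-tapered periodogram
(resolution 1/20 s = 0.05 Hz), not Welch sub-averaging: the emulated
workflow applies one window per analyzed segment, and the per-condition
averaging already provides the variance reduction the analysis needs.
The window correction divides by fs * sum(w^2), which makes the
estimator unit-true in uV^2/Hz: the integral of the PSD over all
frequencies equals the (window-weighted) segment variance. The test
suite checks this Parseval identity to 1%; the residual discrepancy is
the difference between weighted and unweighted sample variance, of
order sqrt(1.6/n) relative, i.e. ~0.5% for 20-s segments at 3 kHz. The
segment mean is removed before tapering, and the spectrum is restricted
to 1-50 Hz, which excludes DC and sub-1 Hz content.

Band powers integrate the PSD by the trapezoidal rule. At 0.05 Hz
resolution the difference between trapezoid and bin-sum is far below
the estimator's sampling error; trapezoid was chosen because it makes
contiguous bands add exactly: the canonical bands (theta 2-12, beta
13-35, gamma 35-50 Hz) leave a 12-13 Hz gap and share the 35 Hz edge,
and with trapezoidal integration on the common grid the shared edge
contributes half a bin to each neighbor, so theta + gap + beta + gamma
equals the 2-50 Hz integral to floating-point accuracy. Normalization
sets the same slice's control-condition band power to 100% exactly.
Peak frequency is the argmax bin over 1-50 Hz, with ties broken toward
the lowest frequency; an all-zero spectrum (e.g. a constant segment)
has no defined peak and returns `NA` rather than an arbitrary bin.

`power_time_course()` reports per-segment (not pairwise-averaged)
full-band power in percent of the baseline - the mean of the last two
whole segments of the reference condition before onset - so the 5-min
cadence of drug-onset time-courses is preserved. For single-epoch
recordings (the 3-h stability control), onset is passed explicitly
(`onset_min = 20`): the first 20 min serve as the control baseline and
reported times count minutes of continuous recording, so the 60/120/180
min marks are 40/100/160 min after baseline end.

## 3. The statistics battery

All four tests are implemented from the rank formulas rather than
delegated, because their small-sample behavior is integral to the
analyses (n = 6-10 throughout): base R's implementations are used in the
test suite as independent references, alongside brute-force enumeration
oracles.

* Kruskal-Wallis: tie-corrected H against chi-square with k - 1 df.
  All-identical data are reported as a labeled degenerate result (H = 0,
  p = 1) instead of an error, since simulated null tables can produce
  them.
* Dunn: pairwise z on mean pooled ranks with tie-corrected variance;
  two-sided normal p-values; family-wise Bonferroni over all pairs by
  default. Whether the emulated analyses adjusted their Dunn p-values is
  not stated, so both adjusted and raw p-values are always emitted and
  the adjustment is configurable.
* Friedman: within-block average ranks, chi-square with k - 1 df and the
  standard tie correction.
* Wilcoxon signed rank: zeros dropped, W+ reported; the p-value is exact
  for n <= 15 - computed by dynamic-programming convolution of the
  signed-rank generating function, which handles tied ranks - and a
  tie- and continuity-corrected normal approximation beyond. The n <= 15
  threshold keeps every paired comparison in the emulated designs exact.

Censored summaries (`summarize_censored()`) substitute the cap for
censored latencies in both the mean +/- SEM and the median/IQR. This
matches how truncated latencies must enter reported cell means (a
mean below the cap with several failures is only arithmetically possible
under cap substitution), and is stated explicitly because a
Kaplan-Meier estimate would be the natural alternative; survival
modeling is out of scope here. Quantiles use linear interpolation
between order statistics (R type 7); IQR values depend on this
convention, so it is fixed and documented. A median is flagged as a
lower bound when more than half the cell is censored.

## 4. The behavioral model and analysis

Hidden-food latencies are lognormal before right-censoring at the 600-s
cap. The emulated assay reports only means and medians, so the family is
a package choice (positive, right-skewed, heavy enough tails to put
realistic mass above the cap). Default locations were chosen once to
reproduce the reported cell structure: vehicle medians near 110 s every
week; treated animals unimpaired at week 1 (median ~130 s) and mostly
above the cap from week 2 (medians 620/650/900 s, giving cap-substituted
cell means near 470/480/520 s with roughly half the animals failing),
with sdlog 0.9. Visible-food latencies, food intake (30- and 120-min
windows), and weekly weight gain carry no group effect by construction.

Between-group weekly tests use the two-group Kruskal-Wallis test
(equivalent to a rank-sum test) because the per-week test is not named
in the emulated analysis; within-group comparisons of each later week
against week 1 use the paired Wilcoxon test, pairing animals by
identity. Feeding status is a stratification variable (visible-food
comparisons run separately for fed and deprived animals), and the random
corner placement of the food is simulated implicitly in the latency
noise but not modeled as a covariate, since no per-corner data exist to
calibrate one.

The interpretation guard encodes the assay's control logic as a
pipeline rule: `behavior_report()` labels a significant hidden-food
group effect an "olfactory deficit" only when every control comparison
(visible food in both feeding strata, both intake windows, every weekly
weight comparison) is non-significant. With eight control tests at
alpha = 0.05, a null study has a ~1/3 chance of tripping at least one
control by chance; the guard is deliberately conservative in that
direction - it withholds the olfactory interpretation rather than
inflating it.

## 5. Reproducibility and problem sizes

Every stochastic routine consumes an explicit seed; cohorts and
replicate studies derive per-entity seeds from one master seed by a
multiplicative-congruential counter (`derive_seeds()`), so runs are
bit-identical under a fixed configuration. `run_pipeline()` writes a
config echo, a log with versions and seed, and result tables stamped
with a hash of the scientific configuration (output location excluded);
re-running the same configuration reproduces every table byte for byte.

Test and validation problem sizes are the package's own choices,
balancing statistical resolution against desk-scale runtimes: the
stability and inverse-peptide null cohorts run at the full default
conditions (n = 7 and 6, 181 and 80 min, 3 kHz); ground-truth plateau
recovery uses 20 master seeds x 7 slices x 30-min recordings at 500 Hz
with step envelopes; type-I error calibration uses 2000 null replicates
per test; behavioral power and null rates use 200 replicates of the
full design. Statistical acceptance bands follow from these sizes (e.g.
cohort means of normalized power have SEM ~3-4 points at n = 7, so null
checks use +/- 10 points).

## 6. What the simulator does and does not establish

Passing tests demonstrate that the pipeline recovers known ground truth
from data with the stated statistical structure: stationary Gaussian
spectra with frequency-uniform power attenuation, lognormal censored
latencies, null controls. Real slice recordings additionally contain
nonstationarities (slow drift, bursting), non-Gaussian waveforms,
line noise and movement artifacts, and possible frequency-specific drug
effects; none of these are emulated, and no artifact rejection beyond
the 1-50 Hz restriction is implemented. Conclusions about such features
are outside what this validation can support. Likewise out of scope:
biophysical OB modeling, spike-level simulation, multichannel geometry,
multitaper/wavelet estimation, phase or coherence analysis, survival
regression for censored latencies, and acquisition-hardware file
formats (plain CSV/TSV/JSON are the only interchange formats).
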