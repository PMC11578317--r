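---
title: "Estimating blood glucose from PPG waveform morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood glucose from PPG waveform morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgglucose)
```

## The problem

A fingertip photoplethysmogram (PPG) records transmitted light intensity as
the blood volume in the finger pulses with each heartbeat. Because glucose
contributes to near-infrared absorption, the morphology of the pulse —
in particular the amplitudes of its landmarks relative to the beat's
starting trough — carries information about blood glucose. `ppgglucose`
implements the full analysis chain that turns a raw PPG waveform into a
glucose estimate in mmol/L:

1. **simulate** waveforms with a known, recoverable glucose signal
   (`simulate_beat()`, `simulate_recording()`, `simulate_cohort()`);
2. **condition and segment** the signal into beats anchored at the trough
   preceding the first double-peak pulse (`condition_signal()`,
   `segment_beats()`);
3. **locate fiducials and extract features**: systolic peak (SP), dicrotic
   notch (DN), diastolic peak (DP) and bottom (Bot), then eleven numeric
   features per beat, averaged per recording (`locate_fiducials()`,
   `extract_features()`, `aggregate_recording()`);
4. **regress** the feature means — together with subject covariates —
   onto reference glucose with a from-scratch gradient-boosted
   decision-tree model and classical baselines (`fit_gbdt()`,
   `fit_baseline()`);
5. **evaluate** with MARD, RMSE, MAE, R², the 1987 Clarke Error Grid,
   Monte Carlo cross-validation and an aleatoric/epistemic uncertainty
   decomposition (`compute_metrics()`, `clarke_report()`,
   `monte_carlo_cv()`, `estimate_uncertainty()`).

No public recordings accompany the underlying study, so the synthetic
generator is a first-class, tested component: it defines the conditions
under which every quantitative claim in this package is made.

## The beat model

One beat on $[0, T]$ is the sum of a systolic and a diastolic Gaussian
pulse minus a narrow Gaussian notch,

$$ s(t) = A_s e^{-(t - t_s)^2 / 2\sigma_s^2}
        + A_d e^{-(t - t_d)^2 / 2\sigma_d^2}
        - A_n e^{-(t - t_n)^2 / 2\sigma_n^2}, $$

the minimal smooth shape producing all four fiducials (Bot at the
inter-beat trough, SP near $t_s$, DN at the notch, DP on the diastolic
bump). Defaults place $t_s = 0.18\,T$, $t_d = 0.40\,T$, $t_n$ midway, with
widths $(0.05, 0.12, 0.03)\,T$; the narrow systolic width keeps the beat's
leading tail within ~0.1% of the inter-beat trough, so a beat extracted
from a recording and a standalone beat agree on their amplitude anchor.

The user configures *target amplitudes* — SP−Bot, DP−Bot and a notch depth
below DP — and the generator calibrates $(A_s, A_d, A_n)$ by an iterated
linear solve so the realized fiducial amplitudes match the targets
essentially exactly (the waveform is linear in the coefficients; the
fiducial locations are refit each iteration, and the systolic centre is
nudged so the realized maximum lands on `systolic_time`). This makes the
glucose link below literal rather than approximate, which is what lets the
recoverability and monotonicity tests assert tight (2%) tolerances.
Setting `notch_depth = 0` deliberately produces a single-humped beat with
a diastolic shoulder — the degenerate case that exercises the detector's
fallback path.

## The glucose link and noise model

`glucose_link()` maps glucose $g$ (mmol/L) affinely to the three amplitude
targets: at the reference glucose 5.4 mmol/L the targets are
(1.0, 0.55, 0.30) a.u. with slopes (0.08, 0.05, 0.03) a.u. per mmol/L.
Additive white Gaussian noise is applied to the waveform with

$$ \sigma(g) = \max(0.005,\; 0.05 - 0.006\,g), $$

a decreasing function of glucose clipped at a floor: low-glucose
recordings are noisier (at 4.4 mmol/L, $\sigma = 0.024$, about 2.5% of the
pulse amplitude; at 6.4 mmol/L, $\sigma = 0.012$). This reproduces, in the
simplest form, the qualitative behaviour of transmitted-light PPG, where a
low glucose level leaves the light less affected and the pulse features
less distinct. Beat rate is drawn uniformly in 60–100 bpm — inside the
1–3 Hz human heart-rate band — with 1% beat-to-beat period jitter.

Three named presets mirror the study's experiments: `nir_single`
(292 recordings, one subject, glucose 4.4–6.4 mmol/L, with an 88-record
training-scale variant `nir_single_88`), `solar_single` (237 recordings,
one subject) and `multi_patient` (626 recordings over 49 subjects,
4.0–15.0 mmol/L — the multi-patient range is this package's choice of a
realistic diabetic span, as no range is stated for that cohort; each
subject also receives a lognormal amplitude factor with sd 0.05 to emulate
inter-individual optical differences). Scenario label sampling always
inserts both range endpoints once, so cohort min/max are deterministic.

**What the generator does *not* emulate:** motion artifacts, baseline
wander from respiration or perfusion changes, sensor saturation,
heart-rate–glucose coupling, and any real optical tissue model. Passing
tests therefore demonstrate that the pipeline is *correct and internally
consistent* — that it recovers a glucose signal its inputs actually
contain — not that these accuracies transfer to real fingertip data.
Reported MARDs on the synthetic cohorts (≈0.5%) are accordingly better
than plausible clinical performance.

## Conditioning and segmentation

`condition_signal()` is a zero-phase spectral projection: FFT bins outside
the passband (including DC) are zeroed and the signal reconstructed.
A projection is exactly idempotent, which makes "conditioning twice equals
conditioning once" a testable identity rather than an approximation. The
default band is 0.5–20 Hz: the lower edge removes baseline drift below
physiological beat rates, and the upper edge was chosen because the
dicrotic notch is the sharpest feature of the pulse — most of its spectral
content lies above 8 Hz for a ~20 ms notch — while white noise power above
20 Hz (the vast majority at 500 Hz sampling) is discarded. Conditioning
can be disabled (`condition = FALSE`) for fidelity checks on noiseless
signals; the band limit necessarily attenuates the notch slightly, a
noise-robustness trade-off, not an extraction defect.

`segment_beats()` finds beat boundaries as local minima of a lightly
smoothed copy (16 ms moving average), restricted to the deepest depth band
(dicrotic dips sit roughly a quarter of the signal span above the
inter-beat troughs and are excluded), thinned to a minimum separation of
1/3 s (the 3 Hz upper heart-rate bound), and snapped back to sample-level
minima of the conditioned signal. The first segment starts at the lowest
trough preceding the first beat that shows double-peak morphology (two
local maxima with adjacent-valley prominence ≥ 10% of the beat span);
subsequent segments run trough-to-trough. Segments are 0-based and
half-open. On an $n$-beat recording this yields $n-2$ to $n$ complete
segments (edge beats are partial).

## Fiducials and the eleven features

Extrema are detected on a 16 ms-smoothed copy of each beat — so noise
ripple cannot pose as a fiducial — but amplitudes are read from the
original samples at the detected indices, keeping noiseless extraction
exact. Bot is the minimum of the pre-systolic limb, SP the global maximum,
DP the most prominent local maximum after SP (prominence ≥ 5% of the beat
span), DN the deepest local minimum between SP and DP. Notchless beats
fall back to zero crossings of a smoothed derivative (or its
steepest-descent/slowest-decline points) and are flagged
`notch_fallback_used`.

The eleven features, in fixed order: three Bot-anchored amplitudes
(SP−Bot, DP−Bot, DN−Bot), three times from beat start (t\_SP, t\_DN,
t\_DP), the beat period, two amplitude ratios ((DP−Bot)/(SP−Bot),
(DN−Bot)/(SP−Bot)), the systolic rise slope (SP−Bot)/t\_SP, and one
spectral feature: periodogram power at the beat fundamental over total
power. The study text names the three anchored amplitudes and counts
"eleven temporal and spectral features" without enumerating them; this
concrete set realizes that description and is isolated behind a feature
registry (`ppg_feature_registry()`) so alternates can be swapped without
touching the pipeline. Per recording, features are averaged over all
non-degenerate beats (degenerate beats are skipped and counted, not
fatal), and subject covariates are encoded as P-features (age, sex as 0/1,
height, weight; missing covariates are median-imputed at model time).

## The regression models

The boosted model is classical least-squares residual boosting:
$F_0 = \bar y$; for $k = 1 \dots N$, a CART regression tree $T_k$ is fit
to the residuals $r_k = y - F_{k-1}(X)$ and $F_k = F_{k-1} + \nu T_k$.
Trees use greedy variance-reduction splits over all features and all
midpoints between consecutive sorted distinct values, with deterministic
tie-breaking (lowest feature index, then lowest threshold) so fits are
reproducible and row-order independent; leaves store training means.
Training MSE is provably non-increasing in $N$ for $\nu \in (0, 1]$.
Defaults — $N = 200$, $\nu = 0.1$, depth 3, minimum leaf size 2 — are
ordinary gradient-boosting practice (the study states none); they sit in
the flat part of the accuracy/runtime curve for cohorts of a few hundred
rows and are exposed in the model configuration.

Baselines for the comparison harness: linear and ridge regression by
normal equations (with pivoted least squares as the rank-deficient
fallback — single-subject cohorts have constant covariate columns), k-NN
(Euclidean, distance ties broken by row order), a single deeper tree,
bagged trees, and a random forest (bootstrap + √d feature sampling per
split). SVM, AdaBoost, extra-trees and CNN variants of the original
comparison are represented as all-NA rows in `benchmark_models()` output:
no kernel or architecture details exist to implement them faithfully.

`calibrate_personal()` personalizes a population model either by
additional boosting rounds on one person's residuals (population trees
frozen) or by an affine output correction; with a single calibration pair
the slope is fixed at 1 and only the intercept moves.

## Evaluation

`compute_metrics()` reports MSE, RMSE, MAE, R² and MARD
($\mathrm{mean}(|\hat y - y| / y) \times 100$), plus signed per-point
relative differences. The Clarke Error Grid is applied after converting
mmol/L to mg/dL (× 18.016); the inequalities are documented clause by
clause in `?clarke_zone`. Because the original 1987 zone definitions leave
boundary membership ambiguous, this package assigns boundary points to the
better (earlier-letter) zone by making the C/D/E region inequalities
strict; the test suite checks point-for-point agreement with an
independently transcribed reference implementation on a 10,000-point
random sweep (off-boundary, the two dialects coincide).

Monte Carlo cross-validation repeats random train/test splits (defaults:
50 repeats, 20% held out — the study reports a mean/min/max MARD summary
but not its split settings) and reports the metric distribution.
Uncertainty is pinned down as: **epistemic** = mean over points of the
standard deviation of predictions across a bootstrap ensemble (default 20
models); **aleatoric** = mean ± sd over points of each point's held-out
residual variability across MC-CV repeats. Both are in mmol/L and
non-negative by construction.

## Numerical choices and degenerate inputs

* Uniform-grid validation tolerates 1e-9 s of time jitter; sampling rates
  within 1e-6 of an integer are snapped.
* Waveform CSVs are written with `%.17g`, so write→read round-trips are
  bit-exact.
* Local-extremum detection is plateau-tolerant (an extremum falling
  exactly mid-sample still registers on both flanking samples).
* Zero-variance tree nodes (response range ≤ 1e-12) become leaves; ties in
  split scores resolve to the lowest feature index, then lowest threshold.
* Flat or monotone beats raise classed `ppg_degenerate_beat` errors;
  recordings whose beats are all degenerate fail loudly rather than
  returning empty rows.
* Glucose must be strictly positive (MARD and the Clarke grid are
  undefined at 0); predictions can optionally be clipped to a
  physiological 2–30 mmol/L.

## Problem sizes used by the shipped analyses

The test suite exercises reduced cohorts (6–100 recordings, 6 s each) for
unit and property checks and the full 292-record NIR cohort for the
end-to-end recovery check; `scripts/acceptance.R` regenerates all three
full-size cohorts (292/237/626 recordings, 10 s at 500 Hz each), runs
5-fold cross-validated boosting on each, a 50-repeat Monte Carlo CV and a
20-model bootstrap ensemble on the NIR cohort. These sizes match the
study's cohort shapes exactly; recording duration (10 s) and sampling rate
(500 Hz) are this package's defaults, as the study states neither.

## Known limitations

* The eleven-feature set is a reconstruction consistent with the study's
  description, not a verbatim copy of an unpublished table; the feature
  registry exists precisely so a different set can be substituted.
* The synthetic link is affine and single-factor; real glucose-morphology
  coupling is confounded with vascular tone, temperature and contact
  pressure, none of which are modelled.
* The boosted model supports squared loss only, and there is no
  hyperparameter search beyond explicit configuration.
* Multi-patient generalization in the simulator is optimistic: subject
  effects are a single amplitude scale, so P-features matter far less than
  they would clinically.
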