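---
title: "Evaluating decompensation alert algorithms for home telemonitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating decompensation alert algorithms for home telemonitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telealert)
```

## The problem

Patients with chronic heart failure decompensate episodically: fluid
accumulates over days to weeks, weight rises, thoracic impedance falls, and
the episode often ends in an unplanned hospitalization. Daily
home-telemonitoring of body weight and noninvasive transthoracic
bio-impedance (NITTI) offers a window in which a timely alert could trigger
intervention. `telealert` implements the full evaluation chain for such
alert algorithms: the alert statistics themselves, the two-week window
labeling that defines true and false alarms, constrained threshold
optimization, and a stratified leave-patient-out cross-validation that
protects the reported operating characteristics from optimism.

Impedance values are stored log-transformed. Impedance distributions are
right-skewed; the log base is not important for any downstream decision
(every algorithm here is either translation-invariant or standardized), and
the natural log is the default because typical chest impedances of 20–40
ohm then land near 3.0–3.7 log-ohm, the scale on which clinical analyses of
this signal are usually reported. The base is configurable in
`load_cohort()`.

## The three output indices

Each algorithm maps a daily measurement series \(x_t\) to an *output
index*; an alert fires when the index crosses a threshold in the direction
of decompensation (up for weight, down for log-impedance).

**Rule of thumb (RoT).** \(\mathrm{RoT}_t = x_t - x_{t-d}\), the simple
difference against the value \(d\) days earlier. Fast but noisy: a single
aberrant reading moves it as much as a genuine trend.

**Moving-average convergence divergence (MACD).**
\(\mathrm{MACD}_t = \mathrm{SMA}_{N_s}(x)_t - \mathrm{SMA}_{N_l}(x)_t\),
the difference of a short and a long trailing simple moving average
(\(N_s < N_l\)). On a linear ramp of slope \(s\) it converges to
\(s\,(N_l - N_s)/2\), which the test suite checks in closed form. It
smooths measurement noise and follows gradual trends in either direction.

**One-sided standardized CUSUM.** Each day is standardized against the
trailing \(d\)-day running mean and SD, current day excluded, so a sudden
deviation is scored against the pre-deviation baseline:
\(z_t = (x_t - \mu_t)/\max(\sigma_t, \sigma_{\min})\). The chart then
accumulates deviations beyond an allowance \(c\), clamped one-sided:
\(S_t = \min(0, S_{t-1} + z_t + c)\) for downward detection (and the
mirrored form with \(\max\) for upward). Sustained drift accumulates;
isolated noise is absorbed by the allowance. Standardization makes the
index translation- and scale-invariant, which the suite verifies as an
algebraic property.

The published formulations of these trend detectors vary in detail; the
forms above are the standard trailing-window choices consistent with the
parameter names used in the telemonitoring literature (day lag \(d\);
window pair \(N_s, N_l\); running-window \(d\) and depreciation \(c\)). An
alternative reading of "depreciation" as a multiplicative decay
\(S_t \leftarrow \gamma S_{t-1}\) exists; the clamp-plus-allowance form is
implemented because it is the textbook CUSUM and matches the qualitative
description of sustained one-sided alerts.

Numerical choices: \(\sigma_{\min} = 10^{-6}\) measurement units guards
division by zero on constant windows; the chart starts at \(S = 0\) after
the warm-up and is reset at monitoring start and after every
hospitalization discharge, never merely because an alert fired.

Thirteen published weight rules (guideline bodies and earlier studies) ship
as presets in `guideline_rules()`; pound thresholds are converted at
0.45 kg/lb. One preset is a moving-average rule (4 lbs on a 5/80-day MACD);
the rest are day differences evaluated through the RoT machinery.

## Imputation, adherence, monitoring blocks

Real adherence is intermittent. Interior gaps are filled by linear
interpolation between the bracketing observations (`prepare_series()`), and
the interpolation is *causal in the real-time sense*: the imputed value for
a gap day depends only on its two bracketing observations, so it becomes
available the moment the later observation arrives and never uses
information beyond it. The suite checks the resulting guarantee
end-to-end: every index value at day \(t\) is unchanged by deleting all
data after \(t\).

Hospital stays interrupt monitoring. Each admission closes the running
monitoring block and a new block opens `pause_days` (default 7) later;
imputation and all indices restart per block, so no trend is interpolated
across a hospitalization. The 7-day figure is a design choice — analyses
of this kind only state that short stretches directly following a
hospitalization are removed — and it is a parameter everywhere it matters.

Adherence is counted on *observed* measurements only (imputed days never
count). The criterion "at least 3 measurements per week" is interpreted
strictly: each 7-day half of the 14-day evaluation window needs ≥ 3
observed values. A lenient variant (≥ 6 anywhere in the fortnight) is
available as `adherence_mode = "per_fortnight"`.

## Windows, labels, and metrics

Monitoring time is divided into 14-day periods such that a period
containing an HF-adjudicated hospitalization ends on the admission day:
within a block ending in an HF admission, windows are tiled backward from
the admission (the leftover partial window at the block start is
discarded); other blocks are tiled forward with the trailing partial
discarded. Days covered, days discarded and hospitalization pauses
partition the monitoring interval exactly, and the suite asserts this
conservation over random event placements.

A period is scored by its *peak* index value (maximum for upward indices,
minimum for downward). For any monotone threshold rule, "an alert occurred
in the window" is equivalent to "the peak crossed the threshold", so a
single score per period supports full ROC sweeps. An event-ending period
whose peak crosses the threshold is a true positive, otherwise a false
negative; non-event periods analogously give false positives and true
negatives. Non-adherent periods are excluded from the analysis — including
event windows, which are excluded rather than counted as missed
detections — as are periods in which the index is entirely undefined
(warm-up).

Non-HF hospitalizations end no period and carry no event label, but the
monitoring pause applies after any admission.

`roc_curve()` sweeps all distinct peaks; `partial_auc()` integrates the
staircase over specificity ∈ [`spec_min`, 1] by trapezoid and normalizes
by \(1 - \texttt{spec\_min}\) so the value lives in [0, 1] (only the argmax
matters for optimization, which normalization preserves).
`youden_threshold()` maximizes \(J = \text{sens} + \text{spec} - 1\) among
points with specificity strictly above the bound, ties broken toward
higher specificity; if the bound is unattainable the most specific point
is returned with a warning.

**False alarms per patient-year.** Clinical workload is better captured by
alert *episodes* than by window counts: consecutive alert days merge into
one episode, an episode is false iff no HF admission follows within 14
days of its onset, and the rate divides false episodes by total monitoring
time. A five-week sustained alert can contribute three window false
positives but only one false alarm; the grace period of 14 days mirrors
the detection window, since no other value is canonical.

**Period-mean comparison.** `compare_period_means()` tests whether values
(raw measurements or output indices) in pre-event windows differ from all
other windows using `lmerTest::lmer(value ~ label + (1 | patient))` —
patient-specific random intercepts absorb between-patient level
differences. On singular fits it falls back to a within-patient label
permutation test with a warning. The suite checks calibration (uniform
p-values under permuted labels) and recovery of an injected −0.4 log-ohm
pre-event shift at 91 patients.

## Parameter optimization and cross-validation

Default search grids: RoT \(d \in \{1,\dots,21\}\); MACD
\(N_l \in \{10, 15, \dots, 50\}\), \(N_s \in \{1,\dots,10\}\) with
\(N_s < N_l\); CUSUM \(d \in \{10, 15, \dots, 30\}\),
\(c \in \{0.5, 0.7, \dots, 1.5\}\). Because two-week periods without an
event vastly outnumber event windows, parameters are chosen to maximize the
partial AUC at specificity above 95%, with ties broken toward smaller
windows (grids are ordered simple-to-complex). Grids are plain data frames
and fully configurable; published per-fold optima in this literature
include CUSUM windows up to 50 days and allowances off the 0.2-step
lattice, so the defaults should be treated as the documented search range,
not a hard constraint.

`cross_validate()` implements stratified leave-patient-out CV with
\(k = 8\) folds: event patients are dealt greedily to balance per-fold
event counts (patients with several events make exact balance impossible,
so balance is best-effort), then event-free patients balance the fold
sizes. For each fold, parameters are optimized on the other seven; the
held-out fold's period peaks are computed under those parameters and
divided by the training-set robust index scale (MAD × 1.4826, falling back
to the SD and then to 1 when the MAD degenerates — a mostly-clamped CUSUM
on near-constant data has MAD 0). This normalization puts peaks obtained
under different per-fold parameters on one axis so the held-out folds can
be recombined into a single unbiased ROC curve; z-scoring and
threshold-relative scaling are alternatives, and the robust scale was
chosen because peak distributions are heavy-tailed near events. The
operating threshold is then chosen once, on the pooled out-of-fold ROC, as
the Youden point with specificity above 90%.

The per-fold chosen parameters are reported with mean and SD
(`summary()` on the result): parameter variance across folds is a direct
read-out of the stability of the selected configuration.

```{r cv-example, eval = FALSE}
co <- generate_cohort(cohort_config(seed = 7))
cv <- cross_validate(co, "cusum", "nitti_log_ohm", seed = 7)
summary(cv)
plot(cv)   # pooled out-of-fold ROC, specificity 0.9-1
```

## The synthetic cohort generator

No individual-level telemonitoring data of this kind are public, so
`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes: 91 patients monitored for about 300 (SD 45) days;
baseline weight N(84, 19²) kg and baseline log-impedance N(3.4, 0.3²)
log-ohm per patient; i.i.d. daily noise (0.6 kg, 0.06 log-ohm);
per-day/per-modality Bernoulli adherence 0.8, optionally with
consecutive-day dropout bursts; a constant per-day event hazard of
24/(91 × 300), giving ≈ 24 expected hospitalizations per cohort; and a
linear prodrome over the 14 days before each admission in which weight
rises 2.5 kg and log-impedance falls 0.4 log-ohm in total, reaching full
magnitude on the admission day. Monitoring pauses 7 days after each
admission and the signal resumes at baseline. The prodrome magnitudes are
calibrated to the reported pre-event vs other-period means for this kind
of cohort (a 0.4 log-ohm impedance gap); the *shape* of real prodromes is
unknown beyond rough monotonicity, and linear is the simplest testable
choice — `inject_event()` makes the drift pluggable for fixtures.

What the generator does **not** emulate: diurnal or seasonal variation,
medication interventions and self-correction, device error spikes,
informative missingness (sicker patients measuring less), or residual
post-discharge elevation. Its pre-event signal (≈ 6.7 daily-noise SDs of
total log-impedance drop) is cleaner and more regular than reality, so
passing the evaluation chain on synthetic cohorts demonstrates the
*machinery* — labeling, optimization, CV bookkeeping — and near-ceiling
synthetic sensitivities must not be read as clinical performance
estimates. Directional conclusions (impedance beats weight; trend
detectors beat day differences at matched specificity) do transfer, and
the suite checks them across 20 generator seeds.

## Problem sizes used by the test suite

Oracle-equivalence checks run 200 random series of length 100 against
independent brute-force implementations (tolerance 1e-9); causality checks
50 gapped series; bookkeeping conservation 100 random event placements;
ROC/Youden oracle comparisons 30 small instances; the separable-limit check
runs full 8-fold CV for all three algorithms on a 16-patient noiseless
cohort; the ordering check runs 8-fold CV for four algorithm/modality
combinations on 20 seeded 91-patient cohorts; mixed-model calibration uses
200 permutations at 91 patients. These sizes keep the whole suite around
six minutes on one core while leaving Monte-Carlo margins wide.

## Known limitations

* The evaluation is window-based; time-to-detection and lead-time
  distributions are out of scope.
* Weight and impedance are evaluated separately; no multivariate fusion.
* The false-alarm grace period and the post-discharge pause are
  conventions, not estimated quantities.
* `compare_period_means()` treats period means as exchangeable within
  patient; serial correlation between adjacent windows is ignored, which
  is anti-conservative for very long records.
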