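---
title: "Methods: simulating and analysing sensory-feedback force tremor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing sensory-feedback force tremor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorfb)
```

## The experiment the package models

Essential tremor (ET) expresses as a 4–12 Hz involuntary oscillation during
voluntary motor acts. In the paradigm this package implements, a participant
pinches a force sensor to match a target force of 15 % of their individually
calibrated maximum (MaxF), holding it for 30 s per trial after a 30 s rest.
Feedback about the deviation from the target is given visually (a cursor
whose position is `(F_p − F_t)·G + F_t`), auditorily (a tone whose pitch is
linearly related to the deviation, 440 Hz at match, clipped to 120–880 Hz,
against a constant 440 Hz reference), or both. The *gain* `G` magnifies the
displayed or heard error without changing the required force: low gain
(0.04) renders the deviation almost invisible, high gain (6.9) exaggerates
it. Each participant completes 12 trials — three fixed-order blocks
(visual-only, audio-visual, auditory-only) of four trials with gain levels
randomised within block, two low and two high per block.

The outcomes per trial are: tremor-band power (the Welch power spectral
density of the normalised, band-passed force, integrated over 4–12 Hz),
voluntary-band power (0–3 Hz), mean force, RMSE of the unfiltered
normalised force against the normalised target (1.0), and the
baseline-corrected mean pupil diameter of the task window as an arousal
proxy.

Raw data from the human study are not deposited, so the package treats the
analysis as a parameter-recovery problem: a synthetic-cohort generator
encodes the qualitative effect structure of the findings (patients'
tremor-band power increases under high gain in every feedback modality;
controls respond weakly and only under combined feedback; patients dilate
their pupils under the auditory-involved high-gain conditions), and the
analysis chain must recover that structure from raw simulated streams.

## The signal model

For each trial, task-window force at 80 Hz is

> F(t) = F_t · [ 1 + d(t) + A · sin(2π f t + φ) + ε(t) ]

with `F_t = 0.15·MaxF` the target force, `d(t)` a voluntary tracking drift
(Gaussian noise band-limited below 1.5 Hz, standard deviation ~8 % of the
target, so that tracking error is dominated by voluntary drift rather than
tremor in both groups), `A` the tremor amplitude, `f` the participant's
tremor frequency,
`φ` a uniform per-trial phase, and `ε` white sensor noise (sd ~0.7 %).
Under high gain the amplitude becomes `A = A₀ (1 + β·w(type))`, one
multiplicative knob `β` per participant with feedback-type weights `w`
(patients: vo 1, va 1.2, ao 1 — the combined condition responds most;
controls: vo 0, va 1, ao 0). Tremor-band power therefore scales as
`(1 + β w)²`, which is the generator-side counterpart of the
multiplicative-looking power increases the analysis is meant to detect.
Rest windows are near-zero force with sensor noise; force ramps smoothly
(3 s smoothstep) into and out of each task plateau so that the zero-phase
band-pass filter is not driven by steps at the epoch edges — a step's slow
transient would otherwise bleed several seconds into the task window in
both time directions.

Pupil diameter at 240 Hz is a participant baseline (≈4.5 mm) plus a
condition-dependent arousal response `a(type, gain) · (1 − e^{−t/τ})`
(τ = 2 s) during the task, decaying during the following rest, plus slow
band-limited noise (sd 0.15 mm below 0.5 Hz). Blinks arrive as a Poisson
process (0.1 Hz, 200 ms): the diameter collapses towards zero with 20 ms
ramps, the confidence score drops below 0.3, and the gaze trace carries a
saccade-like deflection producing an acceleration transient. Where the
specified arousal contrast is zero it is *exactly* zero for every
participant — truncating participant scatter at zero would otherwise
manufacture a spurious positive group effect where none is intended.

Effect sizes are not recoverable from the original figures; the defaults
are calibration knobs chosen once so that the generated contrasts are
strong where the modelled study reports clear effects (within-group
patient contrasts, the controls' audio-visual contrast, the patients'
auditory-involved pupil contrasts) and exactly null elsewhere. They are
parameters of `cohort_effects()`, not estimates of the human data.

### Two sampling levels

`simulate_cohort(level = "signal")` emits complete raw streams that are
pushed through the full processing chain. `level = "feature"` draws
per-trial features directly from the distribution the signal model induces
(sinusoid band power `g²·A²/2` with `g²` the double-pass filter gain at the
tremor frequency, a Gamma-scattered white-noise band floor, the analytic
arousal-ramp mean, matched trial-level noise). The feature level exists so
that Monte-Carlo work on the statistical layer (thousands of cohorts) runs
in seconds; the test suite checks that the two levels agree in
distribution, and the headline pattern-recovery experiment is also run at
the signal level end-to-end at smaller counts.

## The force processing chain

1. **Normalisation** — every sample is divided by `0.15·MaxF`, so perfect
   tracking reads 1.0 and features are comparable across participants. All
   features are exactly invariant to a common rescaling of raw force and
   MaxF.
2. **Band-pass** — a fifth-order Butterworth with corners at 0.1 and 12 Hz,
   designed in zero-pole-gain form and applied as a cascade of second-order
   sections, forward and backward (zero phase, squared magnitude). The
   transfer-function (b, a) form of this tenth-order design is numerically
   fragile at a 0.1 Hz corner and 80 Hz rate, which is why the sections are
   assembled directly from conjugate pole pairs; the realised response
   matches the analytic Butterworth magnitude to ~1e−13 across the band.
   Near the upper corner the pass-band is no longer flat: a 10.8 Hz tremor
   loses ~30 % of its measured band power to the double-pass roll-off. This
   is a property of the modelled processing chain itself and is mirrored in
   the feature-level sampler.
3. **Epoching** — the continuous filtered stream is cut into half-open
   `[onset, offset)` windows keyed by the event-marker stream; 30 s at
   80 Hz gives exactly 2400 samples per task epoch.
4. **Welch PSD** — Hann-windowed averaged periodograms, 4 s segments, 50 %
   overlap, density scaling. The window length is a package decision (the
   modelled study does not print one): 4 s gives a 0.25 Hz grid, putting
   the 3 Hz and 4 Hz band boundaries on grid points. Band powers are
   trapezoidal integrals of the PSD, so a unit-amplitude in-band sinusoid
   integrates to A²/2 = 0.5 and white noise satisfies Parseval within
   Monte-Carlo error.
5. **Error features** — mean force and RMSE are computed on the
   *unfiltered* normalised task epoch: `rmse = sqrt(mean((x − 1)²))`.

Because trials start and stop, the voluntary band (0–3 Hz) of a session
epoch always contains some energy from the task on/off envelope in
addition to the tracking drift; the pure-filter leakage property (an
isolated 8 Hz epoch leaves < 1 % of its power below 3 Hz) holds for
isolated epochs and is tested that way.

## The pupillometry chain

Blinks are detected where confidence falls below 0.6 **or** the robust
z-score (median/MAD) of the gaze-acceleration magnitude exceeds 5; flagged
runs closer than twice the padding are merged and padded by 50 ms per
side. The thresholds are package decisions (the modelled pipeline names
the signals but no cut-offs). Two of them deviate from the first-draft
values one might take from vendor conventions (z = 3, 100 ms padding)
because those values cannot satisfy the chain's own accuracy contract —
at a realistic blink rate they falsely mask ~3 % of clean samples purely
through the robust-z tail of smooth fixational jitter plus padding,
whereas z = 5 with 50 ms padding keeps false masking near 1 % at 100 %
detection of injected blinks. All three are configurable.

Masked samples become NaN and are filled by Gaussian-kernel FFT
convolution: the kernel spans 120 samples (0.5 s at 240 Hz) with standard
deviation span/8 = 15 samples, and missing samples are excluded from the
weight normalisation. A single normalised-convolution pass carries a
first-order bias at gap edges (the one-sided Gaussian average of a sloped
signal is shifted by ~0.8 σ · slope), so the estimate is iterated to
self-consistency, which removes the slope bias and reproduces linear
trends across gaps exactly; `max_iter = 1` recovers the plain one-pass
behaviour. Valid samples are never altered, and traces more than half
missing are rejected rather than invented.

Epochs of `[−10, +30)` s around each task onset are baseline-corrected by
subtracting the mean of the `[−10, −2)` s window (the rest period covers
it), making the trial mean exactly invariant to any constant offset of the
raw trace; the feature is the mean corrected diameter over `[0, 30)` s.
Epochs whose pre-interpolation mask covers ≥ 50 % of their samples yield a
missing feature with the reason recorded — an interpolation spanning most
of an epoch would be invention, not measurement.

## The statistical layer

Contrasts are high-minus-low gain differences per participant and feedback
type. The default unit pairs the k-th low with the k-th high trial
(`trial_pair`), giving two rows per participant and type; with 14
participants per group the pooled between-group t-test then runs on ~56
differences, the scale of the degrees of freedom the modelled study
reports. A `participant` unit (averaging the two trials per gain first) is
available.

* **Between groups** — pooled-variance two-sample t-test on the contrasts,
  per feedback type and outcome.
* **Within groups** — participant means per gain level, paired t-test,
  with a Shapiro–Wilk gate (α = 0.05) diverting to the Wilcoxon
  signed-rank test; the branch taken is always reported. The within-group
  test type is a package decision; the gate mirrors the covariate and
  correlation conventions of the modelled analysis.
* **Trial-level ANOVA** — separate one-way fixed-effects ANOVAs per factor
  (group; feedback type) on trial-level outcomes, reported with each
  factor's own residual df, as the modelled results do. Trials from the
  same participant are treated as independent; under participant
  heterogeneity this is anti-conservative for the group factor, which is
  why the type-I calibration uses the exchangeable null (below) and why
  inferential weight rests on the contrast tests, not the trial-level
  ANOVA. This is a documented limitation, not an endorsement.
* **Covariates and correlations** — Shapiro–Wilk-gated Mann–Whitney vs
  t-test for group comparisons (with a forced Mann–Whitney option, the
  convention for clinical rating scales); Pearson vs Spearman correlation
  gated on Shapiro–Wilk (and Levene across groups when a grouping is
  given); partial correlation by residualising both variables on the
  covariate (rank-transformed first in the Spearman branch) with n − 3
  degrees of freedom. No multiple-testing correction is applied by
  default (the modelled analysis reports uncorrected per-condition
  p-values); a Holm option exists.

### Monte-Carlo utilities and the sizes they run at

`calibrate_type1()` simulates zero-effect cohorts with *no* participant
heterogeneity — the exchangeable null under which all three tests should
hold their nominal level — and checks the rejection rate of the contrast
t-test and both ANOVA factors; the suite runs 1,000 cohorts of 14 per
group. `pattern_recovery()` scores, per simulated study, the full headline
significance pattern (patients significant in vo, va, ao for tremor;
controls only in va; patients' pupil contrast significant in va and ao but
not vo); the suite runs 200 feature-level studies (the rate sits near 0.9
at the defaults; its ceiling is ~0.86 because three truly-null component
tests must simultaneously stay non-significant at α = 0.05) and smaller
signal-level batches end-to-end. `sequential_power()` emulates the
sequential sampling plan of the modelled study: cohorts of increasing size
up to 25 per group, stopping when the primary between-group contrast test
reaches 80 % power; at the default effect sizes the target is reached at
the smallest size examined.

## Numerical and degenerate-input choices

* Half-open windows everywhere (`[onset, offset)`, baseline `[−10, −2)`),
  so adjacent epochs never share samples.
* The Welch integrator handles off-grid band edges by linear interpolation
  of the PSD; a zero-width band integrates to 0; a band outside the grid
  is an error.
* A constant trace filters to exactly zero (steady-state initial
  conditions per section), and an all-zero epoch yields an identically
  zero PSD.
* Constant covariates force the nonparametric branch; a constant
  correlation variable is an error; a constant outcome yields F = 0 by
  convention.
* All randomness flows from one master seed through deterministic child
  seeds (kept below 2³¹), so cohorts, feature tables and written TSVs are
  byte-identical across reruns of the same configuration.

## What passing tests do and do not show

The generator encodes effect *structure*, not tremor mechanism: no
biomechanics, no neural circuit, no gain-dependent change in voluntary
tracking, an ideal common clock (the hardware jitter of the modelled setup
is not simulated), stationary tremor amplitude within trials, and
vendor-idealised blink morphology. Recovery of the synthetic effects
therefore validates the processing and statistics — that the chain
measures what the signal model puts in, at the stated sizes and noise
levels — and says nothing further about human data. Real recordings would
additionally face drifting electrode/sensor baselines, non-sinusoidal and
amplitude-modulated tremor, pupil foreshortening and luminance effects,
none of which are modelled here.
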