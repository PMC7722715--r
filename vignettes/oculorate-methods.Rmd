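---
title: "Pre-target oculomotor inhibition: models, simulator and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-target oculomotor inhibition: models, simulator and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculorate)
```

## The scientific question

During fixation, humans produce small saccades (mostly microsaccades,
< 1 degree) at a rate of roughly 1--2 per second. When a target is
anticipated at a predictable moment, this rate drops in the last few
hundred milliseconds before target onset — *pre-target oculomotor
inhibition*. Two accounts of the effect make different predictions when
foreperiod (cue-to-target interval) distributions are manipulated across
blocks:

* **Certainty hypothesis** — inhibition reflects the observer's global
  state of certainty within a block. Pre-target saccade rate (SR) should
  depend only on the block's foreperiod variability: strongest inhibition
  in full-certainty blocks (one fixed foreperiod), weaker in high-certainty
  blocks (80%/20% mix of two foreperiods), weakest in low-certainty blocks
  (five equiprobable foreperiods) — identically for every trial of a block.
* **Temporal-orienting hypothesis** — inhibition tracks the probability
  that the target is about to appear *now*. For a 1 s foreperiod that is
  the marginal frequency of the 1 s foreperiod in the block (100%, 80% or
  20%); for a 2 s foreperiod it is the conditional probability (hazard):
  once 1 s has passed without a target in a two-foreperiod block, the
  target is certain to come at 2 s, whereas in a five-foreperiod block the
  conditional probability just before 2 s is only
  0.2 / 0.6 = 1/3.

The package implements the full chain that discriminates the two accounts:
a synthetic binocular gaze generator with a configurable hazard-driven
inhibition effect, the preprocessing and saccade-detection pipeline, the
pre-target SR statistic, and the inferential battery (repeated-measures
ANOVA, planned contrasts with FDR control, effect sizes, JZS Bayes
factors) that turns cell means into a per-hypothesis verdict.

```{r}
low <- block_distribution("low_certainty")
hazard_profile(low)
sr_predictions("orienting")
```

## The design

Five block types (`r paste(names(run_config()$blocks_per_type), collapse = ", ")`)
define foreperiod distributions over {1000, 1500, 2000, 2500, 3000} ms.
A session is 17 blocks (1 + 1 + 5 + 5 + 5) of 80 trials; each block's
foreperiod counts are **exact** fractions of the design (counterbalanced,
not sampled), trial order is shuffled, and inter-trial intervals are
uniform on [700, 1200] ms. Trials fall into four conditions:
full-certainty, high-certainty-frequent (the block's 80% foreperiod),
high-certainty-rare (the 20% foreperiod), and low-certainty.

## The generative model

`simulate_gaze()` produces a continuous 1000 Hz binocular recording per
block plus the ground truth of every injected event:

* **Drift** — a 2-D Gaussian random walk, `drift_sd` = 0.08 deg/sqrt(s)
  per axis, yielding drift excursions of a few hundredths of a degree over
  hundreds of milliseconds, typical of stable fixation.
* **Saccades** — an inhomogeneous Bernoulli process at 1 ms resolution.
  Outside foreperiods the rate is `base_saccade_rate` (1.8/s). During a
  foreperiod it is scaled by `1 - inhibition_depth * anticipation(t)`,
  where `anticipation(t)` is the conditional probability that the target
  arrives within `inhibition_window_ms` (300 ms) given that it has not yet
  appeared — the temporal-orienting generative law. At the default
  `inhibition_depth` = 0.8 the pre-target rate in a fully predictable
  trial drops to about 0.36/s, the size of drop reported in fixation
  paradigms with strong temporal expectations. Amplitudes are log-normal
  (median 0.35 deg, sdlog 0.45; predominantly microsaccadic, occasional
  ~1 degree events). Peak velocity follows the main sequence
  `v = 45 * amplitude` with 10% multiplicative log-normal noise — the
  linear regime of the published amplitude--peak-velocity law for small
  saccades. The waveform is a minimum-jerk displacement profile; because
  amplitude, duration and peak velocity of a minimum-jerk movement are
  linked by `v_peak = 1.875 A / d`, the duration follows from the sampled
  amplitude and peak velocity (about 42 ms at the defaults) rather than
  from a separate duration law — the three quantities cannot be set
  independently.
* **Blinks** — a 0.1/s Poisson process, 100--300 ms duration: the pupil
  channel ramps to 0 over 20 ms raised-cosine edges and the position
  channels go missing, emulating video-oculography dropout.
* **Measurement** — both eyes share the drift + saccade signal (conjugate
  gaze) and receive independent white noise, `noise_sd` = 0.01 deg, the
  nominal resolution class of research-grade video eye trackers.

What the generator deliberately does *not* emulate: pupillary light
responses, post-saccadic oscillations, smooth pursuit, saccadic
refractoriness (onsets are genuinely Bernoulli so that closed-form rate
checks hold), corrective-saccade statistics, and drift
micro-structure (tremor). Passing tests therefore demonstrate that the
pipeline recovers events and rate differences from data with realistic
first-order statistics, not that it handles every artifact of real
recordings.

All randomness flows from one integer seed per call; `run_experiment()`
fans a master seed out to per-subject, per-block, per-stage seeds with a
counter-based scheme, so every stage is individually reproducible.

## Preprocessing

* **Filtering** — the position channels are low-pass filtered at 60 Hz
  with a zero-phase 4th-order Butterworth response, applied in the
  frequency domain (the squared magnitude of the digital Butterworth
  response, i.e. the transfer function of one forward and one backward
  pass). Zero phase is essential: any group delay would bias every
  onset-based statistic. Missing spans are preserved; each contiguous run
  is filtered separately with reflective padding. Pupil channels are not
  filtered.
* **Segmentation** — trials span −300 ms before cue to +300 ms after
  target, endpoints inclusive (a 1000 ms foreperiod gives 1601 samples);
  the convention is recorded in the run manifest.
* **Blink exclusion** — blinks are the union of missing-data spans (the
  stand-in for the tracker's proprietary dropout detector) and spans where
  *both* eyes' pupil deviates from the segment mean by more than 2.5 SD
  for at least 3 consecutive samples; segment mean and SD are computed per
  eye, excluding missing samples (otherwise dropout dominates the SD).
  Overlapping events are merged, and samples within 200 ms of any blink
  are excluded from analysis.

## Saccade detection

Velocity is estimated with the classic 5-sample moving-window difference
(`(x[t+2] + x[t+1] - x[t-1] - x[t-2]) / 6Δt`), shrinking symmetrically at
segment edges. Per segment, each velocity component is standardized by its
median and the median-based robust SD `sqrt(median(v²) - median(v)²)` over
valid samples. A saccade is at least 6 consecutive samples in which the
standardized-velocity norm exceeds the threshold; events touching invalid
samples are discarded; only binocular events (temporal overlap in both
eyes) are kept; and an event starting within 50 ms of the previous offset
is discarded as an overshoot. Amplitude is the straight-line displacement
onset→offset (the standard main-sequence convention), not path length.

Two threshold modes are implemented. The default, `"component"`, is the
elliptic criterion of the published velocity-threshold algorithm: the norm
of the component-standardized velocity exceeds `lambda_sd` (6). The
alternative `"norm"` mode re-centers the *norm* at its own median plus
`lambda_sd` robust SDs of the norm. The norm mode is degenerate on
fixation-like data and is therefore not the default: for near-Rayleigh
velocity-norm noise the median of the squared norm equals the squared
median exactly, so the median-based robust SD of the norm is ≈ 0 and the
threshold collapses onto the noise median (we measure robust SDs of
~2e-6 on simulated drift). The component mode reproduces the published
algorithm's behavior and is what all defaults and tests use.

Detection quality control follows the field's convention: the Pearson
correlation between amplitude and peak velocity of retained events (the
main sequence) should exceed 0.9; `main_sequence()` computes it, and the
acceptance checks verify r > 0.9 on a full default synthetic session,
together with precision and recall ≥ 0.9 against the simulator's ground
truth.

## Rates and the pre-target SR

`rate_timecourse()` counts saccade *onsets* per sample across trials,
divides by the number of trials valid at that sample (blink-excluded
samples leave the denominator), and multiplies by the sampling rate —
saccades per second. Where no trial is valid the rate is 0 by convention.
The pre-target SR is the unweighted mean over −100 to 0 ms relative to
target onset, endpoints inclusive (101 samples); per subject × condition
× foreperiod cell, trials are pooled into the cell's time course first and
the window mean is taken second. With complete data the order of averaging
is irrelevant; with blink-censored samples the pooled-then-windowed order
weights each sample by its valid-trial count, which is the convention
implied by computing rates across trials per sample. Trials contributing
no valid pre-target samples drop out of their cell. A 50 ms moving-average
smoother is provided for display only; no statistic is computed on
smoothed traces.

## Statistics

* **RM-ANOVA** — two-way (Condition × Foreperiod over the 1 s/2 s cells)
  and one-way per foreperiod, computed through the standard multivariate
  linear-model route. Mauchly's test per multi-level effect; when violated
  (p < 0.05), the corrected p is Greenhouse–Geisser if ε < 0.7 and
  Huynh–Feldt otherwise. Partial η² with a 95% CI from non-central-F
  inversion (the CI construction is a standard choice; no particular
  method is canonical). The test suite checks the whole table against a
  hand-written sums-of-squares/ε oracle at 1e-8.
* **Planned contrasts** — paired t-tests on subject-level cell means
  (df = n − 1), with the combined high-certainty cell formed by
  within-subject averaging before the difference. The five contrasts form
  one Benjamini–Hochberg family per foreperiod, mirroring the analysis
  plan. Cohen's dz = mean(diff)/SD(diff) with non-central-t CI.
* **Bayes factors** — JZS BF01 (null in the numerator) with the default
  Cauchy prior (scale √2/2) on the standardized effect, by adaptive
  quadrature over the auxiliary scale parameter with the integrand on the
  log scale; the quadrature's absolute-error estimate is reported as a
  percentage. An independent non-central-t mixture quadrature serves as
  the test oracle (0.1%).
* **Within-subject SEM** — subject-centered (grand mean restored), per-cell
  SD/√n, multiplied by the √(M/(M−1)) small-sample bias correction for M
  cells.
* **Foreperiod trend** — one-way RM-ANOVA over the five low-certainty
  foreperiods plus a linear contrast (−2, −1, 0, 1, 2); a negative slope is
  the classic hazard-driven foreperiod effect.

## The verdict rule

`evaluate_hypothesis()` operationalizes "consistent with hypothesis H" as:
every inequality H predicts is FDR-significant (p < 0.05) in the predicted
direction, *and* every equality H predicts is non-significant with
BF01 > 1. Both thresholds are configurable. The rule is ordinal by design —
the hypotheses predict orderings and equalities, never SR magnitudes.

A statistical property of this conjunction is worth knowing: under an
exactly true equality with n = 20 subjects, BF01 > 1 holds with
probability ≈ 0.92 (the JZS BF01 crosses 1 near |t| = 1.87), so even a
perfectly powered experiment affirms both predicted equalities only ~85%
of the time. Replicate-level recovery rates of the orienting verdict
therefore plateau in the low-to-mid 80% range at this sample size; this is
a property of the verdict rule and the sample size, not of the detection
or rate pipeline.

## Problem sizes and numerical choices

The packaged tests run the full chain at deliberately chosen sizes: the
session-level checks use one subject × 17 blocks × 80 trials; the
replicate-level recovery analysis uses 20 replicates of 20 subjects × 17
blocks × 20 trials (a scaled session that keeps all condition frequencies
intact); detector calibration uses ≥ 1000 injected events. Degenerate
inputs are defined, not crashed on: zero velocity variance yields no
detections (with a log message), an all-missing segment is one whole-segment
blink, F = 0/0 is reported as 0, a zero-variance contrast difference gives
t = 0 (zero mean) or an undefined-dz flag (nonzero mean), and cells with no
valid pre-target samples are flagged not-computable rather than imputed.

## Limitations

The simulator's realism is first-order (rates, kinematics, noise spectra),
so absolute detection scores on real recordings will differ; the verdict
rule inherits the finite-sample BF01 ceiling described above; and the
blink stand-in reproduces the observable output of proprietary dropout
detectors (missing spans), not their internals. Accuracy and reaction-time
behavior are simulated only as descriptive placeholders and never tested
inferentially.
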