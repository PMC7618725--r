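---
title: "Gamma activation spread: models, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma activation spread: models, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaspread)
```

## The problem

During a sustained (tonic) grip, cortical gamma-band oscillations
(30--48 Hz) and high-gamma oscillations (52--80 Hz) show brief,
spatially focal amplitude increases, while beta oscillations (13--30 Hz)
desynchronise with movement. In amyotrophic lateral sclerosis (ALS),
loss of inhibitory interneuronal control is thought to let gamma
activation spill over far more of the cortex than in healthy controls.
`gaspread` quantifies that spill-over from parcellated source-space MEG
epochs as the **gamma activation spread (GAS)**: the mean number of
parcels whose gamma power exceeds a control-calibrated activation
threshold per 100 ms time bin, averaged over the tonic grip window
(1--3 s after the visual trigger).

The analysis chain is: time-frequency decomposition and baseline
correction of each parcel's epochs; reduction to band power in 100 ms
bins; binarization of each parcel x band x bin against thresholds set at
+/- 2 pooled standard deviations of the healthy-control distribution;
region-count spread time courses and the GAS scalar; and permutation
GLM inference (group contrasts and clinical associations) with
max-statistic family-wise error control. A synthetic cohort generator
with planted effects closes the loop so that every stage is testable
without patient data.

## Trial structure and the synthetic cohort

Each simulated trial spans -1 to 5 s around the trigger (6 s at 250 Hz
by default, 120 trials per participant), with a 12 N bilateral grip
held during 0--3 s and a tonic phase at 1--3 s. The generator
(`simulate_cohort()`) produces, per participant:

* **Background noise** — independent 1/f-shaped Gaussian noise per
  trial and region (spectral power slope -1, flat below 1 Hz), the
  simplest background that gives realistic time-frequency baselines.
* **Beta rhythm with ERD** — an ongoing 20 Hz oscillation in a set of
  "motor" parcels whose amplitude drops by 70% during 0--3 s with
  0.2 s raised-cosine ramps, emulating movement-related beta
  desynchronisation.
* **Gamma / high-gamma bursts** — Hann-windowed sinusoid packets
  confined to the 1--3 s window. Carrier frequencies are drawn
  uniformly inside the band shrunk by a 2 Hz margin so that a packet's
  spectral main lobe stays in-band (tested: at least 80% of burst power
  falls inside 30--48 Hz). Per trial, a random subset of parcels is
  "active"; the subset size is Poisson around a participant-level mean.
* **Group effect** — ALS participants draw both more active regions
  (gamma: 20 vs 7 on average; high-gamma: 34 vs 17) and longer burst
  durations (0.9 vs 0.5 s), mirroring the qualitative description of
  patient activations as high-power, long-duration and spatially
  extensive. Burst amplitude (2.0 noise-SD units for gamma) was chosen
  once so that bursts are reliably suprathreshold — the regime the
  threshold rule presupposes — and is not otherwise tuned.
* **Clinical covariates** — ages, sexes, ALSFRS-R, symptom duration,
  ECAS, UMN and NfL drawn to roughly match the cohort marginals of the
  study population (e.g. ages near 61 in both groups, ALSFRS-R around
  39). The ALSFRS-R progression rate is generated as
  `0.4 + slope * z(latent spread) + noise` with `slope = 0.15`
  points/month per SD and residual SD 0.25 (total SD ~0.3, matching the
  cohort), then ALSFRS-R is back-derived from the drawn duration so the
  identity `rate = (48 - ALSFRS_R) / duration` holds exactly. A
  fine-motor sub-score (two 0--4 items) is planted with a negative
  latent-spread correlation.
* **Behaviour** — grip length, grip strength (12 N target), reaction
  time and accuracy drawn from identical distributions in both groups
  (a true null), with an optional SD-unit shift for power checks.

Every participant's stream derives from the master seed via a
counter-based substream hash (`substream_seed()`), so cohorts are
bit-reproducible and individual participants can be regenerated.

What the generator does **not** emulate: inter-regional correlation
structure (parcels are independent), non-sinusoidal burst morphology,
heteroscedastic noise across regions, artifacts, or any sensor-space /
forward-model physics. Passing tests therefore demonstrate the
correctness and calibration of the *analysis*, not the physiological
realism of the signals.

## Spectral decomposition

`compute_tfr()` uses complex Morlet wavelets on a 2 Hz grid anchored at
13 Hz, excluding the 48--52 Hz mains gap. Cycle counts default to `f/2`
clipped to `[4, 24]`, i.e. an approximately constant 2 Hz spectral
bandwidth matched to the grid pitch. The constant-bandwidth choice is
what makes the mains gap meaningful: with cycles capped at 12, the
spectral SD at 47 Hz is ~3.9 Hz and a 50 Hz line would leak over 20% of
an in-band response into the gamma band; with `f/2` cycles the measured
leakage is ~7% (tested against a <10% bound). Epochs are analysed with
0.5 s of padding on each side — real signal where the simulator
provides it, reflection otherwise — and trimmed, so wavelet edge
artifacts never reach the -1..5 s window.

Baseline correction is percent change relative to pre-trigger power in
[-0.8, -0.1) s (half-open, i.e. exactly seven 100 ms bins; the window
avoids both the epoch edge and anticipatory activity — the upstream
study does not publish its window, so this is a declared, configurable
default). Two numerical choices deserve emphasis:

* **Denominator pooling.** `compute_band_power()` defaults to
  `baseline_stat = "average"`: the baseline mean is pooled over trials
  per region x frequency before dividing. A single-trial 0.7 s baseline
  estimate has a coefficient of variation near 45% at gamma, and
  dividing by it inflates every out-of-baseline bin by a Jensen bias
  (~+0.19 in simulation) while leaving baseline bins pinned at zero —
  a bimodal structure that would wreck the Gaussian-tail calibration
  below. Pooling the denominator removes the bias; the strict
  single-trial form of the operation remains available
  (`baseline_stat = "trial"`, or `baseline_correct()` at sample level)
  and the two paths agree to machine precision on binned output.
* **Binning.** Band power is averaged over the band's grid points
  (edges inclusive) and over the samples of consecutive 100 ms bins
  tiling the epoch (60 bins for a 6 s trial). Binning is linear and
  commutes with the baseline division, which is what allows the
  memory-bounded chunked implementation.

## Activation thresholds, spread and GAS

`calibrate_thresholds()` pools, for each region x band, the healthy
controls' trial-averaged bin values over the full epoch and sets
activation/deactivation cut-offs at the pooled mean +/- 2 pooled sample
SDs (denominator n-1; the multiplier is configurable). Binarization is
strict (`>` upper, `<` lower; values exactly on a threshold are
neutral), so a degenerate `sd = 0` calibration yields all-neutral
states rather than an error.

The tested default scores the **trial-averaged** power course against
these thresholds. The alternative — binarizing every single trial and
averaging the counts — is supported (calibrate with `level = "trial"`
and pass per-trial band power), but it is not the default for a
calibration reason: thresholds derived from trial-averaged values sit
at +/- 2 SD of the *averaged* distribution, and applying them to raw
trials (whose SD is ~sqrt(n_trials) larger) would fire on ~40% of
noise-only cells per tail rather than the nominal 2.3%. With the
default pairing, the false-activation rate of noise-only control data
scored against its own calibration matches the Gaussian tail
Phi(-2) = 2.28% within one percentage point (tested at 120 trials; with
far fewer trials the skewness of averaged power begins to show).

`spread_timeseries()` counts activated and deactivated regions per band
and bin (averaging over whatever trial dimension remains), and
`compute_gas()` takes the mean activated count over the bins whose
centers fall in the closed window [1, 3] s — 20 bins at the default
pitch; the bin-center rule is explicit because the window endpoints are
edge-sensitive. The same function with `band = "high_gamma"` gives the
high-gamma analogue.

## Inference

Group contrasts and clinical associations use ordinary least squares
with a single-coefficient contrast and permutation inference
(`permutation_test()`), default scheme Freedman--Lane: the outcome is
residualised on the confound columns, residual rows are permuted with
the confound fit held in place, and the full model is refit. P values
are `(1 + #{|t*| >= |t|}) / (1 + n_perm)`; when `n!` does not exceed
20,000 the test switches to exhaustive enumeration and p values are
exact (verified against Monte-Carlo sampling on n = 7 designs).
Family-wise error across the declared family — all bands x bins x
{activated, deactivated} plus the GAS scalars in a group contrast — is
controlled by the permutation distribution of the maximum |t|, the
standard permutation-native correction; its realised FWE on null data
is ~0.05 (tested over 500 simulated datasets). Tests are two-sided
throughout.

Designs contain an intercept, the predictor (group indicator or GAS),
and mean-centered confounds (age, sex as a male indicator, missing-MRI
flag). Confounds that are constant or collinear in a given cohort are
dropped with a message rather than failing the fit. Outcomes with
numerically zero residual variance get a capped, flagged t; constant
outcomes yield t = 0 and p = 1. Clinical associations model
`score ~ GAS + age + sex` within the ALS group, one family per outcome
with no cross-outcome correction (the convention adopted here; the
upstream description is ambiguous between score-on-GAS and
GAS-on-score).

Behavioural metrics are compared with Welch's unequal-variance t test —
available in a summary-statistic form (`welch_from_summaries()`) that
is algebraically identical to the vector form and can be applied
directly to published cohort tables — Bonferroni-corrected over the
four-metric family.

## Validation suite and problem sizes

The package's acceptance checks, all generated in code at test time:

* the published cohort age comparison recomputed from summary
  statistics (t = 0.214 vs the printed 0.21);
* noise-only calibration tails within 2.3 +/- 1.0% per tail
  (8 controls x 10 regions x 120 trials at 200 Hz, gamma band);
* family-wise error of the max-statistic test <= 0.05 + 3 Monte-Carlo
  SE over 500 null datasets (n = 24, 100-element family, 500
  permutations);
* exhaustive-vs-sampled permutation agreement on n = 7 designs and
  hand-counted spread on toy activation maps;
* recovery of the planted group effect: with ~20 vs ~7 active gamma
  regions (10 participants per group, 52 regions, 8 trials per
  participant at 200 Hz to keep the suite fast), the group GAS
  separation exceeds 5 regions and the significant bins concentrate in
  the 1--3 s window in at least 19 of 20 seeds; the planted
  GAS-progression slope is recovered with the correct sign at n = 42
  while the slope-zero null yields uniform permutation p values
  (Kolmogorov--Smirnov over 200 seeds);
* byte-identical CSV outputs across pipeline reruns with the same
  configuration and seed.

These sizes are validation choices: they are large enough for the
stated tolerances (Monte-Carlo SEs are quoted in the tests) and small
enough that the whole suite runs in a few minutes.

## Known limitations

* Thresholds are calibrated on the full epoch, so strong task activity
  in controls slightly inflates the pooled SD and makes thresholds
  conservative; calibrating on pre-trigger bins only is a one-line
  change (`calibrate_thresholds` on a bin-subset of the band power) but
  is not the default.
* The ALS-vs-HC difference in measured GAS exceeds the planted
  active-region difference because longer patient bursts also raise
  within-window coverage; the generator plants a *qualitative* effect,
  not a calibrated GAS value.
* Parcels are simulated independently, so the suite cannot detect
  errors that only manifest under realistic spatial correlation.
* No burst-level segmentation (onsets, durations), no longitudinal
  modelling, and no sensor-space processing: the pipeline starts at
  parcel time courses.
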