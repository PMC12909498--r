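---
title: "Short-segment multimodal fatigue detection: models and methods"
author: "fatigueFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-segment multimodal fatigue detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatigueFusion)
```

## The problem

Operator (e.g. pilot) fatigue degrades reaction time and decision making,
and self-report is unreliable. A practical pre-duty screen must decide
"alert vs fatigued" from a short physiological recording. This package
implements such a screen from two modalities recorded simultaneously:

* **EEG** — 16 scalp channels (10-20 subset: FP1/FP2, F3/F4, F7/F8, C3/C4,
  T3/T4, T5/T6, P3/P4, O1/O2) at 500 Hz. Fatigue shifts band power:
  slow-wave (delta 0.5-4 Hz, theta 4-8 Hz) activity rises broadly, alpha
  (8-13 Hz) rises over visual (occipital) cortex as vigilance declines,
  and beta (13-30 Hz) responds inconsistently.
* **ECG** — one channel at 250 Hz. Classical frequency-domain heart-rate
  variability needs several minutes of signal and is unusable in 2-s
  windows, so the pipeline instead uses raw-waveform statistical moments
  (dispersion, extremes, skewness, kurtosis) as short-window proxies for
  autonomic change.

Each 2-s window of the synchronized pair is one classification sample.

## Pipeline

1. **Preprocess** — 0.5-30 Hz zero-phase band-pass (4th-order Butterworth
   applied as its squared-magnitude response on the FFT grid), brick-wall
   FFT decomposition of the EEG into the four bands, timestamp alignment
   of the two devices, and sliding-window segmentation (2-s windows, 1-s
   step). A 600-s recording yields `floor((600 - 2)/1) + 1 = 599` epochs.
2. **Features** — per epoch: 8 features per (channel, band) — mean, energy,
   variance, RMS from the band signal; band PSD, centroid frequency,
   frequency variance and mean-square frequency from the epoch
   periodogram restricted to the band — plus 7 ECG moments. Full width:
   16 x 4 x 8 + 7 = 519. Features are z-scored per subject (both states
   pooled) to remove baseline differences between individuals.
3. **Selection** — stage one: per-feature one-way ANOVA (alert vs
   fatigue, p < 0.01); an EEG feature *type* survives only if it is
   significant on at least `minChannels = 10` channels in *every* band,
   each ECG feature survives on its own p-value. Stage two: one linear
   soft-margin SVM per channel on that channel's surviving features; the
   mean out-of-fold AUC of its decision scores ranks the channels, and
   the top 8 are kept.
4. **Classification** — gradient-boosted trees (100 trees, depth 6,
   learning rate 0.1, logistic loss with leaf-count and L2 leaf-weight
   penalties) on the fused EEG + ECG feature set, evaluated under
   *cross-clip* (epoch-shuffled stratified folds) and *cross-subject*
   (subject-disjoint folds, repeated with re-randomized groupings)
   cross-validation.

## Statistical choices worth knowing

**Population moments everywhere.** The time-domain identities
`RMS^2 = VAR + MEA^2` and `ENE = N * RMS^2` hold exactly only under the
divide-by-N convention, so variance, SD, skewness (Fisher-Pearson g1) and
kurtosis (excess g2; Gaussian gives 0) all use population conventions.
Kurtosis conventions differ across software; comparisons with other
toolboxes must use the excess form.

**AUC from rank sums.** The per-channel AUC is computed as
`(sum of positive midranks - T(T+1)/2) / (T*F)` — the Mann-Whitney
statistic, equal to the probability that a random fatigue epoch scores
above a random alert epoch, with ties counted half. The SVM's signed
decision values (not hard labels) are the scores; orientation is fixed so
that higher means fatigue.

**ANOVA at nominal level needs exchangeable epochs.** Overlapping epochs
share half their samples, so their features are autocorrelated and the
two-group F-test rejects more often than its nominal level even under the
null (empirically ~0.07 at alpha = 0.01 with 50% overlap). The package's
null-calibration checks therefore run with non-overlapping epochs
(step = window), where the empirical level matches the nominal one. On
real screening data the overlap acts as data augmentation for the
classifier; the ANOVA stage there is a heuristic filter, not a calibrated
test — the same caveat the multiple-comparison-free design already
carries. An optional Benjamini-Hochberg adjustment is available
(`anovaScreen(..., adjust = "BH")`).

**Leakage policy.** Whole-dataset ("global") feature selection before
cross-validation leaks test information into the selected set and inflates
cross-clip estimates. `runPipeline()` therefore re-runs the entire
selection stage inside every training fold by default; the
`global_selection = TRUE` flag reproduces the global-selection protocol for
comparison.

**Degenerate inputs.** Zero in-band power makes CF/FV/MSF 0/0; they are
emitted as 0 with a warning. Constant segments get SKEW = KURT = 0 with a
warning; zero-variance features within a subject z-score to 0. Undefined
precision/recall (empty denominators) are reported as `NA`, never 0.
`FV = MSF - CF^2` is clamped at 0 against floating-point negatives.

## The synthetic cohort generator

The study's real cohort is not publicly deposited, so the package ships a
seeded generator that emulates its structure: paired alert/fatigue
recordings per subject, 10 min per state, 500/250 Hz.

Each EEG channel is a sum of four band-limited Gaussian oscillations
(white noise brick-wall filtered to each band) plus broadband noise —
band-limited noise rather than sinusoids, because pure tones make the
spectral-spread features degenerate. Oscillation RMS amplitudes are
per-subject log-normal baselines (positive, multiplicatively variable —
the very heterogeneity that motivates per-subject z-scoring) times a
state multiplier, so band *power* scales as the multiplier squared. A
fraction `spatialCorrelation = 0.6` of each band oscillation's variance is
shared across channels, mimicking volume conduction; without it, 16
independent channels would make the cohort near-perfectly separable at
any per-channel effect size, which real scalp data never is. The ECG is a
train of Gaussian-bump PQRST-like beats with Gaussian RR jitter; fatigue
multiplies the RR standard deviation and skews the T-analogue bump.

Randomness flows through a seed ladder (master seed, then per-subject,
per-state, per-modality substreams), so enlarging a cohort never perturbs
existing subjects, and identical specs reproduce byte-identical signals.

**Default effects.** The literature gives directions but not magnitudes,
and the defaults are calibrated once so that the full pipeline separates
the states at roughly 90% cross-subject accuracy — clearly learnable but
far from trivial: delta x1.12 globally, theta x1.07 globally (x1.12
frontal/parietal), alpha x1.07 frontal/parietal and x1.26 occipital,
beta x0.92 globally; RR-SD x1.3 and T-bump skew +0.25. Beta is given a
mild global *decrease* (one of the two responses reported in the
literature) and theta a global rise: with an entirely null band the
retention rule "significant on 10+ channels in every band" could retain
nothing, which is a property of the rule, not of the data.

**What the generator does not emulate.** Amplitude multipliers cannot move
the scale-invariant spectral-shape features (CF, FV, MSF), so under the
synthetic model the retained EEG feature types are the four
amplitude-sensitive ones (ENE, VAR, RMS, PSD); on real recordings, where
fatigue also shifts spectral shape within bands, six types survive.
Likewise absent: 1/f background, ocular and movement artifacts (real
recordings deliberately keep blinks as fatigue markers), non-stationary
drifts, and realistic ECG morphology beyond moment control. Passing tests
demonstrate that the *pipeline machinery* recovers known injected
effects under realistic noise, correlation and baseline heterogeneity —
not that the classifier would reach any particular accuracy on real
pilots.

## Problem sizes used by the test-suite and acceptance runs

Structural counts use the full protocol geometry (one 600-s pair; a
32-subject x 2-state x 600-s cohort = 38,336 epochs). Statistical
properties use deliberately smaller cohorts — 4-8 subjects at 40-120 s
per state, 20 seeds for the property sweeps, and two 6-subject cohorts
for null calibration — chosen to keep each property estimate stable (its
Monte-Carlo error well inside the asserted band) at desk scale. The
reported headline accuracies of the package's own runs come from an
8-subject x 120-s cohort under global selection.

## Known limitations

* The generator's fatigue effect is purely multiplicative in band
  amplitude and homogeneous across subjects; subject-specific effect
  directions (reported for beta) are not modelled.
* The retention rule's "every band" quantifier makes the EEG stage brittle
  when a band is truly unaffected; `minChannels` is exposed for that
  reason.
* Mean AUC near 1 compresses ranking differences; with very strong
  injected effects channel recovery saturates rather than sharpens.
* EDF support covers the plain continuous 16-bit subset this package
  writes; EDF+ annotations and per-signal rates are out of scope.
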