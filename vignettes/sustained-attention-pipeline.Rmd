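---
title: "Methods: simulating and classifying sustained-attention EEG under chronic hypoxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying sustained-attention EEG under chronic hypoxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chronic exposure to high altitude changes how the brain sustains attention.
In a Go/No-Go sustained attention task (frequent Go stimuli requiring a
button press, rare No-Go stimuli requiring response withholding, over about
an hour of testing), high-altitude (HA) immigrants and low-altitude (LA)
controls differ in behavioral vigilance (omission errors), in the
sustained potential (SP) — a slow stimulus-locked ERP deflection read at a
centro-parietal channel in the 460–700 ms window — and in post-stimulus
band-power changes (event-related spectral perturbation, ERSP) in the
theta, slow-alpha, fast-alpha and beta bands. Those differences are large
enough that a classifier over SP and ERSP features can discriminate the
two groups.

`gsatpipe` packages that entire analysis as reusable, seeded code:
a synthetic cohort generator (human EEG of this kind is rarely
redistributable, so every downstream stage must be testable without a
download), single-channel preprocessing, the 36-feature extraction,
dual-method feature selection, and leave-one-out classifier evaluation.

## The synthetic cohort generator

`cohort_config()` fixes the study design: 35 HA + 32 LA participants, nine
blocks of 222 trials (198 Go, 24 No-Go), 600 ms stimuli with a 1500 ms
inter-stimulus interval (onsets therefore every 2100 ms), 500 Hz sampling
at a single "CPZ" channel. Blocks map onto three task periods a1/a2/a3
(early/middle/late thirds). No-Go trials split evenly into incongruent
No-Go and repeat No-Go; a repeat No-Go always directly follows a congruent
Go trial with the identical stimulus, which is what makes it a "repeat".
The even subtype split is a configurable default — the emulated study does
not state proportions.

The signal model at the analysis channel is additive:

* **SP component** — one Gaussian bump per trial (SD 60 ms; any smooth
  unimodal shape satisfies the feature definitions). Peak latency and
  amplitude are drawn around group × stimulus-type × period means with
  between-subject and trial-to-trial variability. Latency means pool to
  531.51/538.57/528.14 ms (HA) vs. 579.63/560.97/565.97 ms (LA) across
  periods, with Go peaking ~66 ms before No-Go (applied as a ±33 ms type
  offset); amplitudes run ~5–7 µV (Go) and ~11–15 µV (No-Go). The
  between-subject SDs (45 ms, 3 µV) are back-calculated from the reported
  group standard errors at n = 35.
* **Oscillations** — four band-limited noise components exactly tiling the
  4–30 Hz analysis range (theta 4–8, slow alpha 8–10.5, fast alpha
  10.5–13, beta 13–30 Hz). Each trial multiplies each component by a gain
  `10^(dB/20)` over 330–830 ms post-onset, so the measured ERSP offset in
  the 460–700 ms feature window equals the configured dB table (group ×
  band × type × period, with HA showing stronger theta and weaker
  alpha/beta desynchronization). The gain interval is wider than the
  feature window by design: every STFT frame contributing to 460–700 ms
  lies fully inside it, while all baseline frames lie fully outside.
* **Background** — 1/f noise confined below 4 Hz. Confining the broadband
  background below the lowest analysis band means each band's measured
  power is carried by its own component, so the multiplicative gains map
  onto ERSP dB exactly rather than being diluted by in-band background.
* **Behavior** — Go trials are missed with group × period probabilities
  consistent with the emulated study's marginals (HA ≈ 1.3–1.5%, LA ≈
  3.3–4.4%); responded trials draw reaction times from N(461.6/431.5/426.5
  ms, 85 ms) per period, truncated at 150 ms. Responses on No-Go trials
  (commission errors) are not modeled; the downstream behavioral summary
  reads omissions and Go reaction times only.

Determinism: every participant gets a sub-seed derived arithmetically from
the master seed, so cohorts are bit-reproducible and participants never
share noise. All five noise components of one recording are carved from
disjoint frequency bands of a single white-noise spectrum — disjoint bands
of a Gaussian process are independent, so this equals five independent
draws at a fifth of the FFT cost.

What the generator deliberately does **not** emulate: ocular/muscle
artifacts beyond amplitude outliers (so the 100 µV screen rejects almost
nothing on clean synthetic data), multi-channel topographies, inter-block
rest breaks, commission errors, and any nonstationarity beyond the
configured period effects. Passing tests on synthetic cohorts therefore
demonstrate that the *analysis machinery* is correct and that configured
effects are recoverable — not that real EEG of this population would yield
the same classification numbers.

## Preprocessing

Epochs span [−200, 1000) ms around each onset (600 samples at 500 Hz; the
onset lands at sample index `round(0.2·fs)`, 0-based, half-open windows
throughout). Baseline correction subtracts the mean of [−200, 0) ms;
artifact screening rejects an epoch iff its absolute amplitude *strictly*
exceeds 100 µV after baseline correction (an excursion of exactly 100 µV
is kept). The emulated protocol also mentions a 200 µV ocular criterion on
EOG channels; with a single synthetic channel and no ocular model, the
single 100 µV screen is the whole artifact story — a documented fidelity
gap. An optional zero-phase 0.1–30 Hz Butterworth band-pass
(forward–backward, so the SP latency — a headline feature — is not
shifted) is available for data that is not already band-limited; it
defaults to off because the generator is.

ERPs are pointwise means over accepted epochs, with both No-Go subtypes
pooled into a single No-Go class, per condition × period.

## Features

**Time domain (12).** Over the inclusive [460, 700] ms window (121 samples
at 500 Hz), per condition: peak latency (argmax of the waveform, earliest
tie wins), mean amplitude, total area (the plain sample sum, in
µV·samples, so `area = mean × 121` exactly), latency/mean ratio, |mean|,
and |latency/mean|. A zero mean amplitude makes the ratios undefined; they
propagate as missing values and are median-imputed before selection rather
than crashing the run.

**Time–frequency (24).** Per-trial Hann STFT, power averaged across trials,
converted to 10·log10 dB (power floored at 1e−20), minus the per-frequency
mean log power of the baseline frames — the standard ERSP construction.
The alternative order (log first, then average across trials) is available
via `average_domain = "log"` because the textual description of such
pipelines is often ambiguous on this point; the power-domain average is
the default. Per band × condition: mean dB over the window's frame × bin
cells, the max over frames of the per-frame band mean, and that maximum's
frame time (earliest tie). `max ≥ mean` holds by construction.

Numerical conventions worth stating once:

* STFT frames are 250 ms Hann windows hopped every 20 ms, centers aligned
  to hop multiples relative to stimulus onset (so 460, 600, 700 ms are
  exact frame timestamps), and frames extending past either epoch edge are
  dropped. The window length is a compromise forced by the epoch: frames
  must fit inside [−200, 1000) ms *and* at least one frame center must
  fall in the [−200, 0) baseline — a 500 ms window would leave no valid
  baseline frame. 250 ms gives three baseline frames at the cost of ~4 Hz
  spectral resolution, which blurs narrow neighboring bands (slow vs. fast
  alpha) into each other; band effects survive but attenuated. This is the
  familiar time–frequency trade-off of short-epoch ERSP, not a removable
  implementation detail.
* The frequency grid is zero-padded to 0.5 Hz spacing by default (≥ 5 bins
  in the narrowest band); a 0.1 Hz grid is one argument away
  (`freq_res = 0.1`) and changes band features negligibly while costing
  5× the FFT work, which matters at cohort scale.
* Band intervals are half-open [lo, hi) so slow and fast alpha never share
  a bin; the 30 Hz beta edge is inclusive, matching the 30 Hz low-pass
  ceiling.

## Feature selection

Features are min–max normalized to [0, 1] per column (constant columns map
to 0), then ranked twice:

* **ReliefF** with all samples as anchors (no random sampling —
  deterministic) and k = 10 neighbors under the Manhattan distance on
  range-normalized features. The weight of a feature is the mean over
  anchors of (mean |diff| to the k nearest misses − mean |diff| to the k
  nearest hits). k is clamped to (smallest class − 1) inside
  `evaluate_all()` so reduced cohorts run; a direct call with an
  infeasible k errors.
* **GainRatio** with C4.5-style binary discretization: the threshold
  maximizing information gain over midpoints of consecutive distinct
  values, gain then divided by the split information of that partition
  (defined 0 for constant features).

The selected subset is the intersection of the two top-18 lists, ordered
by ReliefF rank; an empty intersection raises an error suggesting a larger
k. Ties in either ranking break by ascending feature name, so rankings are
reproducible.

By default, selection happens once on the full table before
cross-validation, mirroring the sequential description of such analyses.
That leaks label information into the folds and biases accuracy upward;
`selection_scope = "per_fold"` re-runs normalization and selection inside
every training fold and is the mode to use when the metrics are meant as
estimates of out-of-sample performance.

## Classifiers and evaluation

Three classifiers, evaluated by leave-one-out cross-validation with HA as
the positive class: a linear SVM (cost 1 — a sensible small-n default for
~11 selected features; RBF is configurable), logistic regression (the
standard sigmoid model, maximum-likelihood fit), and a CART decision tree
with the Gini criterion. The tree uses `minsplit = 5`, `minbucket = 2`:
training folds hold ~66 rows, and rpart's default `minsplit = 20` would
nearly forbid splitting. All three are deterministic, so the whole report
is reproducible byte for byte.

Reported per classifier × period: the confusion matrix, accuracy,
precision/sensitivity/specificity, F1, a Wald 95% CI on accuracy
(`p ± 1.96·sqrt(p(1−p)/n)`, clipped to [0, 1]), the full ROC curve over
score thresholds, and the AUC as the Mann–Whitney probability with midrank
tie handling. One arithmetic subtlety: intervals printed next to
two-decimal accuracies are reproduced by feeding the *rounded* accuracy to
the Wald formula (92.54% on n = 67 → 86.25–98.83%), while the raw count
62/67 gives 86.24% — the package exposes both `wald_ci(p, n)` and
`accuracy_ci(n_correct, n)` so either convention is explicit.

A published table this analysis mirrors reports one decision-tree F1
(0.68 in the middle period) that is inconsistent with the confusion matrix
implied by its own printed sensitivity/specificity (which give ≈ 0.74);
the package computes F1 from its definition and makes no attempt to
reproduce internally inconsistent numbers.

## Reduced-scale simulation studies

Simulation tests and the acceptance run use `reduced_config()`: one block
per period, 74 trials per block (66 Go + 8 No-Go) — one ninth of the full
design. Scaling trials down without touching noise would misrepresent the
emulated study: a 66-trial ERP has three times the residual noise of a
594-trial ERP, and peak-latency estimates degrade accordingly. The
miniature therefore divides the stochastic per-trial components
(background RMS, band RMS, trial-level latency/amplitude jitter) by
`sqrt(9) = 3`, preserving the averaged-ERP signal-to-noise ratio and hence
the measured-feature distributions of the full design. Between-subject
variability and all group effects stay untouched. ERSP estimation noise,
which is governed by trial *count* rather than amplitude (power ratios are
scale-free), remains larger than at full scale; time–frequency features
are accordingly noisier in the miniature, which the simulation tolerances
acknowledge.

Problem sizes used by the simulation suite, chosen as the smallest that
leave the tested effects clearly powered: latency-sign recovery runs at
the emulated group sizes (35 + 32; between-subject SD of 45 ms against a
48 ms group difference is only reliably detectable near full n — the
emulated study was powered, and an honest miniature must be too);
selection-majority runs at 16 + 16; the strong-effect positive control
(`strong_effect_config()`, which triples the group-mean separations) at
10 + 10; each over 20 seeds.

## Known limitations

* Single-channel: no topography, re-referencing, or channel interpolation.
* The ERSP leakage discussed above means configured band offsets are
  recovered attenuated and partially mixed between adjacent bands; tests
  assert signs and calibrated magnitudes, not exact dB equality.
* Full-dataset selection (the default, for fidelity) overstates LOOCV
  accuracy; use per-fold selection for honest estimates.
* The behavioral model is minimal (Bernoulli omissions, Gaussian RTs);
  it supports rate/mean recovery checks, not RT-distribution research.
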