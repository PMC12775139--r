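---
title: "Frustration-aware motor-imagery decoding: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frustration-aware motor-imagery decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frustbci)
```

## The problem

A motor-imagery (MI) brain–computer interface decodes imagined left- versus
right-hand movement from multichannel EEG. The discriminative signal is
event-related desynchronization (ERD): a power drop of the mu (~10 Hz) and
beta (~20 Hz) sensorimotor rhythms over the hemisphere contralateral to the
imagined hand (C4 for left-hand imagery, C3 for right-hand). MI decoders
are calibrated once and then assumed stationary — but the user's mental
state is not. Frustration, induced when feedback repeatedly contradicts the
user's intent, changes band power and topography enough to degrade a
decoder trained in a calmer state.

`frustbci` implements a two-decoder architecture: a *passive* BCI estimates
the user's frustration level (low / mid / high, induced experimentally by
clamping task success at 80% / 65% / 50%), and an *active* BCI decodes MI
with one model per frustration state. Three decision strategies combine
them:

* **Method 1 (hard switching).** The state classifier's probability vector
  $p_f = [p_0, p_1, p_2]$ selects one MI model:
  $\hat s = \arg\max p_f$, $\hat y = \arg\max \mathcal M_{\hat s}(X)$.
* **Method 2 (probabilistic fusion).** All three MI outputs are mixed by
  the state probabilities:
  $p^{\mathrm{MI}}_{\mathrm{final}} = \sum_{i=0}^{2} p_i\,\mathcal M_i(X)$,
  $\hat y = \arg\max p^{\mathrm{MI}}_{\mathrm{final}}$. This is soft
  voting; it is 1-Lipschitz in $p_f$ and coincides with Method 1 whenever
  $\max p_f = 1$.
* **Method 3 (state-agnostic baselines).** A single model ignores the
  state: variant 3-1 pools the frustration-stage data, variant 3-2 uses
  only the stage-1 calibration data.

Ties are resolved deterministically: equal state probabilities go to the
lowest state index, equal MI probabilities to `left`.

## Feature extraction

Both decoders use filter-bank common spatial patterns (FBCSP). Windows are
band-filtered through nine 4 Hz bands spanning 4–40 Hz (the canonical
layout; configurable via `filter_bank_spec()`). Per band, CSP solves the
generalized eigenproblem
$\Sigma_A w = \lambda (\Sigma_A + \Sigma_B) w$
on trace-normalized average class covariances; for the 3-class frustration
problem CSP is fitted one-vs-rest per class and features are concatenated.
Class covariances are regularized by analytic shrinkage toward a scaled
identity, with intensity estimated from the dispersion of the per-window
covariances — 3 s windows over up to 64 channels make raw covariances
ill-conditioned, and the estimator degrades gracefully to no shrinkage when
data are plentiful. Features are the normalized log variances
$f_j = \log\!\big(\mathrm{var}(w_j^\top X) \big/ \sum_k \mathrm{var}(w_k^\top X)\big)$,
ranked by plug-in mutual information with the label on 4-bin quantile
discretizations (MIBIF; ties break toward lower feature index) and kept
with CSP pair-completion so each retained filter's partner is retained too.
Defaults: $m = 2$ filter pairs per band, `k_select = 4` features before
completion; both configurable.

## Classifiers and probability calibration

The default backend is an RBF-kernel SVM (`e1071`/libsvm) with cost 1 and
$\gamma = 1/(d \cdot \overline{\mathrm{var}})$ on standardized features.
The fusion laws need *probabilities*, so decision values are calibrated by
a Platt sigmoid fitted on stratified 3-fold cross-validated decision values,
with Wu–Lin–Weng pairwise coupling for the 3-class problem. The calibration
is implemented in the package rather than taken from libsvm's
`probability = TRUE`, for one reason: libsvm shuffles its internal
calibration folds with the C library's `rand()`, which R's seed does not
control, and this package treats bit-reproducibility under a fixed seed as
a contract. The alternative backend is linear discriminant analysis with a
Ledoit–Wolf-shrunk pooled covariance; `backend = "auto"` picks the more
accurate of the two by an inner stratified 5-fold comparison on training
data only, with ties going to the SVM.

## Evaluation protocol

Analysis windows are 3000 samples long with a step of 100 samples (at the
nominal 1000 Hz sampling rate), cut strictly within trials after
preprocessing — per-channel mean removal, a zero-phase biquad notch at
50 Hz (Q = 30), and a zero-phase 4th-order Butterworth bandpass at 1–40 Hz,
in that order. Stage-2 analysis epochs start 0.5 s after ball-movement
onset by default (`epoch_offset_s`). With ~97% overlap, adjacent windows
are nearly identical, so cross-validation folds partition *trials*, never
windows; `crossval()` enforces this leakage guard, and a test demonstrates
that a label-memorizing pipeline scores at chance under the guard and near
100% without it. Accuracies are window-level by default (trial-level
majority voting is available via `fuse(aggregate = "trial")`). Cohort
tables report the arithmetic mean and the population (divide-by-$n$)
standard deviation, rounded to two decimals.

Spectral statistics use Welch's method (1 s Hann segments, 50% overlap,
one-sided density scaling). Band powers integrate the PSD over Delta
(1–4), Theta (4–8), Alpha (8–12), Beta (12–30) and Gamma (30–45 Hz);
group comparisons use pooled-variance two-sample t tests with the sign
convention $t = (\bar x_A - \bar x_B)/\mathrm{se}$, reported per band
without multiple-testing correction (a Bonferroni flag would be a caller's
one-liner; the raw per-band values match how such panels are usually
shown).

## The synthetic cohort generator

Real frustration-BCI recordings are not bundled with the package, so the
generator is first-class, tested code that emulates the statistical
structure the pipeline assumes — and only that structure:

* **Background.** Independent $1/f$ noise per channel (9 µV RMS), plus an
  occipital alpha rhythm at Oz.
* **MI signature.** Two sensorimotor sources (mu + beta oscillations)
  project to C3 and C4; imagining the left hand attenuates the
  right-hemisphere source's power by `mi_erd_depth` (default 0.5), and
  vice versa.
* **State signature.** A key constraint drove this design: normalized
  log-variance CSP features are invariant to spatially *uniform* power
  gains, so a frustration effect expressed as a global band-power change
  would be undecodable by this pipeline — as it would be for FBCSP on real
  data. The generator therefore gives each state a distinct spatial
  pattern, mirroring the band/topography structure reported for
  frustration studies: beta/gamma broadband gains (defaults 1/1.3/1.6 and
  1/1.35/1.65 for low/mid/high) act on the central channels only; a 2–8 Hz
  component is strongest at C3/C4 under low frustration and strongest at
  Oz under high; a frontal-midline 6 Hz theta oscillation at Cz grows with
  frustration; occipital alpha is mildly suppressed under high
  frustration.
* **State-dependent MI.** Frustration degrades the ERD contrast
  (scale 1/0.85/0.7) and rotates the two sensorimotor sources within the
  C3/C4 plane by 0°/60°/120°. The rotation is what makes state-specific
  models genuinely better than a pooled one: a pooled decoder must
  compromise across discriminative directions up to 120° apart, while each
  per-state model sees a fixed mixing it can invert. A smaller spread
  (tens of degrees) lets the pooled model's 3× larger training set win,
  which contradicts the phenomenology the generator exists to emulate.
* **Protocol.** Feedback outcomes are Bernoulli draws at the condition's
  success rate (0.80/0.65/0.50); Likert ratings are normal draws with
  means 2.1/3.5/4.8 and SDs 0.8/1.4/1.2, rounded and clipped to 1..7.

Amplitudes were calibrated once so that the default cohort lands in the
reported accuracy regime (frustration decoding in the mid-80s, specialized
MI decoding from the 50s under high frustration to the 80s under low) and
were then frozen. What passing tests on this cohort do **not** show: the
generator has no artifacts (EOG/EMG), no volume-conduction mixing from a
head model, no within-session non-stationarity, and frustration affects
trials from their first sample. Results on real recordings depend on all
of these.

Every draw derives from one master seed through fixed per-subject
substreams, so cohorts are bit-reproducible and subjects are independent.

## Numerical choices and degenerate inputs

* Filters are applied forward–backward (zero phase); the bandpass is a
  4-pole Butterworth (two poles per edge), numerically safer near the
  1 Hz edge at 1000 Hz than higher-order designs.
* The CSP eigenproblem is solved by whitening with the composite
  covariance; filters are sign-fixed (largest coefficient positive) for
  reproducibility. A composite covariance that stays rank-deficient after
  shrinkage raises an error advising stronger regularization rather than
  returning unstable filters.
* Zero-variance projections (flat windows) and never-predicted classes are
  reported as explicit errors or flagged `NA`s, never silent `NaN`s.
* Degenerate paired tests are handled as documented: identical vectors
  give $t = 0, p = 1$; a noise-free constant shift gives $|t| = \infty,
  p = 0$; the Wilcoxon statistic is flagged rather than computed when all
  differences vanish.
* In `separability_metrics()`, zero within-class spread makes Fisher's
  ratio infinite; the result is flagged `separated` and the linear probe
  falls back to nearest-centroid.

## Problem sizes

The bundled test-suite and the acceptance script exercise the full loop at
12 simulated subjects, 4 channels (C3, Cz, C4, Oz), 1000 Hz, 4 s trials,
12 trials per state and hand in stage 2 (24 per state) and 24 calibration
trials per hand — the scale at which a 5-fold, per-subject, multi-model
study remains a few minutes of computation. Trial counts are the one knob
the protocol leaves open (the generator's own default is 30 per state and
hand); channel count, rate, windowing and the induction design follow the
study conditions.

## Known limitations

* Stage-2 windows do not exclude the feedback (success/failure) period;
  the configurable epoch offset is the only temporal gate.
* Per-task (frustration vs MI) feature selection is independent; no
  attempt is made to share filters across tasks.
* The fusion layer adapts nothing over time. An optional entropy gate
  (`fuse(entropy_fallback = )`) can divert highly uncertain state
  predictions to the pooled model, but it is off by default — the default
  behavior is the pure three-strategy design.
* Online use (incremental updates, artifact handling, latency) is not
  addressed; the package is an offline analysis library.
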