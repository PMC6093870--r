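---
title: "Models and methods behind erpfactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erpfactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(erpfactor)
```

erpfactor implements a complete analysis pipeline for event-related
potential (ERP) experiments with a 2 (emotion: negative, neutral) x 2 (font
size: large, small) x 2 (contrast: high, low) within-subject design, of the
kind used to ask whether emotion effects on word reading are independent of
low-level visual features.  The pipeline has five stages: a synthetic study
generator with known ground truth, an EEG preprocessing chain,
mass-univariate component localization with family-wise error control,
single-trial amplitude extraction, and Bayes-factor model comparison with a
pre-registered sequential stopping rule.  This vignette explains the models,
the defaults, and the choices made where the design was genuinely open.

## The synthetic study generator

Because raw multi-subject EEG recordings are large and rights-encumbered,
every downstream stage is exercised against simulated studies whose ground
truth is known exactly.  `simulation_config()` describes a study; its
defaults mirror the full-scale layout: 40 subjects, 64 channels at 256 Hz,
480 target words (60 per design cell) plus 80 colour-word probes (20 per
size x contrast cell) split into 8 runs of 70 trials, 1,000 ms word
presentation followed by an inter-trial interval drawn uniformly from
1,000–1,500 ms.  `desk_simulation_config()` is the reduced configuration
used throughout the test suite (16 subjects, 32 channels, 20 trials per
cell, 5 probes per cell, 4 runs); these sizes were chosen once as the
smallest design in which every stage remains statistically meaningful.

Each ERP component is a `component_truth()`: a scalp topography times a
temporal kernel times a per-trial amplitude,

* **topography** — a spherical Gaussian bump (SD 35 degrees of arc) centred
  on the component's electrode-cluster centroid, scaled to maximum absolute
  weight 1; smooth fields are the standard ERP phantom.  An explicit weight
  vector can be supplied instead (e.g. an indicator topography for
  recovery tests).
* **temporal kernel** — a unit-peak Gaussian centred on the window midpoint
  with SD one quarter of the window width, so the deflection is confined to
  its analysis window and its tail at stimulus onset (at least 4–5 SDs
  away) is negligible relative to the baseline.
* **amplitude** — `cell mean + subject offset + trial noise` in microvolts.
  The subject offset (one draw per subject, shared across cells) and the
  trial noise are both Normal.

The default component set (`default_component_truths()`) uses the four
published components — P1 (66–148 ms, 8 occipito-temporal sensors), N1
(150–260 ms, 6 temporal sensors), EPN (300–500 ms, 12 occipito-temporal
sensors), LPP (402–684 ms, 10 parietal sensors) — with cell means set to
the published amplitude table.  The published per-cell SDs (about 3.1–3.9
µV) conflate between-subject and between-trial variability; the generator
splits total variance 50/50 between the two sources by default
(`variance_split`), an explicit free choice, not something the source
reports.

Two calibration details matter:

* **Window-mean calibration.** The generator scales each component so that
  the standard extraction — the mean over the component's window samples
  and electrode cluster — of a noiseless unit-amplitude trial is exactly 1.
  The waveform peak is therefore higher than the window mean, as in real
  ERPs.
* **Cross-talk compensation.** The four kernels overlap (the LPP kernel is
  still large inside the EPN window).  The generator computes the 4 x 4
  cross-talk matrix of what each component's extraction window reads from
  every other component and injects the linear transform of the drawn
  amplitudes that makes extraction return the drawn values exactly.
  Without this the EPN window mean would be biased by ~0.2–0.3 µV of LPP
  leakage.

Background noise is a sum of spatially mixed 1/f^β sources (default β = 1,
8 latent sources, 5 µV per channel) and white sensor noise (2 µV).  These
levels were fixed a priori as typical of cleaned continuous EEG; they leave
the cell-mean calibration unbiased (noise is zero-mean and
baseline-corrected) but contribute to extraction variance.  Optional
ingredients with ground-truth bookkeeping: bad channels (replaced by
high-variance noise), artifact bursts (100 ms half-sine of 400 µV added to
a Bernoulli-sampled fraction of epochs; the injected trial list is stored
so the threshold rejector can be validated against it), and probe-task
behaviour (hits drawn Bernoulli per size x contrast cell).

What the generator does **not** emulate: eye movements and blinks, line
noise, electrode drift and impedance changes, latency jitter across trials,
word-level lexical covariates, and reaction times.  Passing tests therefore
demonstrate correctness of the pipeline's statistics, not robustness to
every artifact class of real recordings.

## Preprocessing

The signal chain follows the standard order: re-reference to Cz, remove
per-channel linear trends, high-pass filter, low-pass filter, interpolate
bad channels, re-reference to the channel average, epoch, baseline-correct,
and flag artifact epochs.

**Filters.** `design_windowed_sinc_fir()` builds Hamming windowed-sinc
kernels with even order (integer group delay).  The ideal cutoff is placed
at the half-amplitude point — passband edge minus half the transition band
for the high-pass, plus half for the low-pass — so the realized −6 dB
frequencies land on 0.25 Hz (high-pass: edge 0.5 Hz, order 1,690,
transition 0.5 Hz) and 33.71 Hz (low-pass: edge 30 Hz, order 114,
transition 7.4 Hz) at 256 Hz sampling.  `apply_fir()` performs a single
forward convolution compensated by the `order/2` group delay — not
forward-backward filtering, which would move the −6 dB point to −12 dB —
with edge-replication padding to preserve length.  On noiseless synthetic
input the full chain preserves extracted window means to better than 2%
RMS.

**Spherical splines.** Bad channels are re-estimated from the good ones
with the classical spherical-spline interpolant on the unit sphere, basis
`g(x) = Σ_n (2n+1)/(n^m (n+1)^m) P_n(x) / 4π` with stiffness `m = 4`, 50
Legendre terms and ridge `λ = 1e-5` — the conventional parameter set for
scalp interpolation.  Good channels are passed through bit-exactly.

**Epochs.** Epochs span the half-open interval [−200, 1000) ms, with tmin
snapped to the nearest sample: at 256 Hz that is 307 samples per epoch.
The baseline is every sample with t < 0.  Quality control implements the
two pre-registered exclusion rules with strict inequalities: more than 10
noisy channels, or probe accuracy below 80% in any size x contrast cell.
Burst artifacts are handled by an explicit amplitude-threshold rejector
(default 250 µV) that flags epochs without altering data; it replaces the
subspace-reconstruction step used on real data, which corrects rather than
rejects and is out of scope here.

## Mass-univariate localization

`subject_contrast_maps()` reduces each subject to one channel x time map:
the mean over all retained target trials (the localizer average used for
P1, N1 and LPP), or the negative-minus-neutral difference collapsed over
size and contrast (used for the EPN, whose localizer-average topography is
not specific to emotion).  `tmax_permutation_test()` then computes
one-sample t statistics against zero across subjects at every channel x
sample — 16,384 tests for 64 channels x 256 post-onset samples — and
controls the family-wise error rate with the permutation distribution of
the maximum |t| over the whole grid.  The "each observation keeps its value
or is set to zero" label swap of the paired design is implemented as
per-subject sign flips of the contrast map, which is algebraically the same
test.  Implementation choices:

* the maximum is taken over the entire channel x time grid per permutation
  (two-tailed), yielding a single FWER-controlling threshold;
* Monte-Carlo p-values carry the add-one correction
  `(1 + #{null ≥ |t|}) / (1 + B)`, which keeps them positive and valid;
  with `method = "exact"` all `2^n` sign patterns are enumerated and the
  correction is unnecessary because the identity pattern is included;
* sign vectors are drawn independently per permutation (duplicates
  allowed) from one seeded generator;
* zero-variance grid points are assigned t = 0, so all-zero data yield
  p = 1 everywhere;
* `critical_t` is the `1 − alpha` empirical quantile of the null maxima
  and significance is `|t| > critical_t`.

`select_component_roi()` replaces the subjective "visual inspection"
refinement with a deterministic rule driven by a `component_prior()`
(expected polarity, latency search range, minimum duration 20 ms, minimum
2 simultaneously significant electrodes): inside the search range, keep
significant points whose mean-map sign matches the expected polarity, find
the longest run of consecutive samples with enough such electrodes
(earliest run on ties), and return the run as the window together with the
electrodes significant in at least half of its samples.  When no run
qualifies the function signals a typed "component not localized" error.
Because the original curated windows cannot be derived from any rule, they
also ship verbatim as `reference_component_specs()`; `run_study()` defaults
to automated selection with fallback to these reference specs
(`localization = "auto_fallback"`), recording which source was used.  At
desk scale and realistic amplitudes (~1 µV against ~2.7 µV between-subject
SD) the localizer-average t statistics rarely cross the t-max threshold —
an expected property of the statistic, not a defect — so reproduction runs
lean on the reference specs while high-SNR recovery tests exercise the
automated rule.

Single-trial amplitudes are window-cluster means of retained target
epochs; peak amplitude and latency are computed per subject and cell from
the cluster-averaged waveform (maximum for positive, minimum for negative
polarity, earliest sample on ties).  Peak measures are exploratory: they
are noisier than mean amplitudes and inherit the sample grid's ~3.9 ms
resolution.

## Bayes factors

**JZS t-test.** `jzs_ttest_logbf()` integrates the Jeffreys–Zellner–Siow
marginal likelihood — effect size δ ~ Cauchy(0, r) via g ~
InverseGamma(1/2, r²/2) — with adaptive quadrature on the log(g) scale
after centring on the integrand's mode; agreement with an independent
quadrature oracle is ~1e-14, far inside the 1e-6 contract.  The
conventional scales r = 0.5, 0.707, 1 probe prior sensitivity.

**Factorial linear models.** `linear_model_logbf()` implements the default
g-prior construction for the single-trial amplitude table: every design
term (three mains, three two-way interactions, the three-way) forms its own
effect batch with orthonormal sum-to-zero contrast codes (Kronecker
products for interactions), prior `θ_b ~ N(0, g_b σ²)` with
`g_b ~ InverseGamma(1/2, r²/2)`; the participant factor is a separate
random batch with its own g at scale `r_random = 1`, which is *not* varied
with the reported `r_fixed` — the nuisance prior is held at the unit
default.  Grand mean and σ² take the noninformative prior.  Conditional on
the g's the marginal likelihood is closed-form in the p-dimensional
projected space, and the g-integral is estimated by plain Monte-Carlo over
prior draws (default 100,000 iterations, seeded).  The proportional error
(% pe) is the relative standard error of the BF from 100 batch means; for
ratios of two estimated marginals the two relative errors add in
quadrature.  The null model keeps the participant batch, so "BF versus
null" always means versus the participant-only model.

Model-space conventions: the six theory models are the three additive and
three interactive combinations that always include emotion, where an
interactive model named `A x B` contains its constituent mains and all
lower-order interactions; only the top-down omission analysis produces
non-marginal term sets (the full model minus one term, all others
retained).  Omission Bayes factors are computed as the difference of the
two model marginals directly — the common null cancels.  Post-hoc emotion
contrasts aggregate single trials to one mean per subject and emotion
within each size x contrast cell and apply the paired JZS t-test at each
scale; subject-level means (not single trials) are the standard paired
semantics.

One consequence of the unit-scale hierarchical nuisance prior deserves
note: for a pure two-condition paired design the linear-model BF is close
to, but not identical with, the paired JZS t-test BF.  With a strictly
flat (improper) prior on the subject effects the model reduces exactly to
the one-sample test on the paired differences, but the proper
`r_random = 1` prior shrinks the subject effects slightly and couples the
subject and contrast directions through the shared error variance, leaving
a structural residual of a few percent of the log evidence at 40 subjects
(and the residual does not vanish by merely widening the nuisance prior —
a diffuse proper prior is not the flat limit).  The test suite therefore
validates the two ingredients separately: the Monte-Carlo marginal is
compared with a deterministic two-dimensional quadrature of the same
integral at Monte-Carlo tolerance, and the exact Bayes factor is compared
with the t-test Bayes factor allowing the shrinkage residual
(0.05 + 5% of |log BF|).

All Bayes factors are stored and reported as natural logarithms;
`bf_from_log()` converts to the natural scale (e.g. log BF −1.72 ↦ 0.18).

## Sequential stopping and the study workflow

`sequential_bf_monitor()` replays the pre-registered optional-stopping
plan: monitoring starts at 20 participants and repeats every 3 (the
schedule is clipped so the final check lands exactly on the pragmatic
maximum of 40, i.e. 20, 23, ..., 38, 40).  The statistical rule fires when
the best candidate model beats the null by a factor of 10 — or the null
beats the best model by 10 — *and* the best model beats the second-best by
10.  With several monitored components the study-level stop requires the
rule for all of them (configurable), and components whose localization has
not yet succeeded defer stopping, mirroring the practice of continuing to
the maximum sample when a low-SNR component (the EPN) is not yet reliably
different from noise.  The monitor only ever sees the first n subjects in
arrival order at each check.

`run_study()` composes the whole pipeline — simulate, preprocess, QC,
localize, extract, model comparison, omission, post-hoc contrasts,
sequential decision — into a `study_report` whose provenance (seeds,
inclusion counts, package version, content hash) makes any table
regenerable bit-identically from the same configuration and seed.
`write_study_report()` serializes it as CSV/JSON plus a plain-text
summary.  Binary epoch data use flat little-endian float32 arrays with a
JSON sidecar.

## Problem sizes and numerical choices

The test suite runs everything at desk scale as its own design choice:
family-wise error is estimated from 500 null replicates of 16 subjects x 8
channels x 50 timepoints at B = 1,000 (Monte-Carlo SE ≈ 1 percentage
point); generator calibration uses the full 40-subject, 64-channel layout;
model recovery uses 20 seeded replicates of 16 subjects x 20 trials per
cell with additive size (0.8 σ) and emotion (0.5 σ) effects at r = 0.707;
Monte-Carlo marginals in tests use 1,000–10,000 draws (proportional errors
of a few percent) against the 100,000-draw default.  Known numerical
degeneracies are handled explicitly: zero-variance inputs error in the
t-test and define t = 0 in the permutation grid; rank deficiency surfaces
as a Cholesky failure naming the model; exact enumeration is limited to 20
subjects (2^20 patterns).

## Limitations

The generator's additive Gaussian world cannot probe robustness to
non-stationary artifacts, trial-order effects or latency jitter; the
automated ROI rule is one defensible formalization of a curated step and
will not reproduce the original curation on low-SNR components; the
Monte-Carlo marginal estimator, while matching the cited default-BF
construction, has noticeable proportional error for weakly identified
models at small iteration counts; and item (word) random effects are out
of scope throughout.
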