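---
title: "Peri-ictal PLV networks: model, assumptions and design choices"
author: "jaenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-ictal PLV networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`jaenet` analyses multichannel scalp EEG across seizure states in juvenile
absence epilepsy (JAE). Its processing chain is:

1. **Preprocessing** — 1–45 Hz zero-phase Hamming-windowed FIR band-pass,
   common average reference (CAR), and state-labelled epoching: five 10 s
   epochs per subject for inter-ictal, pre-ictal and post-ictal conditions
   (rest for controls) and five 5 s ictal epochs.
2. **Connectivity** — instantaneous phase from the analytic signal
   $z_x(t) = s_x(t) + i\,\tilde s_x(t) = A_x(t)e^{i\phi_x(t)}$ (Hilbert
   transform), then the phase-locking value per channel pair,
   $\mathrm{PLV} = \frac{1}{N}\left|\sum_{n=1}^{N} e^{i\theta(n)}\right|$,
   with $\theta(n)$ the per-sample phase difference and $N$ the number of
   valid samples of the epoch. One 19×19 PLV matrix results per subject,
   state, band and epoch; bands are delta 1–4, theta 4–8, alpha 8–13,
   beta1 13–30 and beta2 30–45 Hz.
3. **Graph metrics** — weighted clustering coefficient $C$ (Onnela
   geometric-mean variant on max-normalised weights), characteristic path
   length $L$ on inverse-weight edge lengths $d_{ij} = 1/w_{ij}$, global
   and local efficiency, and the small-world index
   $\sigma = (C/C_\mathrm{rand}) / (L/L_\mathrm{rand})$ against a
   weight-permutation null ensemble.
4. **Statistics** — edgewise Welch t (patients vs controls) and one-way
   ANOVA (four states) with Benjamini–Hochberg FDR over the 171 edges;
   covariate-adjusted (sex, age) least-squares group comparison per
   metric; one-factor repeated-measures ANOVA with Tukey–Kramer post hoc
   for the four states; Welch subgroup contrasts; chi-square and pooled-t
   demographics.

## Interpretation of the PLV sample count

The PLV sum index is read as running over the (valid) time samples within
one epoch, giving one PLV per epoch — the standard usage for continuous
EEG. The alternative across-epochs-at-fixed-time reading is incompatible
with epochs that are analysed independently, so it is not implemented.
After the Hilbert transform, 10% of samples at each epoch edge are marked
invalid and excluded from the sum; FFT-based Hilbert estimates are biased
near the boundaries, and a fixed fractional trim keeps $N$ proportional to
the epoch length.

Per-subject state summaries average the five epochs *at the metric level*
(metrics per epoch, then the mean) — the default `reduction = "metric"`.
`average_plv()` provides the entry-wise matrix mean for edgewise displays
and the edgewise statistics; `reduction = "matrix"` switches graph
metrics to that reduction too.

## Graph-analysis conventions

PLV matrices are strictly positive, so the analysis is fully weighted and
dense: no proportional threshold and no binarisation (a `threshold`
argument exists but defaults off). Conventions follow the widely used
brain-connectivity-toolbox defaults: inverse-weight distances (not
$-\log w$), Onnela clustering with normalisation by the maximum weight,
and unreachable pairs excluded from $L$ (they contribute zero to
efficiency). For the small-world index no topology-rewiring null exists on
a dense matrix, so surrogates permute the off-diagonal upper-triangle
weights uniformly at random and symmetrise; 100 surrogates balance
ensemble variance against runtime, and the ensemble is a deterministic
function of the null seed.

A property of this null worth keeping in mind when reading $\sigma$:
permuting weights preserves their multiset, so a matrix whose weights are
exchangeable scores $\sigma \approx 1$, and *any* reproducible structure
(spatial gradients, partially recruited nodes) lowers $\sigma$ below 1
mainly through the path-length ratio. $\sigma$ here therefore behaves as
an index of network *uniformity*: hypersynchronous but spatially graded
ictal networks score lower than relatively unstructured background
activity. This is the mechanism by which the package's synthetic cohorts
reproduce the reduced ictal small-world index alongside raised ictal
clustering and efficiency.

## The synthetic cohort generator

No public EEG accession accompanies the analysis the package implements,
so the generator is a first-class module that produces ground-truth
cohorts on which every downstream stage is testable.

**Oscillators.** Each frequency band is a noisy mean-field
(Kuramoto-type) phase ensemble at the band's centre frequency:
$\dot\phi_i = 2\pi f_i + g_i \frac{K}{n}\sum_j \sin(\phi_j - \phi_i) +
\sigma_\phi \xi_i(t)$, integrated by Euler–Maruyama at the sampling rate.
Channels carry small static natural-frequency detunings $f_i$
(SD `freq_spread_hz`); detuning is what decorrelates channels when
coupling is weak, which lets the uncoupled ensemble reach near-zero PLV
while very strong coupling still locks essentially perfectly — a pure
common-frequency ensemble cannot satisfy both ends at once because phase
noise alone both desynchronises the weak regime and jitters the locked
one. The pairwise PLV of the ensemble is monotone in $K$, which is the
generative ground truth the pipeline must recover.

**States.** The global coupling $K$ is set per state and band; the
defaults give rest, inter-ictal, pre-ictal and post-ictal one moderate
value ($K = 2$, background PLV ≈ 0.4 after CAR at 500 Hz defaults) and
ictal a far higher one ($K = 12$). Pre- and post-ictal coupling equals
inter-ictal coupling so that *only* the ictal state separates
statistically — matching the emulated finding of no differences between
the three non-ictal states. The config validator enforces ictal coupling
≥ every other state in every band.

**Partial ictal recruitment.** Generalized spike-wave discharges are
fronto-centrally dominant; posterior and temporal leads are relatively
spared. The generator models this with a per-channel coupling gain:
during ictal segments T7, T8, P7, P8, O1 and O2 receive a gain of 0.1.
This is also what gives ictal matrices their node-level heterogeneity and
hence the *reduced* ictal small-world index under the permutation null
(see above); a generator whose ictal state is uniformly hypersynchronous
cannot reproduce that direction, because a saturated uniform matrix is
exchangeable and scores exactly $\sigma = 1 \ge \sigma_\mathrm{background}$.

**Surviving the common average reference.** Perfectly zero-lag,
equal-amplitude global synchrony is annihilated by CAR (the common mode
*is* the signal). Real discharges survive re-referencing because channels
differ in amplitude and carry small conduction lags, so each band's
oscillation gets a static per-channel amplitude jitter (±40%) and phase
lag (SD 0.8 rad). Neither affects PLV directly — PLV is invariant to
static per-channel phase offsets — they only matter through the
referencing step, which is exactly their physical role.

**Ictal morphology.** Seizure segments superimpose a spike-and-slow-wave
template: per cycle, a ~70 ms biphasic spike followed by a half-sine slow
wave, demeaned cycle-wise; only the cycle rate is physiological (3 Hz for
the typical-discharge subtype, otherwise drawn from 2.5–4 Hz excluding
the 3 Hz notch). The morphology is a conventional caricature — the
analyses never depend on spike shape, only on the discharge's rate and
its synchrony.

**Background and covariates.** All segments ride on $1/f$ Gaussian noise
(exponent 1, RMS 12 µV, spectrally shaped). Ages are truncated normals
matching the emulated cohort (patients 11.33 ± 5.26 y, controls
12.83 ± 3.26 y, range 5–30), sexes hit 21/15 and 22/14 exactly at
n = 36, and 21 of 36 patients are typical-3 Hz. Per-subject seeds derive
from the master seed, making the whole cohort a pure function of its
configuration.

**What the generator does not emulate:** volume conduction and leadfield
mixing, ocular/muscle artifacts, non-stationary background, medication
or vigilance effects, and any realistic source geometry. Passing tests
demonstrate that the pipeline recovers the generative coupling ordering
through this idealised forward model — not that the same effect sizes
would be observed on clinical recordings.

## Epoching conventions

The ictal epoch is the first 5 s of each annotated seizure; the pre-ictal
window ends at seizure onset and the post-ictal window starts at seizure
offset, both abutting the boundary with no guard gap; inter-ictal windows
must keep ≥ 60 s from every seizure (the recordings' own inter-seizure
gaps are short, so inter-ictal epochs come from seizure-free background);
rest windows may lie anywhere. Windows of one state never overlap and are
taken earliest-first — a deterministic rule, so extraction is idempotent.
Events too close to the recording edges are skipped. None of these
offsets is standardised in the field; they are declared conventions.

## Numerical choices

- **FIR design**: Hamming window, transition width
  $\max(0.25\,f_\mathrm{low},\ 0.5\ \mathrm{Hz})$, tap count
  $\lceil 3.3 f_s / \Delta f \rceil$ (odd), capped at a third of the data
  length so short epochs remain filterable at the cost of a wider
  transition. Filtering applies the symmetric FIR forward and backward
  (implemented as one FFT convolution with the filter's autocorrelation),
  so the net phase response is identically zero — phase estimation
  downstream must not inherit a filter delay. Edges use odd-symmetric
  padding.
- **EDF**: 16-bit quantisation over a declared ±1000 µV physical range
  (a standard clinical dialect; the source recorder's true range is not
  documented anywhere we could follow). Round trips are exact to half a
  quantisation step (~0.015 µV). Annotations are half-open
  `[onset, onset + duration)` intervals in seconds from recording start.
  Both the older (T3/T4/T5/T6) and modern (T7/T8/P7/P8) temporal lead
  names are accepted; the modern names are canonical.
- **Repeated-measures ANOVA** uses no sphericity correction by default
  (Greenhouse–Geisser behind `gg = TRUE`); with four exchangeable
  conditions the uncorrected test holds its nominal size on the
  generator, which the test suite verifies by simulation.
- **Edgewise group tests** use Welch t (unequal variances are the safe
  default); the demographics table uses the pooled two-sample t, which is
  what reproduces the published age comparison from summary statistics.
  Both are available.
- **Ties and degenerate inputs**: all-zero weight matrices raise a
  degenerate-input error for path length and sigma (efficiency returns
  0); a null ensemble with $C_\mathrm{rand} = 0$ or
  $L_\mathrm{rand} = 0$ raises a degenerate-null error rather than
  returning an infinity.

## Problem sizes used by the test suite

The suite exercises the full pipeline at a reduced problem size chosen as
this package's standard verification scale: 5 s epochs for every state,
250 Hz sampling, theta and alpha bands, a 15 s inter-ictal guard, and 50
null surrogates; cohorts are the full 36 + 36 subjects and 20 independent
cohort seeds for the recovery study. Type-I calibration runs 500
replicates of an 8-subject, 10-channel, 2.5 s configuration with
state-invariant coupling. Oracle equivalence for graph metrics uses 200
random graphs of 4–8 nodes against brute-force enumeration.

## Known limitations

- The weight-permutation null makes $\sigma$ a uniformity index (see
  above); comparisons of $\sigma$ across studies that use rewiring nulls
  on thresholded graphs are not like-for-like.
- Scalp-level PLV is sensitive to volume conduction on real data; the
  generator does not model it, so zero-lag-inflation effects are absent
  from the synthetic validation.
- The eLORETA source-space analyses of the emulated study (84 Brodmann
  ROIs, intra-/inter-network FC) are out of scope: they require a head
  model and lead field.
- Artifact removal is a no-op hook (`artifact_removal_hook()`); synthetic
  data is artifact-free, and real-data use should insert a cleaning
  function there.

## Reproducing the analysis

```{r example}
library(jaenet)

bands <- frequency_bands(c("theta", "alpha"))
cfg <- pipeline_config(
  cohort = cohort_config(n_jae = 36, n_hc = 36, bands = bands, seed = 1),
  bands = bands,
  null_model = null_model_config(seed = 8),
  output_dir = "results/run1",
  seed = 1)
report <- run_pipeline(cfg, progress = TRUE)

report$stats$state_tukey   # four-state post hoc contrasts per metric/band
report$stats$demographics  # cohort table analogue
plot_metrics_by_state(report$metrics)
```
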