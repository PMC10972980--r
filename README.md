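# jaenet — peri-ictal EEG phase-locking networks

`jaenet` is an R package for studying how functional brain networks
reorganise around absence seizures in juvenile absence epilepsy (JAE).
It builds phase-locking-value (PLV) connectivity networks from 19-channel
scalp EEG across five conditions — healthy-control rest and patient
inter-ictal, pre-ictal, ictal and post-ictal states — computes weighted
graph-theory metrics of each network, and runs the complete group and
state statistics. Because clinical recordings of this kind are not
publicly deposited, the package ships a synthetic-cohort generator with
known ground truth, so the whole pipeline is testable end to end.

It is intended for EEG methods researchers and epilepsy network analysts
who want a reproducible, fully tested implementation of this analysis
family, and for anyone who needs ground-truth multichannel EEG with
controllable phase coupling.

## The model at the core

For each band-filtered channel pair, the instantaneous phase comes from
the analytic signal

    z_x(t) = s_x(t) + i * H[s_x](t) = A_x(t) exp(i φ_x(t))

(H the Hilbert transform), and synchrony is the phase-locking value

    PLV = (1/N) | Σ_{n=1..N} exp(i θ(n)) | ,   θ(n) = φ_x(n) − φ_y(n)

over the N valid samples of an epoch: 1 for a constant phase lag, 0 for
phases spread uniformly on the circle. Per subject, state and band this
yields a 19 × 19 PLV matrix, analysed as a dense weighted graph with
edge lengths d = 1/w:

- clustering coefficient **C** (Onnela geometric-mean variant),
- characteristic path length **L**,
- global efficiency **E_glob** and local efficiency **E_loc**,
- small-world index **σ = (C/C_rand)/(L/L_rand)** against a
  weight-permutation null ensemble.

Statistics follow the study design: edgewise Welch t (patients vs
controls) and one-way ANOVA (four states) with Benjamini–Hochberg FDR
across the 171 edges; sex- and age-adjusted least-squares group
comparisons per metric; repeated-measures ANOVA with Tukey–Kramer post
hoc across the four states; subgroup contrasts (sex, age ≤ 13 vs > 13,
typical 3 Hz vs atypical discharges); chi-square / pooled-t demographics.

The five analysis bands are delta 1–4, theta 4–8, alpha 8–13, beta1
13–30 and beta2 30–45 Hz. See the vignette
(`vignettes/periictal-plv-networks.Rmd`) for the generator's model, all
conventions and the design rationale.

## Worked example

Replicate the demographic comparisons from published summary statistics:

```r
library(jaenet)

chi_square_2x2(matrix(c(21, 22, 15, 14), nrow = 2))
#>   test_name  statistic   df1 p_value
#> 1 chi_square    0.0577     1   0.810

two_sample_t_from_summary(11.33, 5.26, 36, 12.83, 3.26, 36)
#>   test_name           statistic   df1 p_value
#> 1 two_sample_t_pooled     -1.45    70   0.150
```

The sex ratios 21/15 vs 22/14 give χ² = 0.058 (p = 0.810) — no group
difference — and the ages 11.33 ± 5.26 vs 12.83 ± 3.26 years give
t(70) = −1.45 (p = 0.150): the groups are demographically matched.

Generate coupled oscillator signals and see PLV track the coupling:

```r
band <- frequency_bands("alpha")
weak   <- coupled_phase_signals(19, band, coupling_K = 2,  duration_s = 10,
                                rate_hz = 500, seed = 1)
strong <- coupled_phase_signals(19, band, coupling_K = 12, duration_s = 10,
                                rate_hz = 500, seed = 1)
ep <- function(X) eeg_epoch(X, state = "rest", index = 1, rate_hz = 500)

plv_matrix(ep(weak),   band = "alpha")
#> <plv_matrix> anonymous/rest/alpha epoch 1: 19 nodes, mean off-diagonal PLV 0.186
plv_matrix(ep(strong), band = "alpha")
#> <plv_matrix> anonymous/rest/alpha epoch 1: 19 nodes, mean off-diagonal PLV 0.939

metrics_bundle(plv_matrix(ep(strong), band = "alpha"),
               null_model_config(seed = 2))
#>   clustering_coefficient shortest_path_length global_efficiency local_efficiency small_world_index
#> 1                  0.980                 1.06             0.939            0.939              1.00
```

Weak coupling (K = 2) leaves the channels nearly independent (mean
PLV 0.19); strong coupling (K = 12) locks them (0.94), and the resulting
near-uniform network has short paths (L ≈ 1.06), high efficiency and a
small-world index pinned at 1 — the signature the pipeline detects in
ictal epochs.

A full synthetic study runs through one call (a few minutes at the
default full scale; about half a minute per cohort at the reduced
verification scale the vignette describes):

```r
bands <- frequency_bands(c("theta", "alpha"))
cfg <- pipeline_config(
  cohort = cohort_config(n_jae = 36, n_hc = 36, bands = bands, seed = 1),
  bands = bands, null_model = null_model_config(seed = 8),
  output_dir = "results/run1", seed = 1)
report <- run_pipeline(cfg)
report$stats$state_tukey   # ictal vs pre/post/inter contrasts per metric
```

A thin command-line wrapper is available as
`Rscript scripts/run_pipeline.R --seed 1 --out results/run1`.

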