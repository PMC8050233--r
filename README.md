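# alexfret

Conformational-state analysis of ALEX single-molecule FRET traces, built for
studies of NADPH-dependent cytochrome P450 oxidoreductase (POR) — the
electron donor hub of microsomal P450 metabolism — whose specificity toward
different electron acceptors tracks a ligand-tunable equilibrium between
compact and extended conformations.

Surface-immobilised Cy3/Cy5-labelled enzyme imaged with alternating-laser
excitation (ALEX) yields per-frame intensity triplets
(`I_DD`, `I_DA`, `I_AA`). The package takes such traces (or simulates them)
and provides the full quantitative chain:

* **Simulation** of realistic traces: Markov state switching, the ALEX
  detection model with α/δ/γ/β distortions, 8% intensity noise, single-step
  photobleaching (`sim_state_model()`, `render_alex_trace()`,
  `simulate_control_traces()`).
* **Quality control** by deterministic single-molecule rules: change-point
  bleach detection, stoichiometry gating, anti-correlation (`qc_filter()`).
* **Correction factors**: donor leakage α and direct excitation δ from
  single-fluorophore populations; detection/excitation factors γ and β from
  the linearity of 1/S in E; conversion of raw intensities to absolute
  efficiency and stoichiometry (`estimate_alpha_delta()`,
  `estimate_beta_gamma()`, `apply_corrections()`).
* **State inference** by unbinned-maximum-likelihood Gaussian mixtures with
  BIC model selection — the per-observation likelihood, never a histogram
  fit — and conversion of state means to inter-dye distances through
  E = 1/(1 + (r/R₀)⁶), R₀ = 56 Å (`fit_gmm()`, `scan_k()`,
  `occupancy_table()`, `compare_conditions()`).
* **Dynamics**: per-trace Gaussian-emission HMM idealisation with per-trace
  BIC, dynamic-fraction summaries, and the binning/Pearson cross-correlation
  control for sub-frame dynamics (`fit_trace_hmm()`, `fraction_dynamic()`,
  `control_experiment()`).
* **Structure link**: grid-based accessible-volume simulation of sterically
  allowed dye positions on a PDB structure and expected inter-dye distances
  (`compute_av()`, `dye_pair_distances()`).
* **Activity link**: bounded Hill dose-response fits
  `f(x) = A + (B−A)/(1 + (IC50/x)^n)`, control normalisation with error
  propagation, and the one-way ANOVA + Tukey HSD significance procedure
  (`fit_hill()`, `normalize_to_control()`, `anova_tukey()`).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, `autoplot()` for the main result
types, and a `run_pipeline()` orchestrator with explicit seeds and
byte-reproducible outputs.

## Worked example

Five equilibrium states with inter-dye distances 76/64/57/48/44 Å and
occupancies ≈17/25/16/27/14% define the ligand-free POR equilibrium
(`por_native_mixture()`). Sampling 20,000 frame-wise efficiencies and
scanning the number of states:

```r
library(alexfret)
mix <- por_native_mixture()
e <- sample_mixture(mix, 20000, seed = 1)$e
scan <- scan_k(e, k_min = 1, k_max = 8, seed = 1)
scan
#> BIC scan over k = 1..8; selected k = 5
#> # A tibble: 8 × 3
#>       k log_likelihood     bic
#>   <int>          <dbl>   <dbl>
#> 1     1          -174.    367.
#> 2     2          5298. -10546.
#> 3     3          6268. -12457.
#> 4     4          7414. -14718.
#> 5     5          7596. -15053.
#> 6     6          7599. -15029.
#> 7     7          7603. -15007.
#> 8     8          7604. -14979.
```

BIC bottoms out at five states. The fitted mixture converts to a state
table (S1 is the most extended, lowest-efficiency state):

```r
occupancy_table(scan$best_fit)
#> # A tibble: 5 × 5
#>   state mean_E  sigma distance_A occupancy_pct
#>   <chr>  <dbl>  <dbl>      <dbl>         <dbl>
#> 1 S1     0.139 0.0392       75.9          16.8
#> 2 S2     0.309 0.0396       64.0          25.2
#> 3 S3     0.472 0.0403       57.0          15.9
#> 4 S4     0.714 0.0395       48.1          26.5
#> 5 S5     0.807 0.0410       44.1          15.5
```

Recovered distances land within 0.2 Å and occupancies within ~1.5 points of
the generating truth. A dose-response example: triplicates at eight
log-spaced concentrations generated from a Hill curve (A = 100%, B = 156%,
IC50 = 21 µM, n = 1, 5% noise), refit with the Hill coefficient bounded to
[0, 5]:

```r
cfg <- dose_response_config(A = 100, B = 156, ic50 = 21, hill_n = 1,
                            concentrations = 10^seq(0, 2, length.out = 8),
                            noise_sd = 5, replicates = 3)
fit_hill(simulate_dose_response(cfg, seed = 1), n_bounds = c(0, 5))
#> Hill fit: A=97.93 B=157.98 IC50=19.1 uM n=0.865
```

`autoplot()` works on mixture fits, BIC scans, Hill fits and the
cross-correlation control summary; see the vignette
(`vignettes/conformational-sampling.Rmd`) for the model, its assumptions
and all numerical choices.

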