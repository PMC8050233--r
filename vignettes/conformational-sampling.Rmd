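---
title: "Quantifying conformational sampling from ALEX smFRET traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational sampling from ALEX smFRET traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alexfret)
library(dplyr)
```

## The measurement and the model

NADPH-dependent cytochrome P450 oxidoreductase (POR) shuttles electrons to
microsomal P450s through large FAD/FMN-domain motions between compact and
extended conformations. Surface-immobilised, dual-labelled (Cy3/Cy5) enzyme
imaged by TIRF with alternating-laser excitation (ALEX) yields, per molecule
and per 200 ms frame, three intensities: donor emission under donor
excitation (`I_DD`), acceptor emission under donor excitation (`I_DA`), and
acceptor emission under acceptor excitation (`I_AA`). From these, FRET
efficiency E reports the inter-dye distance through
$E = 1/(1 + (r/R_0)^6)$ with $R_0 = 56$ Å for Cy3/Cy5, and stoichiometry S
separates dual-labelled molecules from single-fluorophore species.

Because functional POR dynamics are faster than the 200 ms frame period,
individual frames sample a conformational *equilibrium*: pooled frame-wise
efficiencies form a multimodal distribution whose modes are long-lived
equilibrium states. The package models this distribution as a Gaussian
mixture fitted by **unbinned maximum likelihood** (the likelihood is the
product of per-observation mixture densities — no histogram is ever fit) and
selects the number of states by BIC. Fitted component means convert to
distances via the Förster relation; component weights are the state
occupancies whose ligand-induced shifts are the scientific readout.

## Pipeline stages

1. **Quality control** (`qc_filter()`): deterministic rules accept traces
   that look like single donor–acceptor pairs — single-step photobleaching
   per dye (change-point detection on `I_AA` and on `I_DD + I_DA`),
   mean apparent stoichiometry inside a window (default 0.3–0.7), at least
   10 usable pre-bleach frames, and donor/acceptor anti-correlation.
   Downstream analysis uses only frames before the first bleach.
2. **Correction** (`estimate_alpha_delta()`, `estimate_beta_gamma()`,
   `apply_corrections()`): donor leakage (α) and direct excitation (δ) come
   from stoichiometry-gated donor-only/acceptor-only populations; detection
   imbalance (γ) and excitation normalisation (β) from the linearity of
   1/S in E across FRET populations. Corrected E and S are stored
   unclamped; clamping happens only at distance conversion.
3. **State inference** (`fit_gmm()`, `scan_k()`, `occupancy_table()`):
   EM with k-means++-style restarts, BIC over a k scan, states labelled
   S1..Sk by decreasing inter-dye distance.
4. **Dynamics** (`fit_trace_hmm()`, `fraction_dynamic()`,
   `control_experiment()`): per-trace Gaussian-emission HMMs idealise each
   trace (state count by per-trace BIC, Viterbi decoding); the fraction of
   traces with at least one transition summarises observable dynamics, and
   the binning/cross-correlation control quantifies what sub-frame dynamics
   would look like.
5. **Structure link** (`compute_av()`, `dye_pair_distances()`): a grid-based
   accessible-volume simulation predicts expected inter-dye distances from
   structural models for comparison with FRET-derived distances.
6. **Activity link** (`fit_hill()`, `anova_tukey()`,
   `normalize_to_control()`): bounded Hill fits of dose-response tables and
   the ANOVA + Tukey HSD significance procedure for comparative activity
   data.

`run_pipeline()` chains stages 1–4 with explicit seeds, per-stage outputs
and a manifest; rerunning with the same seeds reproduces the JSON/TSV
outputs byte for byte.

## A worked example

```{r example, eval = FALSE}
# the ligand-free five-state equilibrium: distances 76/64/57/48/44 Å,
# occupancies ~17/25/16/27/14%
mix <- por_native_mixture()
e <- sample_mixture(mix, 20000, seed = 1)$e

scan <- scan_k(e, k_min = 1, k_max = 8, seed = 1)
scan$selected_k          # 5
occupancy_table(scan$best_fit)
autoplot(scan)           # BIC vs k
autoplot(scan$best_fit)  # mixture over the efficiency histogram
```

## What the synthetic generator emulates — and what it does not

All tests and acceptance experiments run on synthetic data: raw smFRET
recordings are large, instrument-specific and not redistributable inside a
package. The generator reproduces the statistical structure the analysis
relies on:

* Markov state switching with a per-frame transition probability
  (`sim_state_model()`), including the fast two-state control
  (p = 0.95 between E = 0.3 and 0.7).
* The ALEX detection model with configurable α, δ, γ, β distortions,
  8% relative Gaussian intensity noise, and single-step irreversible
  photobleaching with geometric waiting times (`render_alex_trace()`).
  After acceptor bleach the donor recovers to its zero-FRET level, giving
  the classic anti-correlated bleach signature; dark channels carry
  zero-mean Gaussian background noise.
* Gaussian efficiency mixtures with the reference state means and occupancies
  (`por_native_mixture()`, `por_rifampicin_mixture()`), and Hill-shaped
  dose-response tables with replicate noise (`simulate_dose_response()`).

It does **not** emulate camera/EMCCD noise statistics, diffusing-molecule
bursts, dye blinking (suppressed experimentally by the imaging buffer),
spectral fluctuations, or baseline drift. Passing tests therefore
demonstrate that the estimators recover the truth under the stated noise
model, not that they are robust to every artefact of real recordings.

A few generator conventions worth knowing:

* The reported native occupancies (17/25/16/27/14%) sum to 99% due to
  rounding; `por_native_mixture()` renormalises them.
* State widths are not reported; σ = 0.04 in E units is the default, chosen
  so that neighbouring states (ΔE ≈ 0.09–0.24) overlap realistically but
  remain resolvable at realistic sample sizes.
* Trace intensity scale (1000 photons/frame) and dark-channel background
  (noise_fraction × intensity) are arbitrary-unit choices; every estimator
  tested is invariant to uniform rescaling.
* In the binning control, the 8% noise is applied to the *binned*
  intensities: each bin size emulates an acquisition at that temporal
  resolution, and the noise models the measurement uncertainty of that
  acquisition. Injected before binning instead, averaging would shrink
  noise and state fluctuations at the same rate and the donor/acceptor
  anti-correlation would never collapse to zero — contrary to the measured
  behaviour the control is designed to reproduce.

## Numerical choices

* **EM**: best of 10 k-means++-style restarts (short runs, tolerance 1e-6,
  100 iterations), then the winner is polished to a per-observation
  log-likelihood change below 1e-8 (cap 2000 iterations). Component σ is
  floored at 0.01 E-units to prevent spike collapse on duplicated values;
  a component whose weight falls below 1e-4 invalidates the restart.
* **BIC**: `(3k - 1) ln N - 2 ln L` (k means, k sigmas, k−1 free weights);
  the strict minimiser is selected, with no ΔBIC parsimony rule. Mixtures
  are fitted on pooled frame-wise corrected efficiencies of all accepted
  traces (frame-wise pooling maximises power; the trace-wise alternative is
  a user-level aggregation away).
* **α/δ estimation** uses ratios of pooled channel means, identical to the
  mean apparent quantities on noise-free data but free of the ~1e-2
  ratio-noise bias that frame-wise averaging of E_app/S_app incurs at 8%
  intensity noise.
* **Bleach detection**: exhaustive best mean-difference split on a
  5-frame rolling mean, refined on the raw channel; a step must drop by at
  least 50% of the pre-step mean, the pre-step mean must exceed the
  residual noise, and change points within 5 frames of either end are not
  considered (a single outlier frame is not a bleach). One step per dye
  channel is the single-molecule signature; a second drop in the same
  channel flags an aggregate.
* **HMM**: per-trace Baum–Welch with scaled forward–backward, state count
  by per-trace BIC (`K² + 2K - 1` parameters), Viterbi decoding, emission
  σ floored at 1e-4 so that noise-free traces are handled exactly.
* **Hill fits**: bounded Levenberg–Marquardt. Flat tables are flagged
  unidentifiable instead of fitted. Because plateau (B) and IC50 trade off
  along a flat ridge when the tested range ends near the IC50, a fitted
  IC50 outside the tested concentration window is flagged
  (`ic50_in_window = FALSE`) and excluded from summaries — without this,
  occasional ridge solutions (IC50 orders of magnitude beyond the data)
  make averages across replicate experiments meaningless.
* **Accessible volumes**: cubic grid (default 1 Å) inside the 14 Å linker
  sphere; a node is a dye position if it clears every heavy atom by
  dye radius + atom radius (3.5 + 1.7 Å), and must be connected to the
  attachment point through nodes with at least linker-width/2 clearance
  (26-neighbourhood flood fill). This reachability rule is a documented
  simplification of full linker-path modelling; it is property-tested
  (free-space ball volume, wall confinement, monotonicity under added
  atoms) rather than matched to any external implementation. Symmetric
  free-space clouds carry a small convexity bias
  (⟨R⟩ − d ≈ (σ_y² + σ_z²)/2d, about +1.2 Å at 50 Å separation), which the
  tests assert rather than ignore.

## Problem sizes used in the shipped experiments

Mixture-recovery and model-selection experiments use 1e5 efficiencies per
replicate (five replicates), matching a realistic pooled-frame count
(hundreds of traces × hundreds of frames). The binning control uses 30–50
traces of 200 post-binning frames per bin size; HMM recovery suites use
tens of traces of 100–300 frames; Hill-recovery suites use 20 replicate
tables of triplicates at 8 log-spaced concentrations. These sizes make the
full test suite and the acceptance script each complete in a few minutes on
one CPU while keeping Monte Carlo error far below the assertion tolerances.

## Known limitations

* States are equilibrium FRET states; no attempt is made to assign them to
  specific crystal-structure conformations, and no kinetic rates are
  extracted from dwell times.
* The rule-based QC stands in for learned trace classification; its
  thresholds are exposed in `qc_criteria()` rather than tuned to any
  reference classifier.
* Occupancy-shift bootstrap CIs resample traces and refit weights with
  means/σ fixed at the reference condition; if ligands moved the state
  centres substantially this conditioning would be wrong — here ligands are
  assumed (and observed) to shift occupancies, not centres.
* The AV model uses a single uniform heavy-atom radius and uniform cloud
  weighting (AV1-style); per-element radii and three-radius dye models are
  out of scope.
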