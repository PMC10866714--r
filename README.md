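# shrscr

Quantitative analysis of single-cell SHORT-ROOT (SHR) and SCARECROW (SCR)
fluorescence trajectories from *Arabidopsis* root meristems, for researchers
studying how these transcription factors decide between *formative*
(periclinal, fate-separating) and *proliferative* (anticlinal) cell
division.

The package implements, end to end:

* **Trajectory preprocessing** — ingestion of long-format per-cell time
  series (reporter/nuclear-marker ratios sampled every 15 min), moving-average
  smoothing, normalization to the 90th quantile, population averaging with
  s.e.m., and segmentation into cell cycles with a per-cycle min-max
  normalized nuclear size as cell-cycle-phase proxy.
* **ODE model comparison** — SCR predicted from the measured SHR input under
  four candidate models, compared by adjusted R²:
  Michaelis–Menten `dS/dt = βH/(K+H) − γS`; Hill
  `dS/dt = βHⁿ/(Kⁿ+Hⁿ) − γS`; saturating positive feedback
  `dS/dt = βH/(K+H) + αS/(K_f+S) − γS`; and a reduced three-species
  transcription of the bistable SHR–SCR–RBR–CYCD6 network
  (Cruz-Ramírez et al., 2012). Fitting is deterministic multi-start bounded
  Levenberg–Marquardt on log-parameters.
* **Bistability analysis** — fixed points by Newton iteration from a
  documented start lattice (plus a sign-change pre-scan in 1-D), stability by
  Jacobian eigenvalues, bistability and hysteresis intervals across an input
  range, and one-at-a-time parameter scans over two orders of magnitude.
* **Division prediction** — threshold classifiers on SHR/SCR levels,
  optionally restricted to one of four nuclear-size quarters (the first
  quarter ≈ G1/early S); exact one-tailed binomial tests against chance;
  Mann–Whitney comparison of initial nuclear sizes (exact by enumeration for
  combined n ≤ 20); per-treatment first-division summaries with one-sided
  t-tests; and G1/size-quartile concordance.
* **Feature classification** — per-unit dynamic features (max, mean, AUC,
  max rate, time to half-max, per-quarter maxima), a stratified
  cross-validated ridge-logistic classifier, and single-feature
  discrimination ranking.
* **A synthetic trajectory generator** with planted ground truth (sigmoid
  dose-dependent SHR, ODE-driven SCR, lognormal 12 h cell cycles, sawtooth
  nuclear growth, an early-window threshold decision rule, arrested cells,
  multiplicative noise), so every downstream stage is testable without
  microscopy data.

## Worked example

Generate a dose-ladder experiment (eight roots at 0.01–10 µM dex, 25 cells
each), then ask the data which nuclear-size quarter and which threshold best
predict formative division:

```r
library(shrscr)

cfg <- synthetic_config(
  n_roots = 8, cells_per_root = 25,
  dex_dose = c(0.01, 0.02, 0.03, 0.05, 0.1, 0.2, 1, 10),
  theta_star = 0.3, window_star = 1, seed = 7)

rec <- recover_decision_window(cfg)
round(rec$quarter_accuracy, 3)
#>    Q1    Q2    Q3    Q4
#> 0.977 0.942 0.915 0.901
rec$best_quarter
#> [1] 1
rec$best_theta
#> [1] 0.3
rec$top_feature
#> [1] "shr_max_in_q1"
```

The scan recovers the planted rule: requiring the threshold to be met in the
*first* quarter of the nuclear-size range (≈ G1/early S) predicts division
orientation better than any later quarter (97.7% vs ≤ 94.2%), the optimal
threshold equals the planted 0.3 in normalized units, and the single most
discriminative feature is the maximum SHR level during that first quarter.

Fitting the candidate models to the fully induced mean trajectories:

```r
full <- generate_trajectories(synthetic_config(seed = 7))
trajs <- lapply(full$trajectories, function(tr) {
  tr$shr <- smooth_series(tr$shr); tr$scr <- smooth_series(tr$scr); tr
})
grid <- seq(0, 48, by = 0.25)
shr_mean <- average_trajectories(trajs, grid, "shr")
scr_mean <- average_trajectories(trajs, grid, "scr")
fit <- fit_scr_model("michaelis_menten", shr_mean, scr_mean)
fit
#> <fit_result michaelis_menten: r2_adj = 0.9996, n = 193, p = 3>
#> <ode_model_spec michaelis_menten: beta=0.2547, K=0.5376, gamma=0.1509>
```

A monostable three-parameter model explains the mean SHR→SCR relationship
essentially completely (the generator's true parameters are β = 0.25,
K = 0.5, γ = 0.15) — bistability is not needed to describe these dynamics,
which is the package's central model-comparison exercise. The reduced
bistable network is still available for contrast:

```r
bistability_check(ode_model_spec("cruz_ramirez"), c(0, 1.5), n_grid = 7,
                  starts_per_dim = 4)
#> <bistability_report: BISTABLE; max stable states 2, hysteresis over [0.25, 0.75]>
```

`run_pipeline(pipeline_config(...))` chains all stages (simulate/ingest →
preprocess → fit → predict → features) into an output directory with a
manifest, and `make_report()` renders a plain-text summary; reruns with the
same configuration are byte-identical.

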