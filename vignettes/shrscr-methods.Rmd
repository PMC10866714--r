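---
title: "Models and methods behind shrscr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shrscr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrscr)
```

## The scientific question

In the *Arabidopsis* root meristem, the mobile transcription factor
SHORT-ROOT (SHR) moves from the stele into the adjacent ground-tissue cells,
where it activates SCARECROW (SCR). Together they license the *formative*
(periclinal) division that separates endodermis from cortex; without them
cells divide only *proliferatively* (anticlinally). Two competing views of
this decision exist. In the classical bistable-switch picture, positive
feedback between SCR, the SHR-SCR complex, RBR and CYCD6 drives nuclear SHR
and SCR to a high stable steady state, and reaching that attractor is what
commits a cell to formative division. The alternative is a much simpler
threshold-and-timing rule: modest SHR/SCR levels suffice, provided they are
present during an early window of the cell cycle (G1 / early S), for which
per-cycle nuclear size acts as an observable proxy.

`shrscr` implements the quantitative machinery needed to confront these two
views with single-cell fluorescence trajectories: trajectory preprocessing,
ODE model comparison, fixed-point/bistability analysis, windowed threshold
classification with its accompanying statistics, dynamic-feature
classification, and a ground-truth synthetic data generator that makes the
whole pipeline testable without microscopy data.

## Trajectory preprocessing

Input series are per-cell reporter/nuclear-marker intensity ratios sampled
(nominally) every 0.25 h. Preprocessing follows three fixed conventions:

* **Smoothing** (`smooth_series`): a centered moving average whose window
  shrinks at the series boundaries, default 5 frames (75 min). The window is
  configurable; 1 is the identity. A moving average was chosen over
  filter-based smoothers because it needs no tuning beyond the window and
  leaves slow sigmoid dynamics unbiased.
* **Quantile normalization** (`normalize_to_quantile`): division by the
  0.90 quantile of a reference pool, computed with the linear-interpolation
  convention (`type = 7`). The convention is stated because the
  normalization constant depends on it. The pooling scope is configurable
  (`"cell"`, `"root"`, `"dataset"`); the pipeline default is per-dataset
  pooling because threshold scans compare a single threshold *across*
  roots, and per-root divisors would erase genuine between-root differences
  in expression level (e.g. under an induction dose ladder).
* **Averaging** (`average_trajectories`): linear interpolation of each cell
  onto a common grid strictly within its observed span, then per-gridpoint
  mean, s.e.m. and contributing-cell count. Cells stop contributing when
  their observation ends (for instance at a formative division), so the
  count is typically non-increasing late in the timecourse.

Cell-cycle segmentation (`segment_cycles`) cuts a trajectory at its division
events; each segment carries a min-max normalized nuclear size
(`norm_size` in [0, 1]) used as the cycle-phase proxy, and an outcome label:
the orientation of the division ending it, or `censored` for a trailing
segment. Quarters of `norm_size` are half-open, `[(k-1)/4, k/4)`, with the
last quarter closed at 1 — a boundary value belongs to the higher quarter.

## Candidate models of SCR regulation

Four model families predict SCR driven by a measured (or simulated) SHR
input \(H(t)\), linearly interpolated between samples and held constant
beyond the last:

* Michaelis-Menten: \(dS/dt = \beta H/(K+H) - \gamma S\)
* Hill: \(dS/dt = \beta H^{n}/(K^{n}+H^{n}) - \gamma S\), \(n \ge 1\)
* Positive feedback: \(dS/dt = \beta H/(K+H) + \alpha S/(K_f+S) - \gamma S\).
  A saturating (concave) autoregulation term crossing linear decay admits at
  most two fixed-point intersections, so this family is monostable by
  construction — positive feedback alone does not imply bistability.
* `cruz_ramirez`: a reduced three-species transcription of the published
  bistable SHR-SCR network topology (Cruz-Ramirez et al., 2012): SCR
  production activated by the SHR·SCR complex (Hill-2 in the complex), RBR
  sequestration of free SCR at rapid equilibrium, and CYCD6-driven RBR
  phosphorylation that releases SCR — two interlinked positive feedback
  loops. The exact published parameter values are not reproduced here (they
  live in the original supplementary material); the defaults are
  representative values chosen once so that the network is bistable over an
  intermediate range of constant SHR inputs (roughly 0.25-0.75 in
  normalized units) and monostable at both extremes, which is the
  qualitative behaviour the analyses need. A fifth family,
  `self_activation` (\(dS/dt = H + \alpha S^2/(K_f^2+S^2) - \gamma S\)), is a
  minimal one-dimensional switch used to exercise the bistability detector
  against brute-force oracles.

**Integration.** `simulate_model` uses `deSolve`: `lsoda` (stiff-capable)
for the three-species network, the adaptive explicit `ode45` pair for the
one-dimensional families; relative tolerance 1e-6 by default. States that
undershoot below -1e-6 are clipped to zero with a warning. Inside the fit
objective — where the same input curve is integrated thousands of times —
a dedicated fast path advances the linear-in-\(S\) families exactly per grid
interval with the integrating factor and Simpson quadrature, and the
positive-feedback family by fixed-step RK4 (2 substeps per 0.25 h frame).
The fast path agrees with the adaptive integrator to better than 1e-4 in
normalized units; the final reported prediction is always recomputed with
the adaptive integrator.

**Fitting.** `fit_scr_model` minimizes squared residuals between the model
prediction and the mean SCR trajectory with bounded Levenberg-Marquardt
(`minpack.lm`) on log-scale parameters. Multi-start: three log-spaced values
per parameter around unit scale (Hill coefficient starts at 1, 2, 4); all
starts are screened by their initial residual sum of squares and the best 20
are refined (up to 300 iterations each). Everything is deterministic — no
random restarts. Fit quality is the adjusted coefficient of determination,
\(R^2_{adj} = 1-(1-R^2)(n-1)/(n-p-1)\), with \(p\) counting free parameters
only. On noiseless self-generated data all three monostable families
recover \(\beta, K, \gamma\) to within 5%.

**Fixed points and bistability.** `find_steady_states` locates roots of the
autonomous right-hand side at a constant input by damped Newton iteration
with a numerical Jacobian from a lattice of starts (5 log-spaced points per
state dimension over \([10^{-3}, 10^{2}]\)); for one-dimensional families a
sign-change pre-scan over [0, 102] with `uniroot` refinement is added, which
separates closely spaced roots near a fold bifurcation. Roots are merged at
tolerance 1e-6 and classified stable when all Jacobian eigenvalues have
negative real part. `bistability_check` counts stable states across an input
grid; *bistable* means two or more coexisting stable states at some input,
and the hysteresis interval is the input range over which that holds.
`parameter_scan` varies one parameter at a time over a multiplicative grid
(two orders of magnitude, factor 1 included) and re-evaluates both the
prediction quality and the bistability flag without refitting the other
parameters; re-evaluation rather than refitting was chosen because it asks
the sharper question — whether the *same* calibration survives the
perturbation — and keeps the scan cheap and deterministic.

## Threshold prediction of division outcome

`classify_by_threshold` predicts a unit formative when its channel reaches a
threshold \(\theta\) at one or more timepoints, optionally restricted to
timepoints whose `norm_size` lies in a given quarter. `threshold_scan`
sweeps \(\theta\) over a grid (default: 200 even values from 0 to the 99th
percentile of the channel) and reports the accuracy profile, the best
accuracy, and the smallest maximizing threshold (ties deliberately break
toward low thresholds). Two class universes are used, following the two
analyses they implement: whole-trajectory scans classify *formative vs
non-dividing* (censored cells observed at least 12 h — about one median
cell cycle — without dividing); per-cycle windowed scans classify
*formative vs proliferative* segments. Cells that divided only
proliferatively are excluded from the whole-trajectory universe.

Supporting statistics are implemented exactly where exactness is cheap:

* `binomial_one_tailed`: exact upper-tail \(P(X \ge k)\), the chance-level
  test for classification accuracies (chance is about 0.5 for balanced
  two-class problems).
* `mann_whitney`: rank-sum test with full enumeration of group assignments
  for combined \(n \le 20\) (ties handled naturally by enumerating the
  observed ranks) and a tie-corrected, continuity-corrected normal
  approximation above; used to compare initial normalized nuclear sizes of
  formatively vs proliferatively dividing cells.
* `first_division_summary`: per-root percentage of formative first
  divisions, treatment means with s.e.m., and a classic equal-variance
  one-sided two-sample t-test against control. The test direction is
  prespecified from the synchronization mechanism (G1/S arrest enriches
  cells inside the early window, so "greater"; G2/M arrest the converse).
  Zero-variance degenerate comparisons are flagged rather than producing
  NaN.
* `g1_window_concordance`: per complete cycle, the first (linearly
  interpolated) time normalized nuclear size crosses 0.25, scored a success
  when it falls within G1 or at most 1 h after G1 ends (closed boundary);
  aggregated as mean with s.e.m. across roots. This is the calibration that
  justifies reading "first nuclear-size quarter" as "G1 / early S".

`extract_features` computes per-unit dynamic features (max, mean,
trapezoidal AUC, max rate of the smoothed series, time to half-max, per
quarter maxima, initial nuclear size, duration); quarter features of
unvisited quarters are flagged missing, never silently zero.
`train_classifier` runs stratified k-fold cross-validation (default 5) of an
L2-regularized logistic model (`glmnet`, ridge, fixed \(\lambda = 0.01\))
with training-fold median imputation and standardization; fold assignment is
derived from the seed on rows sorted by a content key, so permuting input
row order does not change the result. `single_feature_discrimination` scans
each feature in both inequality orientations and ranks features by their
best single-threshold accuracy.

## The synthetic data generator

`synthetic_config`/`generate_trajectories` emulate an induced-SHR timecourse
with known ground truth. Defaults, with the reasoning:

* sampling every 0.25 h for 48 h; 5 roots x 40 cells;
* dose → amplitude: Hill map \(d^{1.5}/(0.15^{1.5}+d^{1.5})\), negligible at
  0.01 uM and saturating between 1 and 10 uM, matching a near-complete
  rescue at full induction and none at the lowest dose;
* SHR: sigmoid rise (onset delay 3 h, rate 0.4 h\(^{-1}\)) to the
  dose-set plateau, with per-cell lognormal amplitude scatter
  (`amp_cv = 0.25`) reflecting the wide cell-to-cell variation of reporter
  levels within a root; an optional pulse mode decays the signal after a
  configurable width, emulating transient low peaks;
* SCR: driven by the default Michaelis-Menten model
  (\(\beta = 0.25, K = 0.5, \gamma = 0.15\), time scale ~7 h);
* cell cycles: lognormal lengths with median 12 h (sdlog 0.2); nuclear size
  grows linearly from 40 to 110 a.u. within each cycle and resets at
  division; cells start at a uniformly random phase, so part of the
  population is already past the early window at induction;
* planted decision rule: a formative division ends the first *completed*
  cycle in which the noiseless decision channel reaches
  \(\theta^* = 0.3\) at a timepoint whose true phase lies in quarter 1;
  otherwise the division is proliferative. Observation truncates at the
  formative division;
* censoring: a fraction (default 0.1) of cells is cycle-arrested at a phase
  past the decision window and never divides — consistent with the planted
  rule, which never fires for them;
* noise: multiplicative lognormal on intensities (sigma 0.1 per channel),
  additive Gaussian on nuclear size at 2% of the size range, applied after
  outcome assignment;
* G1: the marker is on for the first fraction of each cycle, with mean 0.35
  and cycle-to-cycle s.d. 0.15 (G1 is the most variable phase); this makes
  the G1/quartile concordance a nontrivial statistic rather than an
  identity;
* reproducibility: per-cell random streams are seeded by a stable hash of
  (master seed, root, cell, dose), so any subset — including a single dose
  out of a dose series — regenerates identically in isolation.

Division events are recorded on the last sampled frame of their cycle, so
the post-division size reset falls into the next segment and per-segment
min-max normalization is not contaminated.

Two study designs are used repeatedly. The *fully induced* design (single
dose 10 uM) mirrors the tandem SHR/SCR imaging experiment and feeds the ODE
fits. The *dose ladder* design (doses 0.01-10 uM across roots, e.g.
`dex_dose = c(0.01, 0.02, 0.03, 0.05, 0.1, 0.2, 1, 10)`) mirrors the
induction titration and is the right setting for threshold recovery: with
per-cell amplitude scatter it produces cells whose peak levels bracket
\(\theta^*\) densely, which is what makes the planted threshold
identifiable from data at all. `recover_decision_window` packages that
closure experiment: generate, smooth, segment, scan all four quarters, rank
features. On 200-cell dose-ladder datasets at 10% noise it recovers quarter
1 as the most predictive window, the threshold within 0.05 of
\(\theta^*\), and the quarter-1 maximum as the top-ranked feature, in a
large majority of seeds (20/20 in the runs reported by the test suite).
The threshold grid used there steps by 0.05 — a resolution commensurate
with the multiplicative measurement noise; the 200-point default grid is
meant for accuracy *profiles*, not for point identification of a planted
constant.

What the generator deliberately does **not** emulate: spatial tissue
context and SHR movement (SHR is an exogenous signal); image formation and
segmentation; nonlinear (sigmoidal) nuclear growth, available by
configuration but off by default; cell lineage (daughters are not tracked
as new cells); and biological coupling between SCR and the division
machinery beyond the planted rule. Passing tests on synthetic data
therefore demonstrate the *pipeline's* correctness and the identifiability
of a planted mechanism under realistic noise — not that real cells obey
that mechanism.

Two further honest gaps. First, under the default 3 h onset delay almost no
unsynchronized cell is still inside quarter 1 by the time the threshold is
first reached, so the synthetic "control" arm of the synchronization
experiment yields few formative first divisions (a couple of percent),
lower than observed in real roots; the hydroxyurea ≫ control ≥ oryzalin
ordering is nevertheless reproduced, because arrested cells hold their
phase (default 4 h) while SHR accumulates. Second, arrested (censored)
cells carry full dose-level SHR, so in a fully induced design the
whole-trajectory threshold scan cannot beat class prevalence; in the dose
ladder design, where most non-dividers sit at low doses, it reaches ~85-90%
accuracy at a low threshold — the regime in which such a scan is
informative on real dose-titration data as well.

## Numerical and testing conventions

Degenerate inputs raise classed conditions (`shrscr_*_error`) naming the
offending cell or column. All tie-breaks are documented and deterministic:
smallest threshold at equal accuracy, start order at equal residual,
first-listed feature at equal ranking accuracy. The test suite validates
every numerical component against an independent oracle: a fixed-step RK4
integrator at dt = 1e-3 for the solvers (< 1e-3 absolute over 48 h), dense
sign-change scans for fixed points and bifurcations, exact enumeration for
the binomial and rank-sum tests, brute-force confusion counts for scan
accuracies, and the generator's stored noiseless ground truth for the
planted decision rule (labels are re-derived by `replay_decision_rule` and
must match exactly). Problem sizes in the routine suite are kept modest —
200-cell datasets, 20-seed recovery studies, 36-cycle concordance sets —
which is ample for the majority-vote properties being asserted while
keeping a full run in the low minutes.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every headline
quantity from scratch — model comparison on fully induced means, parameter
recovery error, bistability flags, windowed and whole-trajectory scan
accuracies, threshold recovery, classifier accuracy, feature ranking, G1
concordance, synchronization percentages and the dose-response — and writes
them as a flat JSON object. All randomness derives from `--seed`.
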