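---
title: "A cell-population model of skeletal muscle regeneration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cell-population model of skeletal muscle regeneration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoregen)
```

## The model

After an acute injury (for instance notexin injection into the tibialis
anterior), one cubic millimeter of muscle contains a large pool of damaged
myonuclei whose clearance and replacement play out over about a week. The
package models this as nine interacting populations, all in cells/mm^3
with time in days:

* **Md** — damaged (dead) myonuclei. Injury enters the model *only*
  through `Md(0)`; there is no ongoing damage term, so `Md` can only
  decrease.
* **N**, **Nd** — neutrophils and dead neutrophils. Neutrophils are
  recruited in proportion to remaining damage (`cNin Md`), leave or die at
  a first-order rate (`cNout N`), and die after engulfing debris
  (`cNMd N Md`), which converts them to `Nd`. M1 macrophages clear `Nd`.
* **M**, **M1**, **M2** — monocytes and the two macrophage phenotypes.
  Monocytes follow neutrophil-derived signals (`cMin N`), polarize to M1
  in proportion to remaining dead material (`cMM1 M (Nd + Md)`), and exit
  at `cMout M`. The M1-to-M2 transition is *inhibited* by dead material:
  its rate is `cM1M2 M1 / (cM1M2inhib + Nd + Md)`, so macrophages stay
  pro-inflammatory exactly as long as there is debris to clear, then
  switch to the anti-inflammatory phenotype.
* **QSC**, **ASC**, **Mc** — the myogenic lineage. Quiescent satellite
  cells activate in response to neutrophils and damage, activated cells
  proliferate under M1 signals (`cASCpro ASC M1`), and M2 signals drive
  both differentiation into myocytes (`cASCdiff ASC M2`) and return to
  quiescence (`cASCM2 ASC M2`). Myocytes leave the model as they fuse
  into fibers (`cMcout Mc`); fibers themselves are not modeled.

Two structural facts are load-bearing and are verified by tests:

* **One-way coupling.** Immune populations influence the myogenic lineage
  but receive nothing back. The derivatives of `{Md, N, Nd, M, M1, M2}`
  are independent of the myogenic states and of the six satellite-cell
  constants, so the corresponding sensitivity blocks are exactly zero.
* **Structural non-negativity.** Every loss term of a variable contains
  that variable as a factor, so densities cannot cross zero. The package
  still clamps sub-nanocell negative round-off in reported trajectories.

The model is intended for the 7-day post-injury window only. There is no
homeostatic turnover (for example quiescent cells have no birth/death
absent injury), so extrapolating past day 7 is not meaningful and the
default integration span ends there.

## Parameters and their defaults

The 17 rate constants are all non-negative. `cM1M2inhib` is a saturation
constant in cells/mm^3; constants multiplying a single density are per
day, those multiplying a product of two densities are per day per
cell/mm^3. Two parameter vectors ship with the package:

* `heuristic_initial_estimates()` — order-of-magnitude starting values
  built from the data scales in `magnitude_scales()`: a bilinear constant
  is one over the assumed maximum of its partner variable (for example
  `cNMd = 1/1000` because calibrated neutrophils peak near 1000), an
  influx constant is the required daily flux over the driver magnitude
  (`cNin = 1000/30000`), first-order exit rates start at 1/day, and the
  M1-to-M2 pair starts at `cM1M2inhib = 1000` cells/mm^3 with
  `cM1M2 = 1000` so the conversion runs at about `M1` per day once debris
  is gone. Estimates are reported at five significant digits and each
  search interval spans a factor of 100 both ways — wide enough to matter,
  narrow enough to keep all constants positive and plausible.
* `fitted_rate_parameters()` — the published optimized values, which
  reproduce the headline trajectory features (neutrophil peak near 1000
  cells/mm^3 just before day 1; M1 peak near 7000 cells/mm^3 near day 2).

The default initial state (`default_initial_state()`) is the
strong-injury scenario: 30,000 damaged myonuclei, no dead neutrophils,
and the calibrated day-0 densities of the seven observable types.

## Calibration of proportions to densities

Annotated single-cell data yield counts per cell type per replicate, not
densities. The calibration anchors each day's composition to an external
flow-cytometry series for the monocyte/macrophage lineage: 100, 5000,
20000 and 5000 cells/mm^3 at days 0, 1, 3 and 7. `interpolate_reference()`
fills other days linearly (12,500 at days 2 and 5) with one deliberate
exception — day 3.5 reuses the day-3 value (20,000) rather than
interpolating, because the reference's day-3 measurement is taken to apply
to day-3.5 samples. No extrapolation outside the reference range is
allowed.

`calibrate_targets()` computes, per day, the scale factor
`S(d) = T(d) / P_lineage(d)` from the *cross-replicate mean* lineage
proportion, then `T_X(d) = S(d) mean(P_X(d))` and
`SD_X(d) = S(d) sd(P_X(d))`. Two choices here were genuinely open:

* the standard deviation is the sample (n − 1) statistic, the usual
  choice for a 3–4 replicate design (a day with a single replicate gets
  SD 0);
* replicate proportions are averaged unweighted rather than pooling raw
  counts, so a deeply sequenced replicate does not dominate a shallow one.

Days with no replicates are simply absent from the output rather than
imputed. The calibrated M + M1 + M2 total equals the reference series by
construction, which the tests assert exactly.

Because `Md` and `Nd` are invisible to single-cell assays, their only
targets are fixed single-cell values at day 7 (`T = 1` cell/mm^3 each),
encoding "debris is gone by a week". Note their normalization constant in
the error below is therefore 1, which gives these two terms weight
comparable to whole observable trajectories; `calibrate_targets()` lets
you drop them (`dead_cell_targets = FALSE`) to inspect their influence.

## The fitting error and optimizer

`fit_error()` simulates at the target days and evaluates

    E = sum_X sum_d |Sim_X(d) - T_X(d)| / max_d T_X(d),

an absolute-deviation error normalized per cell type so abundant
populations do not drown out rare ones. `fit_parameters()` minimizes `E`
with a bound-constrained Nelder-Mead simplex: candidate vertices are
clipped into the search box before evaluation (the same box handling used
by the reference simplex implementations that accept bounds), so every
evaluated vector is feasible. The default runs in linear parameter space
with the classical simplex coefficients and a budget of 10,000 error
evaluations; three options matter in practice:

* `log_scale = TRUE` searches in log-parameter space, sensible given the
  constants span about eight orders of magnitude;
* `adaptive = TRUE` uses dimension-scaled expansion/contraction/shrink
  coefficients, which behave markedly better in this 17-dimensional
  search;
* `restarts = n` rebuilds the simplex at the incumbent best point,
  sharing the evaluation budget, which rescues stalled searches.

A practical warning on identifiability: fitting noise-free targets
generated by a known parameter vector reliably collapses the error by
more than 95% from the initial estimates (a test asserts this), but it
does *not* recover the generating vector, and the residual error plateaus
well above the generating vector's own error. A local simplex method on a
17-parameter compartmental model with six time points has no business
finding a global optimum, and the model is not known to be identifiable;
treat fitted constants as a descriptive parameterization of the
trajectories, not as measured biology. For the same reason the published
optimized column should be viewed as *one* good fit, not *the* fit.

## Sensitivity analysis

`perturbation_sensitivity()` increases one constant at a time by 0.1%
(`rel_delta = 0.001`), re-simulates on the hourly grid, and stores the
difference from the unperturbed trajectory — parameters × 169 hourly
times, one matrix per population, each scaled by its own largest absolute
entry into [−1, 1] for heatmap display (blue −1, white 0, red +1 in
`autoplot()`/`export_sensitivity()`). Three conventions are explicit:

* stored values are raw trajectory differences; `derivative = TRUE`
  divides each row by the absolute perturbation instead. Within a matrix
  the two differ only by positive row factors, so signs and per-row shapes
  agree — only cross-parameter comparability changes;
* an all-zero matrix stays all-zero instead of producing 0/0 — the
  satellite-parameter rows of immune-cell matrices are structurally zero;
* differences below 1e-9 of the population's trajectory maximum are
  snapped to zero, a dead band that keeps solver round-off from
  manufacturing spurious signs near zero.

One empirical caution the tests document: at the published optimized
point, increasing the neutrophil engulfment constant `cNMd` *raises*
damaged-myonuclei numbers after about half a day. The constant sits at
its lower bound, so its direct clearance contribution is negligible; its
dominant effect is killing neutrophils, which starves the monocyte-to-M1
pipeline that performs most of the clearance. The effect is robust to the
perturbation size (it persists from 0.1% up to a hundred-fold increase),
so intuition about "engulfment up, debris down" does not hold at this
point of parameter space.

## The synthetic-data generator

`generate_ground_truth()` exists so the calibration-fitting-validation
pipeline can run, and be scored against a known truth, without any
external download. It emulates the *observation process* of the annotated
time series, not the sequencing itself:

* six sampling days {0, 1, 2, 3.5, 5, 7} with 4, 4, 3, 4, 3, 3
  replicates (the validation variant uses days {0, 2, 5, 7}, with no
  day-1 sample);
* 10,000–20,000 cells per replicate, of which a lumped "other" category
  (default 50%) stands in for all unmodeled cell types and is discarded
  before proportions are computed, mirroring the real pre-filtering step;
* cross-replicate composition noise is Dirichlet on the true proportions
  with concentration `dispersion * p_true`, and cells are then drawn
  multinomially. The default `dispersion = 30` puts cross-replicate
  standard deviations at several percentage points on mid-sized
  proportions — variability of the order the real replicates show.
  `dispersion = Inf` disables composition noise for oracle tests;
* reference lineage densities are the true simulated M + M1 + M2 values
  at days {0, 1, 3, 7}, optionally with lognormal noise.

What it does **not** emulate: transcript-level effects (UMIs, dropout,
doublets), annotation error, batch effects, or any distinction between
biological and technical replicate variability. Passing the recovery
tests therefore shows the *pipeline* is correct and reasonably robust to
composition noise; it says nothing about upstream annotation quality on
real data.

One subtlety the tests exploit: with the 4-day reference series, targets
at days 2, 5 and 3.5 are biased even at infinite sequencing depth,
because the true lineage trajectory is not piecewise linear and day 3.5
is not day 3. That bias is a property of the calibration method itself,
so the law-of-large-numbers oracle test sets `ref_days` to the sampling
days, where calibration is exactly invertible.

## Numerical choices

* **Integrator.** `deSolve` with `lsoda` by default: the day-0 transient
  (debris clearance runs at ~`cNin Md` ≈ 2700 cells/day into a pool of
  20) is fast enough that the automatic stiff/non-stiff switching is
  worth having, and it is about four times faster here than the explicit
  Dormand-Prince option (`method = "ode45"`), with agreement to ~3e-7
  relative. Defaults `rtol = 1e-6`, `atol = 1e-9` are tight enough that
  halving them moves observation-grid values by far less than 0.1% of
  each variable's maximum (tested); `loose = TRUE` restores the solver's
  native defaults.
* **Grid values** are obtained by requesting solver output exactly at the
  grid times, not by interpolating a coarse solution.
* **Clamping.** Reported densities below zero by round-off (never more
  than ~1e-9 in magnitude) are clamped to 0; anything below −1e-6 aborts
  as a solver failure. Clamping is applied to reported output only, never
  fed back into the integration state.
* **Degenerate denominator.** The M1-to-M2 term is defined as 0 whenever
  its numerator is 0, so an all-zero parameter or state vector does not
  produce 0/0; with `cM1M2inhib > 0` (as everywhere in the search box)
  the expression is evaluated exactly as written.
* **Peak ties** break to the earliest grid time, so constant or monotone
  trajectories peak at day 0 deterministically.
* **Test problem sizes.** The test suite verifies the adaptive solver
  against a fixed-step Euler oracle at step 1e-4 days on 20 random
  parameter/state draws (draws spanning an order of magnitude around the
  initial estimates, re-drawn if trajectories exceed 1e7 cells/mm^3,
  which keeps the explicit oracle inside its stability region);
  self-consistency fits use a 2,000-evaluation budget and the end-to-end
  recovery test 4,000 evaluations with one restart — enough to
  demonstrate the contracts while keeping the default suite around three
  minutes on one CPU.

## Known limitations

* Single spatial compartment, no delays, no re-injury, no myofiber
  compartment: myocyte fusion is an outflux, so late-stage regeneration
  (day 5–7 myocyte counts) is systematically conservative.
* The fitted parameterization is not unique (see above); uncertainty
  quantification (profile likelihood, bootstrap) is deliberately out of
  scope.
* Sensitivity analysis is local and one-at-a-time; it ranks influence
  near the fitted point only and cannot see interactions a global method
  (Sobol, Morris) would.
* The day-7 dead-cell targets carry a large implicit weight in `E`
  (normalization by 1); whether that is biologically proportionate is a
  modeling judgment the user can toggle.
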