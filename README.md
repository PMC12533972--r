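# myoregen

An R package for modeling cell-population dynamics during skeletal muscle
regeneration after acute injury. It is aimed at quantitative biologists
who want to connect annotated single-cell time-series data (cell-type
counts per replicate per day) to an interpretable mechanistic model of
the injury response: debris clearance by neutrophils and macrophages, the
pro- to anti-inflammatory macrophage switch, and satellite-cell
activation, proliferation, differentiation and return to quiescence.

## The model

Nine populations in one cubic millimeter of tissue — damaged myonuclei
(Md), neutrophils (N), dead neutrophils (Nd), monocytes (M), M1 and M2
macrophages, quiescent (QSC) and activated (ASC) satellite cells, and
myocytes (Mc) — evolve over days post-injury by coupled ODEs:

    dMd/dt  = -cNMd N Md - cM1Md M1 Md
    dN/dt   =  cNin Md - cNout N - cNMd N Md
    dNd/dt  =  cNMd N Md - cM1Nd M1 Nd
    dM/dt   =  cMin N - cMM1 M (Nd + Md) - cMout M
    dM1/dt  =  cMM1 M (Nd + Md) - cM1M2 M1 / (cM1M2inhib + Nd + Md)
    dM2/dt  =  cM1M2 M1 / (cM1M2inhib + Nd + Md) - cM2out M2
    dQSC/dt = -cQSCN QSC N - cQSCMd QSC Md + cASCM2 ASC M2
    dASC/dt =  cQSCN QSC N + cQSCMd QSC Md - cASCM2 ASC M2
               + cASCpro ASC M1 - cASCdiff ASC M2
    dMc/dt  =  cASCdiff ASC M2 - cMcout Mc

Injury is an initial condition (Md(0) = 30,000 for a strong injury); the
M1-to-M2 switch is *inhibited* while dead material remains; and the
coupling is one-way, immune to myogenic. Around the core model the
package provides:

* **Calibration** — convert per-replicate cell-type proportions to
  absolute densities using a reference monocyte/macrophage-lineage series
  (100, 5000, 20000, 5000 cells/mm^3 at days 0, 1, 3, 7; linearly
  interpolated in between, day 3.5 reusing the day-3 value).
* **Fitting** — order-of-magnitude initial estimates with a 100-fold
  search box, and bound-constrained Nelder-Mead minimization of the
  normalized absolute-deviation error
  `E = sum_X sum_d |Sim_X(d) - T_X(d)| / max_d T_X(d)`.
* **Sensitivity** — one-at-a-time 0.1% parameter perturbations on an
  hourly grid, normalized per cell type to [-1, 1], with heatmap and CSV
  export.
* **Synthetic data** — a Dirichlet-multinomial generator reproducing the
  replicate structure of the real studies (3–4 replicates at days 0, 1,
  2, 3.5, 5, 7; 10–20k cells per library, half unmodeled types), used for
  end-to-end parameter-recovery validation.

## Worked example

```r
library(myoregen)

# simulate the fitted model from the strong-injury initial state
traj <- simulate_regeneration(fitted_rate_parameters(),
                              default_initial_state(), grid = "hourly")
summarize_peaks(traj)
#> # A tibble: 9 × 3
#>   cell_type peak_value peak_time
#>   <chr>          <dbl>     <dbl>
#> 1 Md            30000      0
#> 2 N              1095.     0.875
#> 3 Nd              141.     1
#> 4 M              5069.     1.38
#> 5 M1             7051.     1.79
#> 6 M2             6038.     7
#> 7 QSC            2105.     7
#> 8 ASC             914.     3.5
#> 9 Mc              247.     5.04
```

The peak table reads off the inflammatory cascade: neutrophils surge to
about 1100 cells/mm^3 just before day 1, monocytes and M1 macrophages
follow (M1 peaking around 7000 cells/mm^3 near day 2), the
anti-inflammatory M2 pool builds through day 7, and activated satellite
cells crest near day 3.5 as proliferation hands over to differentiation
and return to quiescence.

A full pipeline run on synthetic data:

```r
gt      <- generate_ground_truth(fitted_rate_parameters(),
                                 default_initial_state(),
                                 synthetic_study_config(seed = 7))
targets <- calibrate_targets(proportions_from_counts(gt$counts),
                             gt$reference)
fit     <- fit_parameters(heuristic_initial_estimates(), targets,
                          default_initial_state(),
                          max_evals = 4000, restarts = 1, adaptive = TRUE)
glance(fit)        # final error, error at the initial estimates, reduction
tidy(fit)          # per-parameter estimate with bounds
autoplot(perturbation_sensitivity(fit$parameters,
                                  default_initial_state()))
```

See the vignette (`vignettes/regeneration-model.Rmd`) for the model's
assumptions, the calibration and error-function conventions, and known
limitations.

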