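# nanocascade

Analysis toolkit for experiments on glucose-powered nanozyme particles —
gold-on-silica colloids whose surface catalyses a two-step cascade: glucose
oxidation producing hydrogen peroxide, and H2O2 decomposition to water and
oxygen. Such particles act simultaneously as self-propelled "nanorobots"
(fuel-enhanced diffusion) and as in-situ generators of a steady-state H2O2
signal that modulates cell migration and proliferation. The package is for
researchers who have the instrument-derived tables from these assays —
kinetic time courses, tracker exports, intensity profiles, masks, phase
maps — and need the quantitative pipeline between those tables and the
reported numbers.

Four analysis families are implemented, plus seeded generators that
synthesise every input so the whole pipeline is testable without data:

* **Cascade kinetics** — Michaelis–Menten production
  (v = Vmax·[S]/(Km+[S])) coupled to Hill-type decomposition
  (v = Vmax·[S]^h/(K0.5^h+[S]^h)) on one catalyst; ODE simulation;
  initial-rate estimation from 3/6/9-min incubations; nonlinear
  least-squares fits with standard errors; and the pseudo-order reduction
  d[H2O2]/dt = k1 − k2[H2O2], whose steady state is [H2O2]ss = k1/k2, with
  configurable catalyst-scaling exponents for the two half-reactions.
* **Enhanced diffusion** — drift correction of particle-tracking
  ensembles, time-averaged mean squared displacement, first-second linear
  fits (D_eff = slope/4 in 2D) with honest between-track confidence
  intervals, and percent enhancement between fuel conditions.
* **Diffusiophoresis** — lateral shift of microfluidic co-flow
  fluorescence profiles via windowed intensity centroids.
* **Cell responses** — random-walk motility summaries
  (displacement, distance, directionality, speed, velocity), wound-healing
  gap-closure series, shape circularity, QPI dry mass
  (m = φλ/(2πα)), and exponential doubling-time fits on log2-scale.

Everything takes and returns tidy tibbles, pipes chain the stages, fitted
objects support `tidy()`/`glance()`, and result types have
`autoplot()` methods.

## Worked example

Fit glucose-oxidation kinetics from noisy initial rates over the assay's
six concentrations:

```r
library(nanocascade)

grid <- c(1, 2.5, 5, 10, 20, 30)                      # mM glucose
set.seed(1)
rates <- mm_rate(mm_kinetics(0.42, 2.9), grid) * (1 + rnorm(6, 0, 0.03))
fit <- fit_mm(tibble::tibble(substrate_conc = grid, initial_rate = rates))
fit
#> <Michaelis-Menten fit>
#>   v_max  = 0.420312 (se 0.00992)
#>   k_m    = 2.88311 (se 0.258)
#>   R^2 = 0.99329 on 6 points
```

The fitted Km of 2.88 mM recovers the generating value (2.9 mM) well
inside its standard error; `tidy(fit)` returns the same numbers as a
tibble.

Estimate an effective diffusion coefficient from a simulated
nanoparticle-tracking experiment (250 tracks, 25 fps, 60 s, the standard
acquisition):

```r
tracks <- gen_brownian_tracks(track_sim_spec(
  n_tracks = 250, diffusion_coeff = 21.19, frame_rate = 25, duration = 60,
  seed = 7))

tracks |>
  drift_correct() |>
  compute_msd(max_lag = 1) |>
  fit_diffusion(fit_window = 1)
#> <diffusion_fit> D_eff = 21.2 um^2/s (95% CI 20.89-21.51, between-track, n = 250)
#>   intercept -0.01773 um^2, window 1 s, 25 lags

percent_enhancement(29.29, 21.19)
#> [1] 38.22558
```

The first-second MSD fit recovers the generating D (21.19 um^2/s) inside
its 95% CI; the enhancement helper turns a condition/control pair of D
values into the percent change (here ~38%).

Doubling time from a noisy growth series, and the percent-of-control
convention:

```r
growth <- gen_growth_series(100, 16.8, seq(0, 24, by = 0.5),
                            noise_spec("proportional-gaussian", 0.05),
                            seed = 5)
fit_doubling_time(growth)
#> <doubling_fit> T2 = 16.63 h (95% CI 15.8-17.56), R^2 = 0.9685, n = 49

percent_of_control(12.9, 16.8)  # 76.8 -> "77% of control"
```

A full demonstration pipeline (synthesis through reports, with a
reproducibility manifest) runs from the shipped configuration:

```r
cfg <- system.file("extdata", "demo-config.yaml", package = "nanocascade")
run_pipeline(cfg, out_dir = "demo-out")
```

The methods vignette (`vignettes/nanocascade-methods.Rmd`) documents the
models, numerical choices, and what the synthetic data do and do not
emulate.

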