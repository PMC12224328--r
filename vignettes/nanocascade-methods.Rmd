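---
title: "Models and methods behind nanocascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanocascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocascade)
```

nanocascade analyses experiments on glucose-powered nanozyme particles —
gold-on-silica colloids that catalyse two coupled reactions on one surface:
glucose oxidation producing H2O2, and H2O2 decomposition to water and
oxygen. The package covers four analysis families (cascade kinetics,
single-particle diffusion, microfluidic diffusiophoresis, and cell-scale
responses) plus seeded generators that synthesise every input the analyses
consume. This vignette records the models, the numerical choices, and the
limits of what the synthetic data can demonstrate.

## The cascade model and its steady state

Glucose oxidation follows hyperbolic Michaelis–Menten kinetics,

$$v_p = V_{max,p}\,\frac{[G]}{K_m + [G]},$$

while H2O2 decomposition is sigmoidal (allosteric) with Hill slope $h$,

$$v_d = V_{max,d}\,\frac{[H]^h}{K_{0.5}^h + [H]^h}.$$

The two half-reactions live on one catalyst, so both rates scale with
catalyst concentration $C$. We parameterise that scaling as
$(C/C_{ref})^a$ for production and $(C/C_{ref})^b$ for decomposition
(`cascade_model()`, exponents `production_catalyst_exponent` and
`decomposition_catalyst_exponent`). The full state equation integrated by
`simulate_cascade()` is

$$\frac{d[H]}{dt} = v_p(G)\Big(\tfrac{C}{C_{ref}}\Big)^a -
  v_d(H)\Big(\tfrac{C}{C_{ref}}\Big)^b, \qquad
  \frac{d[G]}{dt} = -v_p(G)\Big(\tfrac{C}{C_{ref}}\Big)^a,$$

with glucose optionally held constant (fed assays).

At fixed glucose and $[H] \ll K_{0.5}$ the system reduces to
$d[H]/dt = k_1 - k_2[H]$ with pseudo-zero-order production
$k_1 = v_p(G)\,(C/C_{ref})^a$ and first-order decomposition
$k_2 = (V_{max,d}/K_{0.5})\,(C/C_{ref})^b$
(`pseudo_order_reduction()`), whose fixed point is the steady-state
concentration $[H]_{ss} = k_1/k_2$ (`steady_state_analytic()`). The
linearisation of the Hill law at the origin is exact only at $h = 1$; for
$h \neq 1$ the reduction is returned with a warning flag rather than a
different formula, because the assays it summarises operate far below
$K_{0.5}$.

The catalyst exponents are the model's deliberate degree of freedom. If
$a = b$, the ratio $k_1/k_2$ cancels the catalyst dependence and the steady
state is flat in $C$; observing instead a monotone (near-linear) rise of
steady-state H2O2 with catalyst loading implies $b < a$ — decomposition
saturating or otherwise lagging production. The default ($a = 1$,
$b = 0.5$) encodes that asymmetric regime while keeping both limiting cases
one argument away; `steady_state_scan()` quantifies the dependence with a
straight-line fit and reports convergence per point ($|dH/dt| <$ 1e-6
mM/min at the end of the horizon).

Numerics: `deSolve::lsoda` at relative tolerance 1e-8, absolute 1e-10 mM;
states are clipped at zero on output (the vector field already keeps them
non-negative up to solver error). Units are fixed internally at mM and
minutes, the scales of the underlying plate-reader assays (3/6/9-minute
incubations, mM substrates).

## Saturation-kinetics fitting

Initial rates come from short incubations: consumed substrate
$y(t) = c(0) - c(t)$ at $t$ = 3, 6, 9 min, fitted by least squares
**through the origin** ($\hat v = \sum t_i y_i / \sum t_i^2$), since
consumption is definitionally zero at $t = 0$ (`estimate_initial_rates()`).
Courses whose substrate rises over time are flagged, not dropped.

`fit_mm()` and `fit_hill()` use bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`). Start values follow a deterministic recipe —
$V_{max}^{(0)} = 1.2\times$ the largest observed rate, $K^{(0)}$ at the
substrate concentration whose rate is closest to half the maximum,
$h^{(0)} = 1.5$ with bounds $h \in (0.1, 10]$ — which converges from
noiseless data to the generating parameters to 1e-6 relative (asserted in
the tests). Non-convergence is an explicit `converged = FALSE` result.
Asymptotic standard errors and $R^2$ accompany every fit; `tidy()` and
`glance()` give tabular views.

## Diffusion from particle tracks

Nanoparticle-tracking videos yield in-plane trajectories at 25 frames/s for
60 s. The pipeline is:

1. **Drift correction** (`drift_correct()`): external flow is estimated as
   the ensemble mean frame-to-frame displacement across all tracks present
   in consecutive frames, accumulated into a drift path and subtracted.
   This estimator is robust to heterogeneous track lengths, unlike
   averaging per-track velocities. Intervals with fewer than 3
   simultaneous tracks get linearly interpolated drift (flagged); a single
   track is returned unchanged with a warning. The correction is
   idempotent.
2. **Time-averaged MSD** (`compute_msd()`): per track, all ordered pairs at
   each lag; the ensemble curve is the unweighted mean over tracks
   (track-length weighting is available), with per-lag SEM across tracks.
3. **Linear fit** (`fit_diffusion()`): ordinary least squares of mean MSD
   versus lag over the first second, with a free intercept that absorbs
   static localisation noise; $D_{eff}$ = slope/4 for two dimensions. A
   negative slope is reported with a flag, never clamped.

The confidence interval deserves a note. The mean-curve residuals are
strongly correlated across lags (every lag shares the same tracks), so an
OLS residual-based slope standard error is not a trustworthy uncertainty.
Because least squares is linear in the response and the ensemble curve is
the unweighted mean of per-track curves, the ensemble slope **equals** the
mean of per-track slopes; `fit_diffusion()` therefore takes the 95% CI
from the between-track dispersion of those per-track slopes (a
t-interval over independent tracks), falling back to the OLS formula only
when per-track curves are unavailable. Simulated ensembles show this
interval covers the generating $D$ at close to the nominal rate, which the
test suite checks across 200 replicate ensembles (60 tracks of 10 s each —
coverage is a property of the interval construction, not the ensemble
size; the headline 250-track, 60-s condition is exercised separately).

Enhancement between conditions is reported as
$100\,(D_{cond} - D_{ctrl})/D_{ctrl}$ (`percent_enhancement()`).

## Microfluidic profile shifts

In a three-inlet co-flow channel, diffusiophoresis shows up as a lateral
displacement of the particle stream's fluorescence profile. The estimator
(`profile_shift()`) is the difference of intensity-weighted centroids,
condition minus control, inside an analysis window (default: the central
2.5 mm, configurable). A centroid recovers a pure translation exactly for
any profile shape and degrades gracefully under noise, which is why it was
chosen over half-maximum edge crossings; the literature rarely states its
shift metric explicitly, so the choice is recorded here as a package
decision. Positions are oriented increasing toward the solute inlet, so
migration toward the solute is positive. Profiles on different grids are
linearly resampled onto the control grid first.

The generator (`gen_flow_profiles()`) builds the stream as a central plug
convolved to error-function edges with scale `smoothing_length`
(transverse diffusion during transit), translated by the true shift —
defaults: 3000 um channel, 1000 um stream, 50 um edge scale, 5 um grid.

## Cell-scale analytics

* **Motility** (`motility_summary()`, `population_motility()`): net
  displacement, total distance, directionality (net/total — the standard
  definition, stated explicitly because assay reports often leave it
  implicit), mean speed (distance/time) and mean velocity (net/time).
  Population errors follow the assay convention: SEM for displacement and
  distance, SD for the rest.
* **Gap closure** (`relative_gap_area()`): gap area per frame as foreground
  pixels times pixel area, normalised to the first frame. A minimal
  texture-based segmenter (`segment_gap()`: local variance, Gaussian
  smoothing, Otsu threshold, largest smooth component) stands in for
  interactive wound-healing tools when only images are available; it is a
  deliberate simplification, not a re-implementation of any specific tool.
* **Circularity** (`circularity()`): $4\pi A/P^2$ with the perimeter from a
  lightly smoothed marching-squares contour. Smoothing before contouring
  removes the staircase bias that would otherwise inflate a circle's
  perimeter by about 5%; residual raster bias motivates the ±0.05
  tolerance used in tests.
* **QPI dry mass** (`dry_mass()`): per-pixel density
  $m = \phi \lambda / (2\pi\alpha)$ with $\alpha$ = 0.18 um^3/pg, summed
  over pixels. `gen_phase_image()` inverts the same relation to synthesise
  phase maps; overlapping discs add phase, as stacked material does.
* **Doubling time** (`fit_doubling_time()`): least squares on
  $\log_2(\text{value})$ versus time; doubling time is the reciprocal
  slope, with the CI propagated from the slope's. The log transform
  stabilises multiplicative noise and gives a closed-form interval; on
  noiseless data it coincides with a direct exponential fit. A
  non-positive slope yields an explicit "no growth" result with an
  unbounded doubling time.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and seed
(`withr::with_seed`), so all downstream analyses are testable bit-for-bit
without instrument data. The default conditions mirror the study's
protocols: 250 tracks at 25 fps for 60 s; cells sampled every 30 min over
24 h; a 500 um starting gap; glucose grid 1–30 mM and H2O2 grid 0.1–1 M
with 3/6/9-min incubations; doubling time 16.8 h.

Noise is a single family — Gaussian, either additive (`sd` in signal
units) or proportional (`sd` as a fraction, the multiplicative-equivalent
used for growth series that span decades) — because the source assays
report replicate SDs but no noise model; magnitudes used in tests (3–5%)
are conventions chosen to resemble plate-reader and imaging replicates,
not measured values.

The persistent random walk uses fixed step length `mean_speed * dt` and
von Mises heading increments whose concentration solves
$I_1(\kappa)/I_0(\kappa) = e^{-\Delta t / P}$, giving heading
autocorrelation $e^{-t/P}$ with persistence time $P$. This is the simplest
walk exposing exactly the two parameters the motility summaries estimate;
it does not model speed fluctuations, cell–cell interactions, or
confinement. Likewise, Brownian tracks have no localisation error or
blinking, gap masks have no cell-front morphology beyond smoothed Gaussian
roughness, and phase images contain ideal discs. Passing tests therefore
demonstrate estimator correctness under the stated generative models —
not robustness to every artefact of real instruments.

## Orchestration

`run_pipeline()` executes any subset of the stages (simulate,
fit-kinetics, analyze-tracks, analyze-profiles, analyze-motility,
analyze-gap, analyze-growth) from one configuration list or YAML/JSON
file. All randomness derives from the single global seed through fixed
per-stage offsets; a manifest records the configuration hash, seed,
package version, and per-stage status with output basenames, so the same
configuration reproduces every output byte-for-byte. Stage names are
validated before anything runs; failures are collected per stage and
raised together. A complete demonstration configuration ships at
`system.file("extdata", "demo-config.yaml", package = "nanocascade")`.

## Known limitations

* The cascade model books no oxygen or gluconolactone, no pH or
  temperature dependence, and no surface-site microkinetics; catalyst
  scaling is a phenomenological power law.
* Intracellular catalase adds to H2O2 decomposition in cell media; the
  model treats that as outside its scope rather than as an extra `k2`
  term.
* The MSD fit assumes normal diffusion over the fit window; no anomalous
  exponent is estimated.
* `segment_gap()` and `circularity()` operate on reasonably clean masks;
  they are not a general cell-segmentation stack.
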