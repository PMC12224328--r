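#' Synthetic cascade assay time course
#'
#' Samples the cascade ODE solution (see [simulate_cascade()]) at the
#' requested times and perturbs both concentration series with the noise
#' spec, clipping at zero — the observable of a plate-reader kinetic assay.
#'
#' @param model A [cascade_model()].
#' @param catalyst_conc Catalyst concentration, mg/mL.
#' @param glucose0,h2o2_0 Initial concentrations, mM (>= 0).
#' @param times Sampling times, minutes; strictly increasing, all >= 0.
#' @param noise A [noise_spec()].
#' @param seed RNG seed.
#' @param glucose_depletion Integrate glucose consumption (default) or hold
#'   glucose constant.
#' @return A tibble `time`, `glucose`, `h2o2` (mM) with `catalyst_conc`
#'   stored as a column.
#' @export
gen_cascade_timecourse <- function(model, catalyst_conc, glucose0, h2o2_0,
                                   times, noise = noise_spec(), seed = 1L,
                                   glucose_depletion = TRUE) {
  if (glucose0 < 0 || h2o2_0 < 0) abort("Initial concentrations must be >= 0.")
  if (any(times < 0) || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing and >= 0.")
  }
  ode_times <- if (times[1] > 0) c(0, times) else times
  traj <- simulate_cascade(model, catalyst_conc, glucose0, h2o2_0,
                           t_end = max(times), glucose_depletion = glucose_depletion,
                           times = ode_times)
  traj <- traj[match(times, traj$time), ]
  withr::with_seed(seed, {
    traj$glucose <- pmax(apply_noise(traj$glucose, noise), 0)
    traj$h2o2 <- pmax(apply_noise(traj$h2o2, noise), 0)
  })
  traj$catalyst_conc <- catalyst_conc
  traj
}

#' Synthetic exponential growth series
#'
#' Generates `n0 * 2^(t / doubling_time)` at the requested times, perturbed
#' by the noise spec and floored at a small positive value (observations of
#' cell counts or total dry mass are positive).
#'
#' @param n0 Initial count or dry mass (> 0), pg for mass.
#' @param doubling_time Doubling time, h (> 0).
#' @param times Sampling times, h.
#' @param noise A [noise_spec()]; use `"proportional-gaussian"` for
#'   multiplicative-equivalent noise.
#' @param seed RNG seed.
#' @return A tibble `time` (h), `value`.
#' @examples
#' s <- gen_growth_series(100, 16.8, seq(0, 24, by = 0.5))
#' fit_doubling_time(s)$doubling_time  # 16.8 exactly
#' @export
gen_growth_series <- function(n0, doubling_time, times,
                              noise = noise_spec(), seed = 1L) {
  if (n0 <= 0) abort("`n0` must be > 0.")
  if (doubling_time <= 0) abort("`doubling_time` must be > 0.")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  value <- n0 * 2^(times / doubling_time)
  withr::with_seed(seed, {
    value <- pmax(apply_noise(value, noise), 1e-9 * n0)
  })
  tibble::tibble(time = times, value = value)
}
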