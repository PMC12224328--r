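#' Simulate 2D Brownian tracks with optional drift
#'
#' Each track has `duration * frame_rate + 1` points starting at the origin;
#' per-axis displacements per frame are Gaussian with mean
#' `drift_velocity * dt` and variance `2 * D * dt` (`dt = 1/frame_rate`).
#' Identical specs (including seed) reproduce identical tables.
#'
#' @param spec A [track_sim_spec()].
#' @return A tidy track table: `track_id`, `frame` (0-based), `time` (s),
#'   `x`, `y` (um), with the spec stored in the `sim_spec` attribute.
#' @examples
#' tracks <- gen_brownian_tracks(track_sim_spec(n_tracks = 5, duration = 2))
#' @export
gen_brownian_tracks <- function(spec) {
  if (!inherits(spec, "track_sim_spec")) abort("`spec` must be a track_sim_spec.")
  dt <- 1 / spec$frame_rate
  n_steps <- round(spec$duration * spec$frame_rate)
  sd_step <- sqrt(2 * spec$diffusion_coeff * dt)
  withr::with_seed(spec$seed, {
    tracks <- purrr::map(seq_len(spec$n_tracks), function(id) {
      dx <- rnorm(n_steps, spec$drift_velocity[1] * dt, sd_step)
      dy <- rnorm(n_steps, spec$drift_velocity[2] * dt, sd_step)
      tibble::tibble(
        track_id = id,
        frame = 0:n_steps,
        time = (0:n_steps) * dt,
        x = c(0, cumsum(dx)),
        y = c(0, cumsum(dy))
      )
    })
  })
  out <- dplyr::bind_rows(tracks)
  attr(out, "sim_spec") <- spec
  out
}

#' Synthetic co-flow intensity-profile pair
#'
#' Emulates the lateral fluorescence profile of a particle stream in a
#' three-inlet co-flow channel: a central plug of width `stream_width` whose
#' edges are error-function shaped with scale `smoothing_length` (transverse
#' diffusion during transit). The condition profile is the base profile
#' translated by `true_shift` toward the solute side (positive positions
#' point toward the solute inlet); both are normalised to unit maximum.
#'
#' @param true_shift Lateral displacement of the condition profile, um;
#'   `|true_shift| < channel_width / 2`.
#' @param channel_width Channel width, um.
#' @param stream_width Width of the particle stream plug, um
#'   (< `channel_width`).
#' @param smoothing_length Error-function edge scale, um (> 0).
#' @param noise A [noise_spec()] applied to both profiles.
#' @param seed RNG seed (used only when noise is active).
#' @param grid_spacing Lateral sampling interval, um.
#' @return A list with elements `control` and `shifted`, both
#'   [intensity_profile()] objects.
#' @examples
#' pr <- gen_flow_profiles(true_shift = 214.4)
#' profile_shift(pr$shifted, pr$control)
#' @export
gen_flow_profiles <- function(true_shift, channel_width = 3000,
                              stream_width = 1000, smoothing_length = 50,
                              noise = noise_spec(), seed = 1L,
                              grid_spacing = 5) {
  if (abs(true_shift) >= channel_width / 2) {
    abort("`true_shift` must satisfy |true_shift| < channel_width / 2.")
  }
  if (stream_width >= channel_width) {
    abort("`stream_width` must be smaller than `channel_width`.")
  }
  if (smoothing_length <= 0) abort("`smoothing_length` must be > 0.")
  x <- seq(0, channel_width, by = grid_spacing)
  plug <- function(center) {
    pnorm(x, center - stream_width / 2, smoothing_length) -
      pnorm(x, center + stream_width / 2, smoothing_length)
  }
  center <- channel_width / 2
  base <- plug(center)
  moved <- plug(center + true_shift)
  withr::with_seed(seed, {
    base <- pmax(apply_noise(base, noise), 0)
    moved <- pmax(apply_noise(moved, noise), 0)
  })
  list(control = intensity_profile(x, base),
       shifted = intensity_profile(x, moved))
}

#' Simulate persistent-random-walk cell tracks
#'
#' Cells take steps of fixed length `mean_speed * sampling_interval` with
#' headings that start uniform and decorrelate with time constant
#' `persistence_time` (von Mises heading increments; see [cell_sim_spec()]).
#' The empirical mean speed equals `mean_speed` by construction.
#'
#' @param spec A [cell_sim_spec()].
#' @return A tidy track table: `cell_id`, `time` (h), `x`, `y` (um), with
#'   the spec in the `sim_spec` attribute.
#' @export
gen_cell_tracks <- function(spec) {
  if (!inherits(spec, "cell_sim_spec")) abort("`spec` must be a cell_sim_spec.")
  dt <- spec$sampling_interval
  n_steps <- floor(spec$duration / dt + 1e-9)
  step_len <- spec$mean_speed * dt
  rho <- exp(-dt / spec$persistence_time)
  kappa <- kappa_from_rho(rho)
  withr::with_seed(spec$seed, {
    tracks <- purrr::map(seq_len(spec$n_cells), function(id) {
      theta <- runif(1, 0, 2 * pi) + cumsum(c(0, rvonmises(n_steps - 1L, kappa)))
      tibble::tibble(
        cell_id = id,
        time = (0:n_steps) * dt,
        x = c(0, cumsum(step_len * cos(theta))),
        y = c(0, cumsum(step_len * sin(theta)))
      )
    })
  })
  out <- dplyr::bind_rows(tracks)
  attr(out, "sim_spec") <- spec
  out
}
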