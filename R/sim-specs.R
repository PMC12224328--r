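#' Brownian track simulation settings
#'
#' Conditions of a nanoparticle-tracking recording: by default 250 tracks at
#' 25 frames/s for 60 s, matching a standard NTA acquisition, with optional
#' uniform drift.
#'
#' @param n_tracks Number of tracks (>= 1).
#' @param diffusion_coeff Diffusion coefficient D, um^2/s (>= 0).
#' @param frame_rate Frames per second (> 0).
#' @param duration Recording length, s (> 0).
#' @param drift_velocity Length-2 uniform drift `(vx, vy)`, um/s.
#' @param seed RNG seed for the generator.
#' @return A `track_sim_spec` object.
#' @export
track_sim_spec <- function(n_tracks = 250L, diffusion_coeff = 21.19,
                           frame_rate = 25, duration = 60,
                           drift_velocity = c(0, 0), seed = 1L) {
  if (n_tracks < 1) abort("`n_tracks` must be >= 1.")
  if (diffusion_coeff < 0) abort("`diffusion_coeff` must be >= 0.")
  if (frame_rate <= 0) abort("`frame_rate` must be > 0.")
  if (duration <= 0) abort("`duration` must be > 0.")
  if (length(drift_velocity) != 2L) abort("`drift_velocity` must have length 2.")
  structure(list(n_tracks = as.integer(n_tracks),
                 diffusion_coeff = diffusion_coeff, frame_rate = frame_rate,
                 duration = duration, drift_velocity = drift_velocity,
                 seed = as.integer(seed)),
            class = "track_sim_spec")
}

#' Cell random-walk simulation settings
#'
#' Conditions of a time-lapse motility assay: by default centroids sampled
#' every 30 min over 24 h. Cells move as a persistent random walk with fixed
#' step length `mean_speed * sampling_interval` and heading increments drawn
#' from a von Mises distribution whose concentration is set so the heading
#' autocorrelation decays as `exp(-t / persistence_time)`.
#'
#' @param n_cells Number of cells (>= 1).
#' @param mean_speed Mean speed, um/h (>= 0).
#' @param persistence_time Heading decorrelation time, h (> 0; `Inf` gives
#'   straight, ballistic tracks).
#' @param sampling_interval Sampling interval, h.
#' @param duration Assay duration, h (>= sampling_interval).
#' @param seed RNG seed.
#' @return A `cell_sim_spec` object.
#' @export
cell_sim_spec <- function(n_cells = 30L, mean_speed = 10,
                          persistence_time = 2, sampling_interval = 0.5,
                          duration = 24, seed = 1L) {
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  if (mean_speed < 0) abort("`mean_speed` must be >= 0.")
  if (persistence_time <= 0) abort("`persistence_time` must be > 0.")
  if (sampling_interval <= 0 || sampling_interval > duration) {
    abort("`sampling_interval` must be positive and <= `duration`.")
  }
  structure(list(n_cells = as.integer(n_cells), mean_speed = mean_speed,
                 persistence_time = persistence_time,
                 sampling_interval = sampling_interval, duration = duration,
                 seed = as.integer(seed)),
            class = "cell_sim_spec")
}

# von Mises concentration kappa with mean resultant length rho:
# solves I1(kappa)/I0(kappa) = rho.
kappa_from_rho <- function(rho) {
  if (rho >= 1 - 1e-9) return(Inf)
  if (rho <= 1e-12) return(0)
  a_ratio <- function(k) {
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  }
  if (rho > 0.999) return(1 / (2 * (1 - rho)))  # large-kappa asymptote
  uniroot(function(k) a_ratio(k) - rho, interval = c(1e-8, 1e4),
          tol = 1e-10)$root
}

# Best & Fisher (1979) rejection sampler for von Mises(0, kappa).
rvonmises <- function(n, kappa) {
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1L
    }
  }
  out
}
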