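#' Synthetic wound-healing gap masks
#'
#' Builds one binary mask per time point with a central cell-free vertical
#' band of width `max(0, initial_gap - closure_rate * t)` (a linearly closing
#' scratch). Edge roughness perturbs each row's left and right front
#' positions with Gaussian jitter smoothed over 10 consecutive rows, giving
#' ragged but spatially coherent fronts. Mask value 1 marks the gap.
#'
#' @param initial_gap Starting gap width, um (<= frame width).
#' @param closure_rate Closure speed, um/h (total front advance).
#' @param times Observation times, h.
#' @param frame `c(width, height)` of the field of view, um.
#' @param pixel_size Pixel edge length, um (> 0).
#' @param edge_roughness Gaussian jitter scale of the fronts, um.
#' @param seed RNG seed.
#' @return A list of binary matrices (rows = y, columns = x).
#' @export
gen_gap_masks <- function(initial_gap = 500, closure_rate = 25, times,
                          frame = c(1500, 1000), pixel_size = 5,
                          edge_roughness = 0, seed = 1L) {
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  if (initial_gap > frame[1]) abort("`initial_gap` exceeds the frame width.")
  ncol_ <- round(frame[1] / pixel_size)
  nrow_ <- round(frame[2] / pixel_size)
  x_centers <- (seq_len(ncol_) - 0.5) * pixel_size
  cx <- frame[1] / 2
  smooth10 <- function(v) {
    as.numeric(stats::filter(v, rep(1 / 10, 10), sides = 2, circular = TRUE))
  }
  withr::with_seed(seed, {
    masks <- purrr::map(times, function(t) {
      gap <- max(0, initial_gap - closure_rate * t)
      if (gap == 0) return(matrix(0L, nrow_, ncol_))
      jl <- jr <- numeric(nrow_)
      if (edge_roughness > 0) {
        jl <- smooth10(rnorm(nrow_, 0, edge_roughness))
        jr <- smooth10(rnorm(nrow_, 0, edge_roughness))
      }
      left <- cx - gap / 2 + jl
      right <- cx + gap / 2 + jr
      mask <- matrix(0L, nrow_, ncol_)
      for (i in seq_len(nrow_)) {
        mask[i, x_centers >= left[i] & x_centers < right[i]] <- 1L
      }
      mask
    })
  })
  masks
}

#' Synthetic quantitative-phase image of disc-shaped cells
#'
#' Inverts the QPI dry-mass relation to synthesise a phase image: inside
#' each disc the phase is \eqn{\phi = 2 \pi \alpha m / \lambda} for that
#' disc's dry-mass density `m`; overlapping discs add their phases (the
#' optical path lengths of stacked material are additive); background is 0.
#'
#' @param cells A data frame with columns `x`, `y` (disc centers, um),
#'   `radius` (um) and `density` (dry-mass density, pg/um^2); may be empty.
#' @param wavelength Imaging wavelength, um (> 0).
#' @param alpha Specific refraction increment, um^3/pg (> 0).
#' @param shape `c(nrow, ncol)` of the image, pixels.
#' @param pixel_size Pixel edge length, um.
#' @return A [phase_map()] object.
#' @examples
#' cells <- tibble::tibble(x = 50, y = 50, radius = 20, density = 3.611)
#' pm <- gen_phase_image(cells, shape = c(100, 100), pixel_size = 1)
#' dry_mass(pm)$total
#' @export
gen_phase_image <- function(cells, wavelength = 0.65, alpha = 0.18,
                            shape = c(256, 256), pixel_size = 0.5) {
  if (wavelength <= 0) abort("`wavelength` must be > 0.")
  if (alpha <= 0) abort("`alpha` must be > 0.")
  phase <- matrix(0, shape[1], shape[2])
  if (!is.null(cells) && nrow(cells) > 0) {
    yy <- (seq_len(shape[1]) - 0.5) * pixel_size  # rows
    xx <- (seq_len(shape[2]) - 0.5) * pixel_size  # columns
    for (i in seq_len(nrow(cells))) {
      inside <- outer((yy - cells$y[i])^2, (xx - cells$x[i])^2, `+`) <=
        cells$radius[i]^2
      phase <- phase + inside * (2 * pi * alpha * cells$density[i] / wavelength)
    }
  }
  phase_map(phase, wavelength = wavelength, alpha = alpha,
            pixel_size = pixel_size)
}
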