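#' Shape circularity of a binary mask
#'
#' \eqn{4\pi A / P^2} with the area from the foreground pixel count and the
#' perimeter from a marching-squares contour of the mask (polygon length of
#' the 0.5 iso-contour). The contour estimator has a small raster bias, so a
#' large rasterised disc scores slightly below or above 1; results are
#' clipped to at most 1. The mask must contain exactly one connected
#' foreground component.
#'
#' @param mask Binary matrix (1/TRUE = object).
#' @param pixel_size Pixel edge length, um (cancels in the ratio; kept for
#'   interface symmetry).
#' @return Circularity in `[0, 1]`: 1 for a disc, \eqn{\pi/4 \approx 0.785}
#'   for a square, lower for elongated shapes.
#' @export
circularity <- function(mask, pixel_size = 1) {
  mask <- (mask > 0) * 1
  if (sum(mask) == 0) abort("Empty mask.")
  labels <- EBImage::bwlabel(mask)
  if (max(labels) != 1L) {
    abort(sprintf("Mask must have exactly one connected component (found %d).",
                  max(labels)))
  }
  area <- sum(mask) * pixel_size^2
  perim <- mask_perimeter(mask) * pixel_size
  min(4 * pi * area / perim^2, 1)
}

# Total 0.5-isocontour length of a binary matrix, in pixel units.
# The mask is lightly Gaussian-smoothed first so the iso-contour tracks the
# shape boundary at subpixel accuracy instead of the staircase of pixel
# edges, whose chamfered corners inflate a circle's perimeter by ~5%.
mask_perimeter <- function(mask, sigma = 2) {
  pad <- ceiling(4 * sigma)
  padded <- matrix(0, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
  padded[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask
  padded <- EBImage::gblur(padded, sigma = sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(padded)),
                                y = seq_len(ncol(padded)),
                                z = padded, levels = 0.5)
  if (length(cl) == 0) abort("No contour found.")
  sum(vapply(cl, function(cc) {
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
  }, 0))
}

#' Relative gap area over time
#'
#' Wound-healing (gap closure) quantification: the gap area in each frame is
#' the foreground (gap) pixel count times the pixel area, reported both
#' absolutely and as a percentage of the initial gap.
#'
#' @param masks List of binary gap masks (1 = cell-free gap), common shape.
#' @param times Observation times, h; one per mask, increasing.
#' @param pixel_size Pixel edge length, um.
#' @return A tibble of class `gap_series`: `time` (h), `gap_area` (um^2),
#'   `relative_area` (% of t = 0).
#' @export
relative_gap_area <- function(masks, times, pixel_size) {
  if (length(masks) != length(times)) {
    abort("`masks` and `times` must have equal length.")
  }
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) abort("All masks must share the same shape.")
  areas <- vapply(masks, function(m) sum(m > 0), 0) * pixel_size^2
  if (areas[1] == 0) abort("Initial gap area is zero; cannot normalise.")
  out <- tibble::tibble(
    time = times,
    gap_area = areas,
    relative_area = 100 * areas / areas[1]
  )
  class(out) <- c("gap_series", class(out))
  out
}

#' Segment the cell-free gap from a texture image
#'
#' Minimal texture-based stand-in for interactive wound-healing tools:
#' cell-covered regions are textured (high local intensity variance), the
#' gap is smooth. The pipeline is a local-variance map (box window), Gaussian
#' smoothing, Otsu threshold, and selection of the largest connected
#' low-variance component as the gap.
#'
#' @param image Numeric matrix (grayscale intensities).
#' @param variance_window Side of the square local-variance window, px.
#' @param smooth_sigma Gaussian smoothing sigma, px.
#' @return Binary matrix, 1 = gap.
#' @export
segment_gap <- function(image, variance_window = 9L, smooth_sigma = 4) {
  image <- image / max(abs(image), 1e-12)
  box <- matrix(1 / variance_window^2, variance_window, variance_window)
  m1 <- EBImage::filter2(image, box)
  m2 <- EBImage::filter2(image^2, box)
  local_var <- pmax(m2 - m1^2, 0)
  smoothed <- EBImage::gblur(local_var, sigma = smooth_sigma)
  thr <- EBImage::otsu(EBImage::Image(smoothed / max(smoothed)))
  low <- (smoothed / max(smoothed)) < thr
  labels <- EBImage::bwlabel(low * 1)
  if (max(labels) == 0) return(matrix(0, nrow(image), ncol(image)))
  sizes <- tabulate(labels[labels > 0])
  (labels == which.max(sizes)) * 1
}
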