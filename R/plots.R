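#' Plot an MSD curve
#'
#' Mean MSD versus lag with a +/- SEM ribbon; overlay the first-second linear
#' fit by adding `ggplot2::geom_abline()` from a [fit_diffusion()] result.
#'
#' @param object An `msd_curve` from [compute_msd()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$msd - .data$sem,
                                      ymax = .data$msd + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lag (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' Plot a gap-closure series
#'
#' Relative gap area (% of t = 0) versus time.
#'
#' @param object A `gap_series` from [relative_gap_area()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gap_series
#' @export
autoplot.gap_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$relative_area)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (h)", y = "Relative gap area (%)") +
    ggplot2::ylim(0, NA) +
    ggplot2::theme_minimal()
}

#' Plot a lateral intensity profile
#'
#' @param object An [intensity_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot intensity_profile
#' @export
autoplot.intensity_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Lateral ~ position ~ (mu * m)),
                  y = "Normalised intensity") +
    ggplot2::theme_minimal()
}

#' Rose plot of tracks from a common origin
#'
#' Re-centers every track at the origin, the standard presentation of a
#' random-walk motility assay.
#'
#' @param tracks Tidy track table (`track_id` or `cell_id`, `time`, `x`,
#'   `y`).
#' @return A ggplot.
#' @export
plot_tracks_rose <- function(tracks) {
  id_col <- if ("cell_id" %in% names(tracks)) "cell_id" else "track_id"
  df <- tracks |>
    dplyr::group_by(.data[[id_col]]) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::mutate(x = .data$x - dplyr::first(.data$x),
                  y = .data$y - dplyr::first(.data$y)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data[[id_col]])) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m))) +
    ggplot2::theme_minimal()
}

#' Plot a growth series with its exponential fit
#'
#' Log2-scaled values versus time with the fitted doubling-time line.
#'
#' @param series A growth tibble (`time`, `value`).
#' @param fit Optional [fit_doubling_time()] result; fitted when omitted.
#' @return A ggplot.
#' @export
plot_growth <- function(series, fit = NULL) {
  if (is.null(fit)) fit <- fit_doubling_time(series)
  intercept <- mean(log2(series$value) - fit$slope * series$time)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time, y = log2(.data$value))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = intercept,
                         linetype = 2) +
    ggplot2::labs(x = "Time (h)", y = expression(log[2] ~ value),
                  subtitle = sprintf("Doubling time %.1f h", fit$doubling_time)) +
    ggplot2::theme_minimal()
}
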