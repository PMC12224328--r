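#' @keywords internal
validate_tracks <- function(tracks, id_col = "track_id") {
  need <- c(id_col, "time", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss) > 0) {
    abort(paste0("Track table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y))) {
    abort("Track coordinates must be finite.")
  }
  bad <- tracks |>
    dplyr::group_by(.data[[id_col]]) |>
    dplyr::summarise(ok = all(diff(.data$time) > 0) && dplyr::n() >= 2L,
                     .groups = "drop")
  if (!all(bad$ok)) {
    abort(paste0("Tracks with non-increasing times or < 2 points: ",
                 paste(bad[[id_col]][!bad$ok], collapse = ", ")))
  }
  invisible(tracks)
}

#' Remove common drift from an ensemble of trajectories
#'
#' Estimates external drift as the ensemble mean frame-to-frame displacement
#' over all tracks present in consecutive frames, accumulates it into a drift
#' path, and subtracts that path from every trajectory. After correction the
#' per-frame ensemble mean displacement is zero to numerical precision.
#' Intervals covered by fewer than `min_tracks` simultaneous tracks get their
#' drift increment linearly interpolated from neighbouring intervals; those
#' frames are listed in the `interpolated_frames` attribute. A single track is
#' returned unchanged with a warning, since drift is then unidentifiable.
#'
#' Tracks must share a common frame clock (identical time stamps across
#' tracks at each frame), the situation for tracker exports from one video.
#'
#' @param tracks Tidy track table: columns `track_id`, `time` (s), `x`, `y`
#'   (um).
#' @param min_tracks Minimum simultaneous tracks for a direct drift estimate.
#' @return The corrected track table, same shape as the input, with
#'   attributes `drift` (tibble `time`, `x`, `y`: the subtracted path) and
#'   `interpolated_frames`.
#' @export
drift_correct <- function(tracks, min_tracks = 3L) {
  validate_tracks(tracks)
  if (dplyr::n_distinct(tracks$track_id) < 2L) {
    warn("Only one track: drift is unidentifiable, returning input unchanged.")
    attr(tracks, "drift") <- NULL
    return(tracks)
  }
  frames <- sort(unique(tracks$time))
  n_int <- length(frames) - 1L
  idx <- match(tracks$time, frames)

  by_track <- split(
    data.frame(i = idx, x = tracks$x, y = tracks$y),
    tracks$track_id
  )
  sum_dx <- numeric(n_int); sum_dy <- numeric(n_int); cnt <- integer(n_int)
  for (tr in by_track) {
    o <- order(tr$i)
    i <- tr$i[o]; x <- tr$x[o]; y <- tr$y[o]
    consec <- which(diff(i) == 1L)
    if (length(consec) == 0) next
    j <- i[consec]  # interval index: frame j -> j+1
    sum_dx[j] <- sum_dx[j] + (x[consec + 1L] - x[consec])
    sum_dy[j] <- sum_dy[j] + (y[consec + 1L] - y[consec])
    cnt[j] <- cnt[j] + 1L
  }
  dx <- ifelse(cnt > 0, sum_dx / cnt, NA_real_)
  dy <- ifelse(cnt > 0, sum_dy / cnt, NA_real_)
  weak <- which(cnt < min_tracks)
  if (length(weak) > 0) {
    good <- which(cnt >= min_tracks)
    if (length(good) == 0) abort("No interval has enough simultaneous tracks.")
    dx[weak] <- stats::approx(good, dx[good], xout = weak, rule = 2)$y
    dy[weak] <- stats::approx(good, dy[good], xout = weak, rule = 2)$y
  }
  drift_x <- c(0, cumsum(dx))
  drift_y <- c(0, cumsum(dy))

  out <- tracks
  out$x <- tracks$x - drift_x[idx]
  out$y <- tracks$y - drift_y[idx]
  attr(out, "drift") <- tibble::tibble(time = frames, x = drift_x, y = drift_y)
  attr(out, "interpolated_frames") <- frames[weak]
  out
}

#' Time-averaged mean squared displacement
#'
#' Per track, the time-averaged MSD at lag \eqn{k\Delta t} uses all ordered
#' pairs of points separated by that lag:
#' \eqn{MSD_k = \langle |r(t_i + k\Delta t) - r(t_i)|^2 \rangle_i}. The
#' ensemble curve is the unweighted mean over tracks (a track-length-weighted
#' mean is available via `weighted = TRUE`), with the standard error of the
#' mean across tracks per lag.
#'
#' @param tracks Tidy track table (`track_id`, `time` s, `x`, `y` um) with a
#'   uniform frame interval per track.
#' @param max_lag Largest lag, s; must not exceed the shortest track
#'   duration.
#' @param weighted Weight tracks by their number of contributing pairs
#'   instead of equally.
#' @return A tibble of class `msd_curve`: `lag` (s), `msd` (um^2), `sem`
#'   (um^2), `n_tracks`. The per-track curves are kept in the `per_track`
#'   attribute (matrix, tracks x lags) for downstream confidence intervals.
#' @examples
#' tr <- tibble::tibble(track_id = 1, time = 0:2, x = c(0, 1, 3), y = 0)
#' compute_msd(tr, max_lag = 2)  # 2.5, 9
#' @export
compute_msd <- function(tracks, max_lag, weighted = FALSE) {
  validate_tracks(tracks)
  by_track <- split(tracks[c("time", "x", "y")], tracks$track_id)
  if (length(by_track) == 0) abort("No tracks supplied.")
  durations <- vapply(by_track, function(tr) diff(range(tr$time)), 0)
  if (max_lag > min(durations) + 1e-9) {
    abort("`max_lag` exceeds the shortest track duration.")
  }
  dts <- vapply(by_track, function(tr) median(diff(tr$time)), 0)
  dt <- median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt)) {
    abort("Tracks must share a common frame interval.")
  }
  n_lags <- floor(max_lag / dt + 1e-9)
  if (n_lags < 1) abort("`max_lag` shorter than one frame interval.")

  per_track <- matrix(NA_real_, nrow = length(by_track), ncol = n_lags,
                      dimnames = list(names(by_track), NULL))
  for (i in seq_along(by_track)) {
    tr <- by_track[[i]]
    o <- order(tr$time)
    x <- tr$x[o]; y <- tr$y[o]; n <- length(x)
    kmax <- min(n_lags, n - 1L)
    for (k in seq_len(kmax)) {
      dxk <- x[(1L + k):n] - x[1L:(n - k)]
      dyk <- y[(1L + k):n] - y[1L:(n - k)]
      per_track[i, k] <- mean(dxk^2 + dyk^2)
    }
  }
  if (weighted) {
    npts <- vapply(by_track, nrow, 0L)
    w <- outer(npts, seq_len(n_lags), function(n, k) pmax(n - k, 0))
    w[is.na(per_track)] <- 0
    mean_msd <- colSums(per_track * w, na.rm = TRUE) / colSums(w)
  } else {
    mean_msd <- colMeans(per_track, na.rm = TRUE)
  }
  n_contrib <- colSums(!is.na(per_track))
  sem <- apply(per_track, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  out <- tibble::tibble(
    lag = dt * seq_len(n_lags),
    msd = mean_msd,
    sem = sem,
    n_tracks = n_contrib
  )
  attr(out, "per_track") <- per_track
  attr(out, "dt") <- dt
  class(out) <- c("msd_curve", class(out))
  out
}

#' Effective diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of the ensemble mean MSD against lag over
#' `(0, fit_window]`, with a free intercept that absorbs static localisation
#' noise. For two-dimensional tracks the effective diffusion coefficient is
#' slope/4.
#'
#' The 95% confidence interval is taken, when per-track curves are available,
#' from the between-track dispersion of per-track slopes: because the
#' ensemble curve is the unweighted mean of per-track curves and least
#' squares is linear in the response, the ensemble slope equals the mean of
#' the per-track slopes, and independent tracks give an honest standard error
#' for it (a t-interval). Without per-track curves the interval falls back to
#' the OLS residual-based slope standard error, which ignores lag-to-lag
#' correlation of the mean curve.
#'
#' @param curve An [compute_msd()] result (class `msd_curve`).
#' @param fit_window Upper lag bound of the fit, s; needs >= 3 lags inside.
#' @return An object of class `diffusion_fit`: `d_eff` (um^2/s), `ci95`,
#'   `intercept` (um^2), `fit_window`, `dimensionality = 2`, `n_tracks`,
#'   `ci_method`, and `negative_slope` flag (a negative fitted slope is
#'   reported, not clamped). [tidy()]/[glance()] methods available.
#' @export
fit_diffusion <- function(curve, fit_window = 1.0) {
  if (fit_window <= 0) abort("`fit_window` must be > 0.")
  sel <- curve$lag > 0 & curve$lag <= fit_window + 1e-12 & !is.na(curve$msd)
  if (sum(sel) < 3L) abort("Need >= 3 lags inside the fit window.")
  lag <- curve$lag[sel]
  msd <- curve$msd[sel]
  ols <- lm(msd ~ lag)
  slope <- unname(coef(ols)[2L])
  intercept <- unname(coef(ols)[1L])
  d_eff <- slope / 4

  per_track <- attr(curve, "per_track")
  ci_method <- "ols"
  n_tracks <- max(curve$n_tracks[sel])
  if (!is.null(per_track)) {
    pt <- per_track[, which(sel), drop = FALSE]
    complete <- stats::complete.cases(pt)
    if (sum(complete) >= 2L) {
      # per-track OLS slopes via the shared projection weights
      lc <- lag - mean(lag)
      w <- lc / sum(lc^2)
      d_i <- as.vector(pt[complete, , drop = FALSE] %*% w) / 4
      se <- sd(d_i) / sqrt(length(d_i))
      tq <- qt(0.975, df = length(d_i) - 1L)
      ci <- c(d_eff - tq * se, d_eff + tq * se)
      ci_method <- "between-track"
      n_tracks <- length(d_i)
    }
  }
  if (ci_method == "ols") {
    # a zero-residual curve triggers R's "perfect fit" note; the zero SE is valid
    se_slope <- suppressWarnings(summary(ols))$coefficients[2L, 2L]
    tq <- qt(0.975, df = length(lag) - 2L)
    ci <- c(d_eff - tq * se_slope / 4, d_eff + tq * se_slope / 4)
  }
  if (d_eff < 0) {
    warn("Fitted MSD slope is negative; d_eff reported as-is.")
  }
  structure(
    list(d_eff = d_eff, ci95 = ci, intercept = intercept,
         fit_window = fit_window, dimensionality = 2L,
         n_tracks = n_tracks, ci_method = ci_method,
         negative_slope = d_eff < 0, n_lags = length(lag)),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> D_eff = %.4g um^2/s (95%% CI %.4g-%.4g, %s, n = %d)\n",
    x$d_eff, x$ci95[1], x$ci95[2], x$ci_method, x$n_tracks))
  cat(sprintf("  intercept %.4g um^2, window %.3g s, %d lags\n",
              x$intercept, x$fit_window, x$n_lags))
  invisible(x)
}

#' @rdname fit_diffusion
#' @param x A `diffusion_fit` object.
#' @param ... Unused.
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    term = c("d_eff", "intercept"),
    estimate = c(x$d_eff, x$intercept),
    conf.low = c(x$ci95[1], NA_real_),
    conf.high = c(x$ci95[2], NA_real_)
  )
}

#' @rdname fit_diffusion
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(d_eff = x$d_eff, conf.low = x$ci95[1],
                 conf.high = x$ci95[2], n_tracks = x$n_tracks,
                 fit_window = x$fit_window, ci_method = x$ci_method,
                 negative_slope = x$negative_slope)
}

#' Percentage diffusion enhancement
#'
#' `100 * (d_condition - d_control) / d_control`: the percent change of the
#' effective diffusion coefficient in a fuel condition relative to the
#' fuel-free control.
#'
#' @param d_condition,d_control Effective diffusion coefficients, um^2/s;
#'   `d_control` must be positive.
#' @return Percent change (vectorised over `d_condition`).
#' @examples
#' percent_enhancement(29.29, 21.19)  # ~38%
#' @export
percent_enhancement <- function(d_condition, d_control) {
  if (any(d_control <= 0)) abort("`d_control` must be > 0.")
  100 * (d_condition - d_control) / d_control
}
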