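#' Motility metrics for a single cell track
#'
#' Standard random-walk assay summaries over a centroid path
#' \eqn{r(t_0) \ldots r(T)}:
#' net displacement \eqn{|r(T) - r(t_0)|}, total distance
#' \eqn{\sum |\Delta r|}, directionality ratio (net/total; 0 for a closed
#' loop, defined as 0 for a stationary cell), mean speed (total distance per
#' elapsed time) and mean velocity (net displacement per elapsed time).
#'
#' @param track A tibble with columns `time` (h), `x`, `y` (um) for one cell
#'   (a `cell_id`/`track_id` column is allowed and carried through).
#' @return A one-row tibble: `cell_id`, `net_displacement` (um),
#'   `total_distance` (um), `directionality`, `mean_speed` (um/h),
#'   `mean_velocity` (um/h).
#' @examples
#' track <- tibble::tibble(time = c(0, 1, 2), x = c(0, 30, 30), y = c(0, 0, 40))
#' motility_summary(track)
#' @export
motility_summary <- function(track) {
  if (!all(c("time", "x", "y") %in% names(track))) {
    abort("`track` needs columns time, x, y.")
  }
  if (nrow(track) < 2L) abort("A track needs at least 2 points.")
  if (anyDuplicated(track$time)) abort("Duplicate timestamps in track.")
  track <- dplyr::arrange(track, .data$time)
  id <- track[["cell_id"]] %||% track[["track_id"]] %||% NA
  dx <- diff(track$x); dy <- diff(track$y)
  total <- sum(sqrt(dx^2 + dy^2))
  net <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
              (track$y[nrow(track)] - track$y[1])^2)
  elapsed <- track$time[nrow(track)] - track$time[1]
  tibble::tibble(
    cell_id = id[1],
    net_displacement = net,
    total_distance = total,
    directionality = if (total > 0) net / total else 0,
    mean_speed = total / elapsed,
    mean_velocity = net / elapsed
  )
}

#' Population motility table
#'
#' Applies [motility_summary()] to every track and aggregates each metric.
#' Error conventions follow the random-walk assay reporting: standard error
#' of the mean for net displacement and total distance, standard deviation
#' for directionality, speed and velocity.
#'
#' @param tracks Tidy track table with columns `cell_id` (or `track_id`),
#'   `time` (h), `x`, `y` (um).
#' @return A tibble with one row per metric: `metric`, `mean`, `error`,
#'   `error_type` (`"sem"` or `"sd"`), `n`.
#' @export
population_motility <- function(tracks) {
  id_col <- if ("cell_id" %in% names(tracks)) "cell_id" else "track_id"
  validate_tracks(tracks, id_col = id_col)
  per_cell <- tracks |>
    dplyr::group_split(.data[[id_col]]) |>
    purrr::map(motility_summary) |>
    dplyr::bind_rows()
  n <- nrow(per_cell)
  sem_metrics <- c("net_displacement", "total_distance")
  metrics <- c(sem_metrics, "directionality", "mean_speed", "mean_velocity")
  purrr::map(metrics, function(m) {
    v <- per_cell[[m]]
    is_sem <- m %in% sem_metrics
    tibble::tibble(
      metric = m,
      mean = mean(v),
      error = if (n > 1) {
        if (is_sem) sd(v) / sqrt(n) else sd(v)
      } else NA_real_,
      error_type = if (is_sem) "sem" else "sd",
      n = n
    )
  }) |> dplyr::bind_rows()
}

#' Fold change between two population motility tables
#'
#' Ratio of population means, condition over control, per metric.
#'
#' @param condition,control Outputs of [population_motility()].
#' @return A tibble `metric`, `fold_change`.
#' @export
motility_fold_change <- function(condition, control) {
  dplyr::inner_join(condition, control, by = "metric",
                    suffix = c("_cond", "_ctrl")) |>
    dplyr::transmute(.data$metric,
                     fold_change = .data$mean_cond / .data$mean_ctrl)
}
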