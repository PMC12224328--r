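#' Read a tracker-export track table
#'
#' Reads the delimited export convention of common particle/cell trackers:
#' columns `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`, `POSITION_T`
#' (positions in um, time in the unit the experiment used — seconds for
#' particle videos, hours for time-lapse cell assays). Rows may be in any
#' order; tracks are grouped by id and sorted by frame.
#'
#' @param path File path.
#' @param dialect Export dialect; only `"tracker-export"` is supported.
#' @param id_col Name of the id column in the returned tidy table
#'   (`"track_id"` for particles, `"cell_id"` for cells).
#' @return A tidy tibble `track_id` (or `cell_id`), `frame`, `time`, `x`,
#'   `y`.
#' @export
read_tracks <- function(path, dialect = "tracker-export",
                        id_col = "track_id") {
  dialect <- match.arg(dialect)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y", "POSITION_T")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Track file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- tibble::tibble(
    id = raw$TRACK_ID, frame = raw$FRAME, time = raw$POSITION_T,
    x = raw$POSITION_X, y = raw$POSITION_Y
  ) |>
    dplyr::arrange(.data$id, .data$frame)
  bad <- out |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(ok = all(diff(.data$frame) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    abort(paste0("Non-monotone or duplicated frames in track(s): ",
                 paste(bad$id[!bad$ok], collapse = ", ")))
  }
  names(out)[1] <- id_col
  out
}

#' Write a track table in tracker-export format
#'
#' Inverse of [read_tracks()]: writes `TRACK_ID`, `FRAME`, `POSITION_X`,
#' `POSITION_Y`, `POSITION_T` as CSV. A `frame` column is synthesised from
#' the per-track time order when absent.
#'
#' @param tracks Tidy track table (`track_id` or `cell_id`, `time`, `x`,
#'   `y`, optionally `frame`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  id_col <- if ("track_id" %in% names(tracks)) "track_id" else "cell_id"
  validate_tracks(tracks, id_col = id_col)
  if (!"frame" %in% names(tracks)) {
    tracks <- tracks |>
      dplyr::group_by(.data[[id_col]]) |>
      dplyr::mutate(frame = rank(.data$time) - 1) |>
      dplyr::ungroup()
  }
  out <- tibble::tibble(
    TRACK_ID = tracks[[id_col]], FRAME = tracks$frame,
    POSITION_X = tracks$x, POSITION_Y = tracks$y, POSITION_T = tracks$time
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a lateral intensity profile
#'
#' Two-column delimited text: position (um) and intensity (arbitrary
#' units). Intensity is normalised to unit maximum on load.
#'
#' @param path File path.
#' @param analysis_window Optional `c(lo, hi)` window passed to
#'   [intensity_profile()].
#' @return An [intensity_profile()].
#' @export
read_profile <- function(path, analysis_window = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(raw) < 2L) abort("Profile file needs two columns: position, intensity.")
  intensity_profile(raw[[1]], raw[[2]], analysis_window = analysis_window)
}

#' @rdname read_profile
#' @param profile An [intensity_profile()].
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(
    tibble::tibble(position_um = profile$position,
                   intensity = profile$intensity),
    path
  )
  invisible(path)
}

#' Write/read a binary mask or phase map as TIFF with a JSON sidecar
#'
#' Masks are stored as 0/1 single-channel TIFF; phase maps as 32-bit float
#' TIFF (radians). Pixel size and, for phase maps, wavelength and the
#' specific refraction increment live in `<path>.json`.
#'
#' @param mask Binary matrix.
#' @param path Output TIFF path (sidecar written at `<path>.json`).
#' @param pixel_size Pixel edge length, um.
#' @return `path`, invisibly (readers return the object).
#' @export
write_mask_tiff <- function(mask, path, pixel_size) {
  tiff::writeTIFF((mask > 0) * 1, path, bits.per.sample = 8L)
  jsonlite::write_json(list(pixel_size_um = pixel_size, kind = "mask"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  structure((img > 0.5) * 1L, pixel_size = side$pixel_size_um)
}

#' @rdname write_mask_tiff
#' @param map A [phase_map()].
#' @export
write_phase_tiff <- function(map, path) {
  # TIFF floats are stored in [0, 1]; record the rescale factor in the sidecar
  scale <- max(map$phase, 1e-12)
  tiff::writeTIFF(map$phase / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = map$pixel_size, wavelength_um = map$wavelength,
         alpha_um3_per_pg = map$alpha, phase_scale_rad = scale,
         kind = "phase"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_phase_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  phase_map(img * side$phase_scale_rad, wavelength = side$wavelength_um,
            alpha = side$alpha_um3_per_pg, pixel_size = side$pixel_size_um)
}
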