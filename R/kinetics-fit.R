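#' Initial rates from short-incubation time courses
#'
#' Computes one initial rate per assay course from the consumed substrate at
#' early times (e.g. 3/6/9 min incubations). Consumption is
#' `conc(0) - conc(t)`; the rate is the least-squares slope of consumption
#' versus time constrained through the origin (consumption is definitionally
#' zero at t = 0): \eqn{\hat v = \sum t y / \sum t^2}. The t = 0
#' concentration is reported as the course's substrate concentration.
#'
#' @param courses A tibble of assay time courses with columns `time`
#'   (minutes), the substrate column named by `substrate`, and (for several
#'   courses) a `course_id` column; or a list of such tibbles.
#' @param substrate Which column carries the tracked substrate:
#'   `"glucose"` or `"h2o2"`.
#' @return A tibble of rate points: `course_id`, `substrate_conc` (mM),
#'   `initial_rate` (mM/min), and `increasing` — `TRUE` flags a course whose
#'   substrate rose over time (a negative fitted consumption rate).
#' @examples
#' tc <- tibble::tibble(time = c(0, 3, 6, 9),
#'                      glucose = c(10, 9.45, 8.98, 8.60))
#' estimate_initial_rates(tc, "glucose")
#' @export
estimate_initial_rates <- function(courses, substrate = c("glucose", "h2o2")) {
  substrate <- match.arg(substrate)
  if (is.data.frame(courses)) {
    if (!"course_id" %in% names(courses)) courses$course_id <- 1L
    courses <- split(courses, courses$course_id)
  }
  rows <- purrr::imap(courses, function(course, id) {
    if (!all(c("time", substrate) %in% names(course))) {
      abort(sprintf("Each course needs columns `time` and `%s`.", substrate))
    }
    course <- dplyr::arrange(course, .data$time)
    t <- course$time
    y0 <- course[[substrate]][t == min(t)][1L]
    if (min(t) > 0) {
      abort("Each course must include a t = 0 observation for the initial concentration.")
    }
    tt <- t[t > 0]
    if (length(tt) < 2L) {
      abort("Each course needs >= 2 time points beyond t = 0.")
    }
    if (length(unique(tt)) == 1L) abort("All post-zero times are identical.")
    consumed <- y0 - course[[substrate]][t > 0]
    rate <- sum(tt * consumed) / sum(tt^2)
    tibble::tibble(
      course_id = if (is.null(id)) NA_character_ else as.character(id),
      substrate_conc = y0,
      initial_rate = rate,
      increasing = rate < 0
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$increasing)) {
    warn("Some courses show increasing substrate over time; flagged in `increasing`.")
  }
  out
}

# Shared machinery for the two saturation fits.
saturation_fit <- function(points, formula, start, lower, upper, class,
                           param_builder) {
  stopifnot(all(c("substrate_conc", "initial_rate") %in% names(points)))
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = points, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(converged = FALSE, message = conditionMessage(fit),
           estimates = NULL, std_errors = NULL, r_squared = NA_real_,
           data = points, fit = NULL),
      class = c(class, "saturation_fit")
    ))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(est)),
                                              names(est)))
  res <- points$initial_rate - stats::predict(fit)
  sst <- sum((points$initial_rate - mean(points$initial_rate))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  structure(
    list(converged = TRUE, message = NULL,
         estimates = as.list(est), std_errors = as.list(se),
         r_squared = r2, params = param_builder(est),
         data = points, fit = fit),
    class = c(class, "saturation_fit")
  )
}

#' Fit Michaelis-Menten kinetics to initial-rate points
#'
#' Nonlinear least squares of \eqn{v = V_{max} S / (K_m + S)} via bounded
#' Levenberg-Marquardt. Start values: `v_max` at 1.2x the largest observed
#' rate; `k_m` at the substrate concentration whose rate is closest to half
#' the maximum. Both parameters are bounded below by small positive values.
#' Non-convergence is reported explicitly (`converged = FALSE`), never as
#' silently defaulted estimates.
#'
#' @param points A tibble of rate points with columns `substrate_conc` (mM)
#'   and `initial_rate` (mM/min); at least 3 distinct concentrations.
#' @param ref_catalyst_conc Catalyst concentration the rates refer to, mg/mL.
#' @return An object of class `mm_fit` with elements `estimates`
#'   (`v_max`, `k_m`), `std_errors`, `r_squared`, `converged`, and — when the
#'   fit converged — `params`, an [mm_kinetics()] object. Use [tidy()] /
#'   [glance()] for tabular views.
#' @examples
#' s <- c(1, 2.5, 5, 10, 20, 30)
#' pts <- tibble::tibble(substrate_conc = s,
#'                       initial_rate = 10 * s / (2.9 + s))
#' fit_mm(pts)
#' @export
fit_mm <- function(points, ref_catalyst_conc = 0.1) {
  if (length(unique(points$substrate_conc)) < 3L) {
    abort("fit_mm needs >= 3 distinct substrate concentrations.")
  }
  vmax0 <- 1.2 * max(points$initial_rate)
  half <- max(points$initial_rate) / 2
  km0 <- points$substrate_conc[which.min(abs(points$initial_rate - half))]
  saturation_fit(
    points,
    initial_rate ~ v_max * substrate_conc / (k_m + substrate_conc),
    start = list(v_max = vmax0, k_m = max(km0, 1e-6)),
    lower = c(v_max = 1e-9, k_m = 1e-9),
    upper = c(v_max = Inf, k_m = Inf),
    class = "mm_fit",
    param_builder = function(est) {
      mm_kinetics(est[["v_max"]], est[["k_m"]], ref_catalyst_conc)
    }
  )
}

#' Fit Hill (allosteric sigmoidal) kinetics to initial-rate points
#'
#' Nonlinear least squares of \eqn{v = V_{max} S^h / (K_{0.5}^h + S^h)} over
#' `(v_max, k_half, h)`, with the Hill slope bounded to `(0.1, 10]` and
#' started at 1.5. `fix_h` pins the slope (e.g. `fix_h = 1` reduces the model
#' to Michaelis-Menten form).
#'
#' @inheritParams fit_mm
#' @param fix_h Optional fixed Hill slope; `NULL` (default) fits it.
#' @return An object of class `hill_fit`; see [fit_mm()] for the structure.
#'   `params` is a [hill_kinetics()] object when converged.
#' @export
fit_hill <- function(points, fix_h = NULL, ref_catalyst_conc = 0.1) {
  n_needed <- if (is.null(fix_h)) 4L else 3L
  if (length(unique(points$substrate_conc)) < n_needed) {
    abort(sprintf("fit_hill needs >= %d distinct substrate concentrations.",
                  n_needed))
  }
  vmax0 <- 1.2 * max(points$initial_rate)
  half <- max(points$initial_rate) / 2
  k0 <- points$substrate_conc[which.min(abs(points$initial_rate - half))]
  if (is.null(fix_h)) {
    saturation_fit(
      points,
      initial_rate ~ v_max * substrate_conc^h /
        (k_half^h + substrate_conc^h),
      start = list(v_max = vmax0, k_half = max(k0, 1e-6), h = 1.5),
      lower = c(v_max = 1e-9, k_half = 1e-9, h = 0.1),
      upper = c(v_max = Inf, k_half = Inf, h = 10),
      class = "hill_fit",
      param_builder = function(est) {
        hill_kinetics(est[["v_max"]], est[["k_half"]], est[["h"]],
                      ref_catalyst_conc)
      }
    )
  } else {
    h_fixed <- fix_h
    saturation_fit(
      points,
      initial_rate ~ v_max * substrate_conc^h_fixed /
        (k_half^h_fixed + substrate_conc^h_fixed),
      start = list(v_max = vmax0, k_half = max(k0, 1e-6)),
      lower = c(v_max = 1e-9, k_half = 1e-9),
      upper = c(v_max = Inf, k_half = Inf),
      class = "hill_fit",
      param_builder = function(est) {
        hill_kinetics(est[["v_max"]], est[["k_half"]], h_fixed,
                      ref_catalyst_conc)
      }
    )
  }
}

#' @export
print.saturation_fit <- function(x, ...) {
  kind <- if (inherits(x, "mm_fit")) "Michaelis-Menten" else "Hill"
  cat(sprintf("<%s fit>", kind), "\n")
  if (!x$converged) {
    cat("  did not converge:", x$message, "\n")
    return(invisible(x))
  }
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-6s = %.6g (se %.3g)\n", nm, x$estimates[[nm]],
                x$std_errors[[nm]]))
  }
  cat(sprintf("  R^2 = %.5f on %d points\n", x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_mm
#' @param x A fitted `mm_fit`/`hill_fit` object.
#' @param ... Unused.
#' @method tidy saturation_fit
#' @export
tidy.saturation_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = double(),
                          std.error = double()))
  }
  tibble::tibble(
    term = names(x$estimates),
    estimate = unlist(x$estimates, use.names = FALSE),
    std.error = unlist(x$std_errors, use.names = FALSE)
  )
}

#' @rdname fit_mm
#' @method glance saturation_fit
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, converged = x$converged,
                 nobs = nrow(x$data))
}
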