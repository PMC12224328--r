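make_grid_tracks <- function(n_tracks, n_frames, dt = 0.04, seed = 1,
                             d = 1, drift = c(0, 0)) {
  gen_brownian_tracks(track_sim_spec(
    n_tracks = n_tracks, diffusion_coeff = d, frame_rate = 1 / dt,
    duration = (n_frames - 1) * dt, drift_velocity = drift, seed = seed
  ))
}

test_that("MSD matches closed forms on stationary, ballistic, and hand-enumerated tracks", {
  still <- tibble::tibble(track_id = rep(1:3, each = 5),
                          time = rep(0:4, 3), x = 2, y = -1)
  expect_true(all(compute_msd(still, max_lag = 3)$msd == 0))

  v <- 3
  ball <- tibble::tibble(track_id = 1, time = 0:10, x = v * (0:10), y = 0)
  curve <- compute_msd(ball, max_lag = 5)
  expect_equal(curve$msd, v^2 * curve$lag^2)

  hand <- tibble::tibble(track_id = 1, time = 0:2, x = c(0, 1, 3), y = 0)
  ch <- compute_msd(hand, max_lag = 2)
  expect_equal(ch$msd, c((1 + 4) / 2, 9))
})

test_that("MSD equals the exhaustive pair-enumeration oracle on short random tracks", {
  set.seed(5)
  for (rep in 1:4) {
    n <- sample(10:50, 1)
    tr <- tibble::tibble(track_id = 1, time = seq_len(n) - 1,
                         x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    k <- n - 1L
    curve <- compute_msd(tr, max_lag = k)
    expect_equal(curve$msd, msd_pairs_oracle(tr$x, tr$y, k))
  }
})

test_that("MSD is invariant under translation and rotation of the field", {
  tracks <- make_grid_tracks(4, 40, seed = 9)
  base <- compute_msd(tracks, max_lag = 0.4)
  shifted <- dplyr::mutate(tracks, x = x + 123.4, y = y - 77)
  expect_equal(compute_msd(shifted, max_lag = 0.4)$msd, base$msd)
  th <- 0.83
  rotated <- dplyr::mutate(tracks, x0 = x, x = cos(th) * x0 - sin(th) * y,
                           y = sin(th) * x0 + cos(th) * y, x0 = NULL)
  expect_equal(compute_msd(rotated, max_lag = 0.4)$msd, base$msd)
})

test_that("MSD preconditions are enforced", {
  tracks <- make_grid_tracks(3, 20)
  expect_error(compute_msd(tracks, max_lag = 10), "shortest track")
  expect_error(compute_msd(tracks[0, ], max_lag = 0.1), "missing|No tracks")
})

test_that("drift correction removes a uniform drift exactly", {
  drifted <- make_grid_tracks(12, 100, seed = 3, d = 2, drift = c(1, 0.5))
  corrected <- drift_correct(drifted)
  mean_disp <- corrected |>
    dplyr::group_by(time) |>
    dplyr::summarise(mx = mean(x), my = mean(y)) |>
    dplyr::mutate(dx = c(NA, diff(mx)), dy = c(NA, diff(my)))
  expect_lt(max(abs(mean_disp$dx), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(mean_disp$dy), na.rm = TRUE), 1e-9)
})

test_that("drift correction barely perturbs an undrifted ensemble's D estimate", {
  tracks <- gen_brownian_tracks(track_sim_spec(
    n_tracks = 80, diffusion_coeff = 21.19, frame_rate = 25, duration = 10,
    seed = 21
  ))
  d_raw <- fit_diffusion(compute_msd(tracks, max_lag = 1))$d_eff
  d_cor <- fit_diffusion(compute_msd(drift_correct(tracks), max_lag = 1))$d_eff
  expect_lt(abs(d_cor - d_raw) / d_raw, 0.02)
})

test_that("drift correction is idempotent and warns on a single track", {
  tracks <- make_grid_tracks(8, 60, seed = 17, drift = c(0.7, -0.2))
  once <- drift_correct(tracks)
  twice <- drift_correct(once)
  expect_equal(twice$x, once$x, tolerance = 1e-12)
  expect_equal(twice$y, once$y, tolerance = 1e-12)

  single <- dplyr::filter(tracks, track_id == 1)
  expect_warning(out <- drift_correct(single), "unidentifiable")
  expect_equal(out$x, single$x)
})

test_that("fit_diffusion inverts exact linear curves and decouples the intercept", {
  lags <- seq(0.04, 1, by = 0.04)
  d <- 21.19
  curve <- tibble::tibble(lag = lags, msd = 4 * d * lags,
                          sem = NA_real_, n_tracks = 1L)
  fit <- fit_diffusion(curve, fit_window = 1)
  expect_equal(fit$d_eff, d, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_true(fit$ci95[1] <= fit$d_eff && fit$d_eff <= fit$ci95[2])

  offset <- dplyr::mutate(curve, msd = msd + 0.37)
  fit2 <- fit_diffusion(offset, fit_window = 1)
  expect_equal(fit2$d_eff, d, tolerance = 1e-10)
  expect_equal(fit2$intercept, 0.37, tolerance = 1e-9)

  down <- dplyr::mutate(curve, msd = 1 - 0.5 * lag)
  expect_warning(fneg <- fit_diffusion(down, fit_window = 1), "negative")
  expect_true(fneg$negative_slope)
  expect_lt(fneg$d_eff, 0)
})

test_that("between-track confidence intervals bracket the estimate and cover the truth", {
  tracks <- gen_brownian_tracks(track_sim_spec(
    n_tracks = 120, diffusion_coeff = 21.19, frame_rate = 25, duration = 15,
    seed = 31
  ))
  fit <- fit_diffusion(compute_msd(drift_correct(tracks), max_lag = 1))
  expect_identical(fit$ci_method, "between-track")
  expect_true(fit$ci95[1] <= fit$d_eff && fit$d_eff <= fit$ci95[2])
  expect_true(fit$ci95[1] <= 21.19 && 21.19 <= fit$ci95[2])
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "d_eff"], fit$d_eff)
})

test_that("percent enhancement is the relative change in percent", {
  expect_equal(percent_enhancement(20, 20), 0)
  expect_equal(percent_enhancement(30, 20), 50)
  expect_error(percent_enhancement(10, 0), "d_control")
})
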