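test_that("noise specs validate and `none` means exact model values", {
  expect_error(noise_spec("additive-gaussian", -1), "non-negative")
  s <- gen_growth_series(100, 16.8, seq(0, 24, by = 0.5))
  expect_equal(s$value, 100 * 2^(s$time / 16.8))
})

test_that("generators are pure functions of spec and seed", {
  spec <- track_sim_spec(n_tracks = 5, diffusion_coeff = 2, duration = 2,
                         seed = 99)
  expect_identical(gen_brownian_tracks(spec), gen_brownian_tracks(spec))

  cspec <- cell_sim_spec(n_cells = 5, mean_speed = 10, seed = 42)
  expect_identical(gen_cell_tracks(cspec), gen_cell_tracks(cspec))

  expect_identical(
    gen_gap_masks(times = c(0, 6), edge_roughness = 5, seed = 7),
    gen_gap_masks(times = c(0, 6), edge_roughness = 5, seed = 7)
  )
  n <- noise_spec("additive-gaussian", 0.1)
  expect_identical(gen_growth_series(100, 16.8, 0:24, n, seed = 3),
                   gen_growth_series(100, 16.8, 0:24, n, seed = 3))
})

test_that("cascade time-course generator matches the simulator and honours noise", {
  m <- ref_cascade(hill_h = 1)
  zero <- gen_cascade_timecourse(m, 0.1, 0, 0, times = c(3, 6, 9))
  expect_true(all(zero$glucose == 0) && all(zero$h2o2 == 0))

  tc <- gen_cascade_timecourse(m, 0.1, 10, 0, times = c(3, 6, 9))
  ref <- simulate_cascade(m, 0.1, 10, 0, t_end = 9, times = c(0, 3, 6, 9))
  expect_equal(tc$glucose, ref$glucose[-1], tolerance = 1e-7)
  expect_equal(tc$h2o2, ref$h2o2[-1], tolerance = 1e-7)

  expect_error(gen_cascade_timecourse(m, 0.1, -1, 0, times = c(3, 6)), ">= 0")
  expect_error(gen_cascade_timecourse(m, 0.1, 5, 0, times = c(6, 3)),
               "increasing")

  # Monte-Carlo check of the additive noise contract at one time point
  noisy <- purrr::map_dbl(1:200, function(s) {
    gen_cascade_timecourse(m, 0.1, 10, 0, times = c(3, 6, 9),
                           noise = noise_spec("additive-gaussian", 0.05),
                           seed = s)$glucose[2]
  })
  expect_equal(sd(noisy), 0.05, tolerance = 0.2)
})

test_that("Brownian steps have the prescribed variance and D = 0 freezes tracks", {
  frozen <- gen_brownian_tracks(track_sim_spec(n_tracks = 3,
                                               diffusion_coeff = 0,
                                               duration = 1, seed = 2))
  expect_true(all(frozen$x == 0) && all(frozen$y == 0))

  spec <- track_sim_spec(n_tracks = 50, diffusion_coeff = 21.19,
                         frame_rate = 25, duration = 60, seed = 8)
  tracks <- gen_brownian_tracks(spec)
  expect_equal(dplyr::count(tracks, track_id)$n,
               rep(60 * 25 + 1, 50))
  steps <- tracks |>
    dplyr::group_by(track_id) |>
    dplyr::reframe(dx = diff(x), dy = diff(y))
  target <- 2 * 21.19 * 0.04
  expect_equal(var(steps$dx), target, tolerance = 0.05)
  expect_equal(var(steps$dy), target, tolerance = 0.05)
})

test_that("cell-track generator hits its speed, distance, and persistence contracts", {
  straight <- gen_cell_tracks(cell_sim_spec(n_cells = 10, mean_speed = 10,
                                            persistence_time = Inf, seed = 5))
  pop <- population_motility(straight)
  expect_equal(pop$mean[pop$metric == "directionality"], 1)

  frozen <- gen_cell_tracks(cell_sim_spec(n_cells = 4, mean_speed = 0, seed = 5))
  mets <- population_motility(frozen)
  expect_true(all(mets$mean == 0))

  walk <- gen_cell_tracks(cell_sim_spec(n_cells = 200, mean_speed = 10,
                                        persistence_time = 2, duration = 24,
                                        sampling_interval = 0.5, seed = 12))
  summ <- population_motility(walk)
  expect_equal(summ$mean[summ$metric == "total_distance"], 240,
               tolerance = 0.1)
  expect_equal(summ$mean[summ$metric == "mean_speed"], 10, tolerance = 0.1)
})

test_that("PRW heading decorrelation follows the persistence time", {
  dt <- 0.5; p <- 2
  walk <- gen_cell_tracks(cell_sim_spec(n_cells = 400, mean_speed = 10,
                                        persistence_time = p, duration = 12,
                                        sampling_interval = dt, seed = 77))
  cos_increments <- walk |>
    dplyr::group_by(cell_id) |>
    dplyr::reframe(theta = atan2(diff(y), diff(x))) |>
    dplyr::group_by(cell_id) |>
    dplyr::reframe(dc = cos(diff(theta)))
  expect_equal(mean(cos_increments$dc), exp(-dt / p), tolerance = 0.02)
})

test_that("directionality of a PRW ensemble decays with track duration", {
  spec <- function(dur) cell_sim_spec(n_cells = 150, mean_speed = 10,
                                      persistence_time = 1, duration = dur,
                                      sampling_interval = 0.5, seed = 14)
  dirs <- purrr::map_dbl(c(2, 8, 24), function(dur) {
    pop <- population_motility(gen_cell_tracks(spec(dur)))
    pop$mean[pop$metric == "directionality"]
  })
  expect_true(all(diff(dirs) < 0))
})

test_that("gap masks close linearly and reproduce exact areas when smooth", {
  masks <- gen_gap_masks(initial_gap = 500, closure_rate = 25,
                         times = c(0, 12, 25), frame = c(1500, 1000),
                         pixel_size = 5, edge_roughness = 0, seed = 1)
  # t = 0: exactly 500 um x 1000 um of gap
  expect_equal(sum(masks[[1]]) * 25, 500 * 1000)
  # t past closure: empty mask
  expect_true(all(masks[[3]] == 0))

  series <- relative_gap_area(masks, c(0, 12, 25), pixel_size = 5)
  expect_equal(series$relative_area, c(100, 40, 0))

  rough <- gen_gap_masks(initial_gap = 500, closure_rate = 25,
                         times = c(0, 12), frame = c(1500, 1000),
                         pixel_size = 5, edge_roughness = 5, seed = 4)
  rs <- relative_gap_area(rough, c(0, 12), pixel_size = 5)
  expect_equal(rs$relative_area[2], 40, tolerance = 2 / 40)
})

test_that("growth generator doubles on schedule and closes with the fitter", {
  s <- gen_growth_series(100, 16.8, c(0, 8, 16.8, 24))
  expect_equal(s$value[3], 200)
  fit <- fit_doubling_time(gen_growth_series(250, 16.8, seq(0, 24, by = 0.5)))
  expect_equal(fit$doubling_time, 16.8, tolerance = 1e-6)
  expect_error(gen_growth_series(0, 16.8, 0:5), "n0")
  expect_error(gen_growth_series(10, -2, 0:5), "doubling_time")
})

test_that("phase-image generator inverts the dry-mass relation", {
  empty <- gen_phase_image(NULL, shape = c(32, 32))
  expect_true(all(empty$phase == 0))

  cells <- tibble::tibble(x = 60, y = 60, radius = 40,
                          density = 0.65 / 0.18)
  pm <- gen_phase_image(cells, wavelength = 0.65, alpha = 0.18,
                        shape = c(120, 120), pixel_size = 1)
  inside <- pm$phase[60, 60]
  expect_equal(inside, 2 * pi, tolerance = 1e-12)

  # fine pixels: integrated mass within 1% of density x disc area
  pm_fine <- gen_phase_image(
    tibble::tibble(x = 50, y = 50, radius = 40, density = 3.611),
    shape = c(200, 200), pixel_size = 0.5)
  expect_equal(dry_mass(pm_fine)$total, 3.611 * pi * 40^2, tolerance = 0.01)

  # overlapping discs add phase
  two <- tibble::tibble(x = c(50, 52), y = c(50, 50), radius = 10,
                        density = 1)
  pm2 <- gen_phase_image(two, shape = c(100, 100), pixel_size = 1)
  expect_equal(max(pm2$phase), 2 * (2 * pi * 0.18 / 0.65), tolerance = 1e-12)
})
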