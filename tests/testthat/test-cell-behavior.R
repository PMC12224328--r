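test_that("motility metrics match closed-form paths", {
  straight <- tibble::tibble(time = seq(0, 24, by = 1),
                             x = 10 * seq(0, 24, by = 1), y = 0)
  s <- motility_summary(straight)
  expect_equal(s$net_displacement, 240)
  expect_equal(s$total_distance, 240)
  expect_equal(s$directionality, 1)
  expect_equal(s$mean_speed, 10)
  expect_equal(s$mean_velocity, 10)

  loop <- tibble::tibble(time = 0:4, x = c(0, 1, 1, 0, 0),
                         y = c(0, 0, 1, 1, 0))
  sl <- motility_summary(loop)
  expect_equal(sl$net_displacement, 0)
  expect_equal(sl$directionality, 0)

  # 3-4-5 right-angle path
  tri <- tibble::tibble(time = c(0, 1, 2), x = c(0, 30, 30), y = c(0, 0, 40))
  st <- motility_summary(tri)
  expect_equal(st$total_distance, 70)
  expect_equal(st$net_displacement, 50)
  expect_equal(st$directionality, 5 / 7)
  expect_equal(st$mean_speed, 35)
  expect_equal(st$mean_velocity, 25)

  expect_error(motility_summary(tibble::tibble(time = c(0, 0, 1),
                                               x = 0:2, y = 0)),
               "Duplicate")
})

test_that("total distance always bounds net displacement on random tracks", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    tr <- tibble::tibble(time = seq_len(n), x = cumsum(rnorm(n)),
                         y = cumsum(rnorm(n)))
    s <- motility_summary(tr)
    expect_gte(s$total_distance, s$net_displacement - 1e-12)
    expect_gte(s$mean_speed, s$mean_velocity - 1e-12)
    expect_true(s$directionality >= 0 && s$directionality <= 1 + 1e-12)
  }
})

test_that("population summaries use the assay's error conventions", {
  one <- tibble::tibble(cell_id = 1, time = c(0, 1, 2),
                        x = c(0, 30, 30), y = c(0, 0, 40))
  pop1 <- population_motility(dplyr::bind_rows(
    one, dplyr::mutate(one, cell_id = 2), dplyr::mutate(one, cell_id = 3)))
  expect_true(all(pop1$error == 0))
  expect_identical(
    pop1$error_type[pop1$metric %in% c("net_displacement", "total_distance")],
    rep("sem", 2))
  expect_identical(
    pop1$error_type[pop1$metric %in% c("directionality", "mean_speed",
                                       "mean_velocity")],
    rep("sd", 3))
  expect_true(all(pop1$n == 3))

  # fold change by population means: 1.35x faster condition
  ctrl <- gen_cell_tracks(cell_sim_spec(n_cells = 40, mean_speed = 10,
                                        seed = 31))
  cond <- gen_cell_tracks(cell_sim_spec(n_cells = 40, mean_speed = 13.5,
                                        seed = 31))
  fc <- motility_fold_change(population_motility(cond),
                             population_motility(ctrl))
  expect_equal(fc$fold_change[fc$metric == "mean_speed"], 1.35,
               tolerance = 1e-6)
})

test_that("circularity ranks disc, square, and elongated rectangle correctly", {
  disc <- matrix(0, 120, 120)
  yy <- row(disc) - 60.5; xx <- col(disc) - 60.5
  disc[yy^2 + xx^2 <= 50^2] <- 1
  expect_gte(circularity(disc), 0.95)

  square <- matrix(0, 120, 120)
  square[11:110, 11:110] <- 1
  expect_equal(circularity(square), pi / 4, tolerance = 0.05 / (pi / 4))

  rect <- matrix(0, 40, 220)
  rect[11:30, 11:210] <- 1  # 10:1 aspect
  expect_lt(circularity(rect), 0.5)

  expect_error(circularity(matrix(0, 10, 10)), "Empty")
  two <- matrix(0, 20, 20)
  two[2:5, 2:5] <- 1
  two[12:15, 12:15] <- 1
  expect_error(circularity(two), "exactly one")
})

test_that("relative gap area is a pure area ratio", {
  m1 <- matrix(0, 50, 50); m1[, 20:30] <- 1
  same <- relative_gap_area(list(m1, m1, m1), c(0, 6, 12), pixel_size = 4)
  expect_equal(same$relative_area, c(100, 100, 100))
  expect_equal(same$gap_area[1], sum(m1) * 16)

  closed <- relative_gap_area(list(m1, matrix(0, 50, 50)), c(0, 24),
                              pixel_size = 4)
  expect_equal(closed$relative_area[2], 0)

  # invariant to pixel size
  a <- relative_gap_area(list(m1, m1 * 0), c(0, 1), pixel_size = 1)
  b <- relative_gap_area(list(m1, m1 * 0), c(0, 1), pixel_size = 7)
  expect_equal(a$relative_area, b$relative_area)

  expect_error(relative_gap_area(list(matrix(0, 5, 5), m1[1:5, 1:5]),
                                 c(0, 1), 1),
               "zero|shape")
})

test_that("dry mass follows the phase relation linearly and geometrically", {
  expect_equal(dry_mass(phase_map(matrix(0, 8, 8)))$total, 0)

  pm <- phase_map(matrix(2 * pi, 10, 10), wavelength = 0.65, alpha = 0.18,
                  pixel_size = 0.5)
  dm <- dry_mass(pm)
  expect_equal(dm$density[1, 1], 0.65 / 0.18)
  expect_equal(dm$total, 100 * (0.65 / 0.18) * 0.25)

  # linear in phase; scales with lambda and 1/alpha
  base <- matrix(runif(64), 8, 8)
  t1 <- dry_mass(phase_map(base))$total
  expect_equal(dry_mass(phase_map(2 * base))$total, 2 * t1)
  expect_equal(dry_mass(phase_map(base, wavelength = 1.3))$total,
               2 * t1, tolerance = 1e-12)
  expect_equal(dry_mass(phase_map(base, alpha = 0.36))$total, t1 / 2)

  # invariant under 90-degree rotation
  rot <- t(base[nrow(base):1, ])
  expect_equal(dry_mass(phase_map(rot))$total, t1)
})

test_that("doubling-time fits recover exact exponentials and flag no-growth", {
  t <- seq(0, 24, by = 0.5)
  s <- tibble::tibble(time = t, value = 100 * 2^(t / 16.8))
  fit <- fit_doubling_time(s)
  expect_equal(fit$doubling_time, 16.8, tolerance = 1e-9)
  expect_equal(fit$ci95, c(16.8, 16.8), tolerance = 1e-6)
  expect_equal(fit$slope, log2_slope_oracle(s$time, s$value))
  expect_equal(glance(fit)$r.squared, 1)

  # noisy series: fitted slope still equals the closed-form regression slope
  set.seed(41)
  noisy <- dplyr::mutate(s, value = value * exp(rnorm(length(t), 0, 0.05)))
  fn <- fit_doubling_time(noisy)
  expect_equal(fn$slope, log2_slope_oracle(noisy$time, noisy$value))
  expect_true(fn$ci95[1] < fn$doubling_time & fn$doubling_time < fn$ci95[2])

  expect_warning(
    flat <- fit_doubling_time(tibble::tibble(time = 0:5,
                                             value = 100 * 2^(-(0:5) / 10))),
    "unbounded")
  expect_true(flat$no_growth)
  expect_identical(flat$doubling_time, Inf)

  expect_error(fit_doubling_time(tibble::tibble(time = 0:3,
                                                value = c(1, 2, -1, 4))),
               "> 0")
  expect_error(fit_doubling_time(tibble::tibble(time = 0:2, value = 1:3)),
               "4 points")
})

test_that("doubling-time ratios reproduce the percent-of-control convention", {
  expect_equal(round(percent_of_control(12.9, 16.8)), 77)
  expect_equal(round(percent_of_control(18.1, 16.8)), 108)
  expect_error(percent_of_control(10, 0), "dt_control")
})

test_that("texture segmentation recovers a smooth central gap", {
  set.seed(55)
  img <- matrix(rnorm(200 * 200, 0.5, 0.2), 200, 200)  # textured cells
  img[, 81:120] <- 0.5                                  # smooth gap band
  gap <- segment_gap(img)
  expect_gt(mean(gap[, 91:110]), 0.9)   # gap interior recovered
  expect_lt(mean(gap[, c(1:60, 141:200)]), 0.1)  # cell field excluded
})
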