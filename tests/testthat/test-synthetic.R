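test_that("rendering is deterministic for a fixed seed", {
  sc <- scenario("fsk_ibmx_saturating", n_cells = 2, duration_min = 4,
                 seed = 11)
  a <- render_movie(sc)
  b <- render_movie(sc)
  expect_identical(a$movie$channels, b$movie$channels)
  expect_identical(a$truth$expression, b$truth$expression)

  d1 <- tempfile(); d2 <- tempfile()
  write_movie(a$movie, d1); write_movie(b$movie, d2)
  for (ch in names(a$movie$channels)) {
    f1 <- file.path(d1, paste0(ch, ".tif")); f2 <- file.path(d2, paste0(ch, ".tif"))
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  # different seed changes the pixels
  c2 <- render_movie(scenario("fsk_ibmx_saturating", n_cells = 2,
                              duration_min = 4, seed = 12))
  expect_false(identical(a$movie$channels, c2$movie$channels))
})

test_that("movies round-trip through multi-page TIFF", {
  sc <- scenario("fsk_ibmx_saturating", n_cells = 2, duration_min = 4,
                 seed = 3)
  syn <- render_movie(sc)
  dir <- tempfile()
  write_movie(syn$movie, dir)
  back <- read_movie(dir)
  expect_equal(back$t_min, syn$movie$t_min)
  expect_equal(back$pixel_size, syn$movie$pixel_size)
  # rendered counts are non-negative integers, so quantisation is lossless
  expect_equal(back$channels$CFP[[1]], round(syn$movie$channels$CFP[[1]]),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(write_ground_truth(syn$truth, file.path(dir, "gt.json")), NA)
})

test_that("saturating-stimulation movies impose the calibrated dynamic range", {
  cal <- ratio_calibration()
  sc <- scenario("fsk_ibmx_saturating", n_cells = 3, noise = "off", seed = 5)
  syn <- render_movie(sc, cal = cal)
  expect_equal(syn$truth$max_ratio_increase_pct, 100 * cal$DR)
  # noise off: the analysis recovers the imposed increase exactly
  rs <- analyze_fret_movie(syn$movie, segment_threshold = 350)
  inc <- max_ratio_increase(rs)
  expect_equal(nrow(inc), 3)
  expect_equal(inc$max_increase_pct, rep(100 * cal$DR, 3), tolerance = 1e-9)
})

test_that("chip movies visualise the gradient in the dye channel", {
  sc <- scenario("chip_gradient", n_cells = 3, duration_min = 4,
                 c_source = 20, c_sink = 0, seed = 9)
  syn <- render_movie(sc)
  slope <- recover_dye_slope(syn$movie, syn$truth)
  expect_equal(slope, 0.08, tolerance = 0.02)
  expect_equal(syn$truth$slope_nM_per_um, 0.08)
})

test_that("camera noise is Poisson-dominated above the dark level", {
  sc <- scenario("fsk_ibmx_saturating", n_cells = 1, duration_min = 4,
                 seed = 21)
  syn <- render_movie(sc)
  # pixels of the cell interior share one expected signal; variance across
  # them estimates the noise model
  masks <- threshold_segment(syn$movie$channels$YFP[[1]], 350)
  core <- erode_mask(masks[[1]]$mask, 3)
  px <- syn$movie$channels$CFP[[1]][core] - sc$noise$dark
  expect_gt(var(px) / mean(px), 0.8)
  expect_lt(var(px) / mean(px), 1.3)
})

test_that("migration tracks follow the scenario reversal rules", {
  # zero speed and noise: constant tracks
  sc <- scenario("dmso_control", n_cells = 4, duration_min = 30, seed = 2)
  tr <- make_migration_tracks(sc, migration_params(v0 = 0, sigma_step = 0))
  expect_true(all(tr$tracks$displacement_um == 0))

  # control with full initial upward bias: drift dominates the mean
  sc <- scenario("no_membrane_anchor_control", n_cells = 40,
                 duration_min = 120, seed = 4)
  tr <- make_migration_tracks(sc, migration_params(p_up_init = 1))
  expect_equal(tr$truth$rule, "none")
  m <- tr$tracks |>
    dplyr::group_by(t_min) |>
    dplyr::summarise(mean = mean(displacement_um))
  expect_true(all(diff(m$mean) > 0))

  # gradient scenario: every cell points down the gradient after its tau
  sc <- scenario("chip_gradient", n_cells = 10, duration_min = 120,
                 frame_interval_min = 5, seed = 6)
  tr <- make_migration_tracks(sc)
  expect_equal(tr$truth$rule, "flip")
  late <- tr$tracks[tr$tracks$t_min > 60, ]
  expect_true(all(late$s == -1))

  # uniform 100 nM: polarity is resampled; both signs appear late
  sc <- scenario("chip_uniform", dose = 100, n_cells = 30,
                 duration_min = 120, frame_interval_min = 5, seed = 8)
  tr <- make_migration_tracks(sc)
  expect_equal(tr$truth$rule, "randomize")
  late <- tr$tracks[tr$tracks$t_min == 120, ]
  expect_true(any(late$s == 1) && any(late$s == -1))

  # uniform 20 nM keeps polarity fixed
  sc <- scenario("chip_uniform", dose = 20, n_cells = 5, duration_min = 30,
                 seed = 8)
  expect_equal(make_migration_tracks(sc)$truth$rule, "none")
})

test_that("full loop: analysis recovers ground truth from rendered movies", {
  # FRET ratio time courses at default noise (RMS < 0.01 ratio units)
  cal <- ratio_calibration()
  sc <- scenario("fsk_ibmx_saturating", n_cells = 4, seed = 31)
  syn <- render_movie(sc, cal = cal)
  rs <- analyze_fret_movie(syn$movie, 350)
  per_cell_rms <- rs |>
    dplyr::filter(!excluded) |>
    dplyr::group_by(cell) |>
    dplyr::arrange(t_min, .by_group = TRUE) |>
    dplyr::summarise(rms = sqrt(mean((mean_ratio - syn$truth$ratio)^2)))
  expect_equal(nrow(per_cell_rms), 4)
  expect_true(all(per_cell_rms$rms < 0.01))

  # cytoplasmic depletion curves (< 3% relative error on the drop series)
  sc <- scenario("dish_uniform", dose = 100, n_cells = 4, duration_min = 12,
                 seed = 32)
  syn <- render_movie(sc)
  masks <- threshold_segment(syn$movie$channels$YFP[[1]], 350)
  ser <- cytoplasmic_intensity_series(syn$movie, masks)
  err <- ser |>
    dplyr::group_by(cell) |>
    dplyr::summarise(max_err = max(abs(drop - syn$truth$drop)))
  expect_true(all(err$max_err < 0.03 * max(syn$truth$drop)))

  # translocation parameter recovery within 10% relative error
  fits <- ser |>
    dplyr::group_by(cell) |>
    dplyr::group_modify(~ glance(fit_depletion(.x))) |>
    dplyr::ungroup()
  expect_true(all(abs(fits$k - syn$truth$k) / syn$truth$k < 0.1))
  expect_true(all(abs(fits$plateau - syn$truth$plateau_drop) /
                    syn$truth$plateau_drop < 0.1))

  # nuclear displacements exact to <= 1 px
  sc <- scenario("dmso_control", n_cells = 4, duration_min = 30,
                 frame_interval_min = 5, seed = 33)
  tracks <- make_migration_tracks(sc)
  syn <- render_migration_movie(sc, tracks)
  rec <- nuclear_displacement(syn$movie, threshold = 800)
  for (i in 1:4) {
    got <- rec$y_px[rec$cell == i]
    truth <- syn$truth$y_px[i, ]
    expect_true(all(abs(got - truth) <= 1))
  }
})

test_that("fixture suite is self-consistent", {
  fx <- fixture_suite(seed = 99)
  expect_equal(fx$manifest$seed[1], 99)
  expect_equal(sum(fx$disk$frame > 0), fx$disk$expected$area)
  expect_equal(length(fx$translated_nucleus$frames), 6)
  expect_equal(length(fx$ramp$expected$bin_means), 20)
})
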