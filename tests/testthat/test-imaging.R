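fx <- fixture_suite()

test_that("threshold segmentation finds disks with exact areas and ordering", {
  expect_length(threshold_segment(matrix(0, 32, 32), 10), 0)

  masks <- threshold_segment(fx$disk$frame, 100)
  expect_length(masks, 1)
  expect_equal(masks[[1]]$area, fx$disk$expected$area)
  expect_equal(unname(masks[[1]]$centroid), fx$disk$expected$centroid)

  masks <- threshold_segment(fx$two_disks$frame, 100, min_area = 20)
  expect_length(masks, 2)
  expect_lt(masks[[1]]$centroid["row"], masks[[2]]$centroid["row"])
  expect_equal(vapply(masks, `[[`, integer(1), "area"),
               fx$two_disks$expected$areas)

  # threshold above the maximum intensity is not an error
  expect_length(threshold_segment(fx$disk$frame, 1e6), 0)

  # debris below min_area is discarded
  tiny <- matrix(0, 20, 20); tiny[5:6, 5:6] <- 100
  expect_length(threshold_segment(tiny, 10), 0)
})

test_that("component labelling is 8-connected", {
  m <- matrix(0, 5, 5)
  m[1, 1] <- 1; m[2, 2] <- 1; m[3, 3] <- 1 # diagonal chain
  lab <- label_components(m)
  expect_equal(max(lab), 1)
  m[5, 5] <- 1
  expect_equal(max(label_components(m)), 2)
})

test_that("erosion is monotone and excludes rims of its depth exactly", {
  mask <- fx$rimmed_disk$mask
  er <- erode_mask(mask, 20)
  expect_true(all(mask[er])) # eroded mask is a subset
  expect_true(any(er))
  # the 10-px bright rim lies entirely outside the 20-px eroded core
  expect_equal(mean(fx$rimmed_disk$frame[er]),
               fx$rimmed_disk$expected$post_erosion_mean)
  # eroding a thin object to nothing
  thin <- matrix(FALSE, 30, 30); thin[10:20, 14:16] <- TRUE
  expect_false(any(erode_mask(thin, 2)))
})

test_that("ratio maps are dark-corrected and masked", {
  masks <- threshold_segment(fx$disk$frame, 100)
  df <- 50
  cfp <- fx$disk$frame + df
  fret <- fx$disk$frame + df
  map <- fret_ratio_map(fret, cfp, masks, df, df)
  expect_true(all(map[masks[[1]]$mask] == 1))
  expect_true(all(is.na(map[!masks[[1]]$mask])))

  # numerator equal to the dark frame gives ratio 0
  map0 <- fret_ratio_map(matrix(df, 64, 64), cfp, masks, df, df)
  expect_true(all(map0[masks[[1]]$mask] == 0))

  # non-positive denominator pixels are undefined, not infinite
  bad_cfp <- cfp; bad_cfp[32, 32] <- df
  mapb <- fret_ratio_map(fret, bad_cfp, masks, df, df)
  expect_true(is.na(mapb[32, 32]))

  expect_error(fret_ratio_map(matrix(0, 3, 3), matrix(0, 4, 4), masks),
               "shape")

  # imposed uniform ratio recovered exactly without noise
  map13 <- fret_ratio_map(1.30 * (cfp - df) + df, cfp, masks, df, df)
  expect_equal(cell_mean_ratio(map13, masks[[1]])$mean_ratio, 1.30)
})

test_that("cell means respect the expression filter", {
  masks <- threshold_segment(fx$disk$frame, 100)
  m <- masks[[1]]
  map <- matrix(NA_real_, 64, 64)
  map[m$mask] <- 2.5
  expect_equal(cell_mean_ratio(map, m)$mean_ratio, 2.5)

  res <- cell_mean_ratio(map, m, expression_frame = matrix(10, 64, 64),
                         min_expression = 100)
  expect_true(res$excluded)
  expect_match(res$reason, "expression")

  # half at 1.0, half at 2.0 with equal pixel counts
  half <- matrix(NA_real_, 64, 64)
  rows <- which(m$mask, arr.ind = TRUE)
  med <- stats::median(unique(rows[, 2]))
  half[m$mask] <- ifelse(which(m$mask, arr.ind = TRUE)[, 2] <= med, 1, 2)
  n1 <- sum(half[m$mask] == 1); n2 <- sum(half[m$mask] == 2)
  expect_equal(cell_mean_ratio(half, m)$mean_ratio,
               (n1 * 1 + n2 * 2) / (n1 + n2))

  # no defined pixels -> excluded with reason
  empty <- matrix(NA_real_, 64, 64)
  expect_true(cell_mean_ratio(empty, m)$excluded)
})

test_that("cytoplasmic tracking erodes the rim away and normalises to t0", {
  # static movie: rimmed disk repeated; rim at 200, core at 100
  frames <- rep(list(fx$rimmed_disk$frame + 100), 4)
  movie <- pkaprozone:::new_movie(list(mCherry = frames, YFP = frames),
                                  t_min = 0:3, pixel_size = 0.389,
                                  dark = list(mCherry = 100, YFP = 100))
  masks <- list(list(id = 1L, mask = fx$rimmed_disk$mask,
                     area = sum(fx$rimmed_disk$mask),
                     centroid = c(row = 64, col = 64)))
  ser <- cytoplasmic_intensity_series(movie, masks, erosion_px = 20)
  expect_equal(ser$intensity,
               rep(fx$rimmed_disk$expected$post_erosion_mean, 4))
  expect_true(all(ser$norm == 1))
  expect_true(all(ser$drop == 0))

  # a cell thinner than the erosion depth is flagged and omitted
  thin_mask <- matrix(FALSE, 128, 128); thin_mask[40:80, 60:70] <- TRUE
  ser2 <- cytoplasmic_intensity_series(
    movie, c(masks, list(list(id = 2L, mask = thin_mask, area = sum(thin_mask),
                              centroid = c(row = 60, col = 65)))),
    erosion_px = 20
  )
  expect_equal(unique(ser2$cell), 1)
  expect_match(attr(ser2, "exclusions"), "cell 2")
})

test_that("nuclear displacement tracks integer translations exactly", {
  frames <- fx$translated_nucleus$frames
  movie <- pkaprozone:::new_movie(list(CFP = frames), t_min = 0:5,
                                  pixel_size = 0.389, dark = list(CFP = 0))
  tr <- nuclear_displacement(movie, threshold = 500)
  expect_equal(tr$displacement_um[1], 0)
  # +3 px per frame toward the source (up) for 5 frames at 0.389 um/px
  expect_equal(tr$displacement_um[6],
               fx$translated_nucleus$expected$displacement_um_frame5,
               tolerance = 1e-9)
  expect_false(any(tr$missing))

  # static nucleus
  movie0 <- pkaprozone:::new_movie(list(CFP = rep(frames[1], 3)), t_min = 0:2,
                                   pixel_size = 0.389, dark = list(CFP = 0))
  tr0 <- nuclear_displacement(movie0, 500)
  expect_true(all(tr0$displacement_um == 0))

  # threshold above max -> all missing, no interpolation
  trm <- nuclear_displacement(movie, threshold = 1e6)
  expect_true(all(trm$missing))
  expect_true(all(is.na(trm$displacement_um)))
})

test_that("binned profiles recover imposed ramps", {
  # uniform ratio -> identical bins
  mask <- list(id = 1L, mask = fx$ramp$mask, area = sum(fx$ramp$mask),
               centroid = c(row = 30, col = 20))
  uni <- fx$ramp$ratio; uni[!is.na(uni)] <- 1.7
  bp <- bin_profile(uni, mask)
  expect_equal(nrow(bp), 20)
  expect_true(all(bp$mean_ratio == 1.7))

  # linear ramp: bin means match the fixture manifest and are affine
  bp <- bin_profile(fx$ramp$ratio, mask)
  expect_equal(bp$mean_ratio, fx$ramp$expected$bin_means, tolerance = 1e-12)
  expect_equal(diff(bp$mean_ratio), rep(diff(bp$mean_ratio)[1], 19),
               tolerance = 1e-9)
  # imposed ramp increases away from the top: front-minus-rear is negative
  expect_lt(mean(bp$mean_ratio[bp$position < 0.5]) -
              mean(bp$mean_ratio[bp$position >= 0.5]), 0)

  # extent of exactly 20 px: one pixel row per bin
  small <- matrix(FALSE, 30, 10); small[6:25, 3:8] <- TRUE
  msk <- list(id = 1L, mask = small, area = sum(small),
              centroid = c(row = 15, col = 5))
  vals <- matrix(NA_real_, 30, 10); vals[small] <- rep(1:20, each = 1)[row(small)[small] - 5]
  bp1 <- bin_profile(vals, msk)
  expect_equal(bp1$mean_ratio, as.numeric(1:20))

  # undersized extent is rejected with the reason
  tiny <- matrix(FALSE, 30, 10); tiny[6:15, 3:8] <- TRUE
  expect_error(bin_profile(vals, list(id = 1, mask = tiny), n_bins = 20),
               "extent")
})

test_that("population statistics match the textbook pooled t computation", {
  df <- tibble::tibble(
    cell = rep(1:6, each = 2),
    t_min = rep(c(0, 10), 6),
    value = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2),
    group = rep(c("a", "b"), each = 6)
  )
  out <- population_stats(df, group = "group", test_at = 10)
  expect_equal(out$series$mean, rep(c(1, 2), 2))
  expect_equal(out$series$n, rep(3L, 4))
  expect_true(all(out$series$sem == 0))
  # constant identical vectors in both groups: t = 0, p = 1
  expect_equal(out$test$statistic, 0)
  expect_equal(out$test$p.value, 1)
  # identical non-constant groups also give p = 1
  df2 <- df
  df2$value <- c(1, 1, 2, 2, 3, 3, 1, 1, 2, 2, 3, 3)
  out2 <- population_stats(df2, group = "group", test_at = 10)
  expect_equal(out2$test$p.value, 1)

  # long-hand pooled-variance oracle on fixed arrays
  x <- c(2.1, 2.9, 3.4, 2.2); y <- c(3.1, 3.8, 4.4)
  got <- pooled_t_test(x, y)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  p_hand <- 2 * pt(-abs(t_hand), length(x) + length(y) - 2)
  expect_equal(got$statistic, t_hand)
  expect_equal(got$p.value, p_hand)
  expect_equal(got$df, length(x) + length(y) - 2)

  # SEM definition: sample SD over sqrt(n)
  s <- population_stats(tibble::tibble(cell = 1:3, t_min = 0,
                                       value = c(1, 2, 6)))$series
  expect_equal(s$sem, sd(c(1, 2, 6)) / sqrt(3))

  # test refused when a group has n < 2, means still reported
  df3 <- tibble::tibble(cell = 1:3, t_min = 0, value = 1:3,
                        group = c("a", "a", "b"))
  out3 <- population_stats(df3, group = "group", test_at = 0)
  expect_true(out3$test$refused)
  expect_equal(nrow(out3$series), 2)
  expect_error(pooled_t_test(1, c(1, 2)), "n >= 2")
})
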