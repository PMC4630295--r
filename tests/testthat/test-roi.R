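test_that("contrast t-map handles trivial and separation cases", {
  d <- block_design(n_blocks = 4, block_duration = 8, sample_interval = 2)
  dims <- c(3, 3, 2, d$n_timepoints)
  set.seed(17)
  x <- array(rnorm(prod(dims)), dims)
  # same condition on both sides -> t = 0
  t0 <- contrast_tmap(x, d, cond_a = "on", cond_b = "on")
  expect_true(all(abs(t0) < 1e-12))
  # large clean shift -> huge positive t
  x[1, 1, 1, ] <- 0.01 * rnorm(dims[4]) + 100 * (d$labels == "on")
  tm <- contrast_tmap(x, d)
  expect_gt(tm[1, 1, 1], 50)
  # degenerate voxel -> NaN
  x[2, 2, 2, ] <- 5
  expect_true(is.nan(contrast_tmap(x, d)[2, 2, 2]))
  expect_error(contrast_tmap(x, d, cond_a = "faces"),
               class = "phasereg_error_config")
})

test_that("contrast t-map applies the hemodynamic delay shift", {
  d <- block_design(n_blocks = 6, block_duration = 8, sample_interval = 2,
                    hemodynamic_delay = 6)
  dims <- c(2, 1, 1, d$n_timepoints)
  x <- array(rnorm(prod(dims), sd = 0.1), dims)
  # response delayed by exactly 3 samples matches the shifted labels
  lagged <- c(rep(0, 3), 10 * (d$labels == "on"))[seq_len(dims[4])]
  x[1, 1, 1, ] <- x[1, 1, 1, ] + lagged
  expect_gt(contrast_tmap(x, d)[1, 1, 1], 20)
  expect_lt(contrast_tmap(x, d, delay = 0)[1, 1, 1],
            contrast_tmap(x, d)[1, 1, 1])
})

test_that("pooled t matches t.test on a single voxel", {
  d <- block_design(n_blocks = 2, block_duration = 10)
  x <- array(0, c(1, 1, 1, 20))
  set.seed(23)
  x[1, 1, 1, ] <- rnorm(20) + 2 * (d$labels == "on")
  ref <- t.test(x[1, 1, 1, d$labels == "on"], x[1, 1, 1, d$labels == "off"],
                var.equal = TRUE)
  expect_equal(contrast_tmap(x, d)[1, 1, 1], unname(ref$statistic))
})

test_that("ROI definition picks the largest face-connected cluster per hemisphere", {
  tm <- array(0, c(8, 4, 3))
  # left hemisphere (x <= 4): cluster of 5 and cluster of 3
  tm[1:2, 1, 1] <- 5; tm[1, 2, 1] <- 5; tm[1:2, 1, 2] <- 5   # size 5
  tm[4, 4, 1:3] <- 6                                          # size 3
  # right hemisphere: diagonal voxels are NOT face-connected
  tm[6, 2, 2] <- 4; tm[7, 3, 2] <- 4
  roi <- define_roi(tm, threshold = 3, split_x = 4)
  expect_equal(roi$left$n_voxels, 5)
  expect_equal(roi$left$mean_t, 5)
  expect_equal(roi$right$n_voxels, 1)

  # all sub-threshold -> empty ROI is valid
  roi0 <- define_roi(array(0, c(4, 4, 2)))
  expect_equal(roi0$left$n_voxels, 0)
  expect_true(is.na(roi0$left$mean_t))
})

test_that("cluster-size ties break by mean t then lowest linear index", {
  tm <- array(0, c(6, 2, 2))
  tm[1:2, 1, 1] <- 4        # size 2, mean 4
  tm[1:2, 2, 2] <- c(6, 6)  # size 2, mean 6 -> wins
  roi <- define_roi(tm, threshold = 3, split_x = 6)
  expect_equal(roi$left$mean_t, 6)
  # exact tie in mean t -> lowest linear index wins
  tm2 <- array(0, c(6, 2, 2))
  tm2[3:4, 1, 1] <- 4
  tm2[1:2, 2, 2] <- 4
  roi2 <- define_roi(tm2, threshold = 3, split_x = 6)
  expect_equal(sort(roi2$left$voxels$x), c(3, 4))
  expect_equal(roi2$left$voxels$z, c(1, 1))
})

test_that("vein contribution metrics follow the normalized-size definitions", {
  mk_roi <- function(n, mean_t, hemi = "right") {
    structure(list(voxels = tibble::tibble(), n_voxels = n, mean_t = mean_t,
                   hemisphere = hemi, threshold = 3), class = "roi_result")
  }
  vc <- vein_contribution(mk_roi(100, 8), mk_roi(62, 6))
  expect_equal(vc$n_norm, 0.62)
  expect_equal(vc$percent_vein, 38)
  expect_equal(vc$metric1, 38)
  expect_equal(vc$metric2, 2)
  expect_equal(vc$percent_vein, (1 - vc$n_norm) * 100, tolerance = 1e-12)

  same <- mk_roi(10, 5)
  vc0 <- vein_contribution(same, same)
  expect_equal(vc0$percent_vein, 0)
  expect_equal(vc0$metric1, 0)
  expect_equal(vc0$metric2, 0)

  vc100 <- vein_contribution(mk_roi(10, 5), mk_roi(0, NA_real_))
  expect_equal(vc100$percent_vein, 100)
  expect_equal(vc100$metric1, 10)

  anom <- vein_contribution(mk_roi(10, 5), mk_roi(12, 5))
  expect_equal(anom$flag, "spr_roi_larger_than_mag")
  expect_error(vein_contribution(mk_roi(0, NA_real_), mk_roi(0, NA_real_)),
               class = "phasereg_error_data")
})

test_that("laterality indices match their definitions and flag degeneracy", {
  mk_roi <- function(n, mean_t, hemi) {
    structure(list(voxels = tibble::tibble(), n_voxels = n, mean_t = mean_t,
                   hemisphere = hemi, threshold = 3), class = "roi_result")
  }
  l <- laterality(mk_roi(67, 5, "right"), mk_roi(33, 5, "left"))
  expect_equal(l$size_lat, 0.34)
  expect_equal(l$fsnr_lat, 0)
  expect_equal(laterality(mk_roi(50, 4, "right"), mk_roi(50, 6, "left"))$size_lat, 0)
  expect_equal(laterality(mk_roi(10, 4, "right"), mk_roi(0, NA, "left"))$size_lat, 1)
  empty <- laterality(mk_roi(0, NA, "right"), mk_roi(0, NA, "left"))
  expect_true(is.na(empty$size_lat))
  expect_equal(empty$flag, "undefined")
})

test_that("group-level utilities wrap the standard tests", {
  df <- tibble::tibble(
    n_mag = c(100, 80, 60, 40), n_spr = c(60, 60, 50, 38),
    metric1 = c(40, 20, 10, 2), mean_t_mag = c(9, 7, 5, 4)
  )
  rc <- roi_metric_correlation(df)
  expect_equal(rc$estimate, cor(df$metric1, df$mean_t_mag))
  pt <- roi_paired_test(df)
  expect_equal(unname(pt$df), 3)
  expect_gt(pt$statistic, 0)
})

test_that("vein contribution grows with the vein's task phase amplitude", {
  # 3-point sweep of the oxygenation change driving the vein response
  spec <- phantom_single_vein()
  res <- lapply(c(0.62, 0.66, 0.70), function(ya) {
    veins <- list(vein_model(center = c(15, 0, 5), radius = 0.5,
                             theta = pi / 2, azimuth = pi / 2,
                             oxygenation_active = ya))
    st <- phantom_signal(spec$grid, veins, subdivisions = 9,
                         background_phase = spec$background_phase)
    tr <- preprocess_series(synthesize_phantom(
      spec$grid, veins, spec$design, noise_sd = spec$noise_sd, seed = 61,
      states = st, background_phase = spec$background_phase))
    te <- preprocess_series(synthesize_phantom(
      spec$grid, veins, spec$design, noise_sd = spec$noise_sd, seed = 62,
      states = st, background_phase = spec$background_phase))
    tm <- contrast_tmap(te, spec$design)
    ts <- contrast_tmap(suppress_volume(tr, te, method = "sPR"), spec$design)
    # single-structure phantom: analyse the hemisphere containing the vein
    vein_contribution(define_roi(tm, split_x = 4)$right,
                      define_roi(ts, split_x = 4)$right)
  })
  m1 <- vapply(res, function(r) r$metric1, numeric(1))
  m2 <- vapply(res, function(r) r$metric2, numeric(1))
  expect_true(all(diff(m1) > 0))
  expect_true(all(diff(m2) > 0))
})
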