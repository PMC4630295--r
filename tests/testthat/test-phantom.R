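test_that("field model zeros: parallel veins outside, magic angle inside", {
  par <- vein_model(center = c(0, 0, 0), radius = 1, theta = 0)
  pts <- cbind(runif(20, 2, 10), runif(20, -5, 5), runif(20, 2, 10))
  expect_true(all(abs(offres_field(pts, par)) < 1e-12))

  magic <- vein_model(center = c(0, 0, 0), radius = 2,
                      theta = acos(sqrt(1 / 3)))
  inside <- cbind(runif(10, -0.5, 0.5), runif(10, -0.5, 0.5),
                  runif(10, -0.5, 0.5))
  expect_true(all(abs(offres_field(inside, magic)) < 1e-12))
})

test_that("extravascular field matches the closed dipole form", {
  vm <- vein_model(center = c(0, 0, 0), radius = 1, theta = pi / 2,
                   azimuth = pi / 2)  # axis along y, B0 along z
  dchi <- vm$dchi_do * vm$hematocrit * (1 - vm$oxygenation_rest) * 1e-6
  f0 <- 42.577478518e6 * vm$field_strength
  # r = 2R along the projected B0 direction (phi = 0): + (dchi/8) f0
  expect_equal(offres_field(c(0, 3, 2), vm), dchi * f0 / 8, tolerance = 1e-10)
  # phi = 90 deg (lateral): cos(2 phi) = -1
  expect_equal(offres_field(c(2, -1, 0), vm), -dchi * f0 / 8, tolerance = 1e-10)
  # inside, perpendicular: (dchi/6) f0 (3 cos^2 - 1) = -(dchi/6) f0
  expect_equal(offres_field(c(0.2, 5, 0.1), vm), -dchi * f0 / 6,
               tolerance = 1e-10)
  # decay as (R/r)^2
  expect_equal(offres_field(c(0, 0, 4), vm) / offres_field(c(0, 0, 2), vm),
               0.25, tolerance = 1e-10)
})

test_that("extravascular field integrates to zero over a full annulus", {
  vm <- vein_model(center = c(0, 0, 0), radius = 1, theta = pi / 3,
                   azimuth = 0.7)
  u <- c(sin(vm$theta) * cos(vm$azimuth), sin(vm$theta) * sin(vm$azimuth),
         cos(vm$theta))
  e1 <- c(0, 0, 1) - cos(vm$theta) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ang <- seq(0, 2 * pi, length.out = 3600)[-1]
  ring <- 2.5 * (cos(ang) %o% e1 + sin(ang) %o% e2)
  f <- offres_field(ring, vm)
  expect_lt(abs(mean(f)), 1e-6 * max(abs(f)))
})

test_that("noiseless voxel phase is linear in TE in the small-angle regime", {
  grid <- phantom_grid(dim = c(10, 4, 3), voxel_size = c(2, 2, 2))
  vm <- vein_model(center = c(9, 0, 3), radius = 0.5, theta = pi / 2,
                   azimuth = pi / 2)
  s1 <- phantom_signal(grid, vm, subdivisions = 9, echo_time = 0.004)
  s2 <- phantom_signal(grid, vm, subdivisions = 9, echo_time = 0.008)
  # a voxel two steps from the vein: weak single-polarity field, small phase
  p1 <- Arg(s1$off[7, 2, 2])
  p2 <- Arg(s2$off[7, 2, 2])
  expect_lt(abs(p2), pi / 2)
  expect_equal(p2 / p1, 2, tolerance = 0.05)
})

test_that("halving the subvoxel sampling changes voxel signals by < 1%", {
  spec <- phantom_single_vein()
  hi <- phantom_signal(spec$grid, spec$veins, subdivisions = 15)
  lo <- phantom_signal(spec$grid, spec$veins, subdivisions = 7)
  tissue <- exp(-spec$veins[[1]]$echo_time / spec$veins[[1]]$t2star_tissue)
  expect_lt(max(Mod(hi$off - lo$off)) / tissue, 0.01)
  expect_error(phantom_signal(spec$grid, spec$veins, subdivisions = 3),
               class = "phasereg_error_config")
})

test_that("phantom realizes the vein / adjacent / far fSNR taxonomy", {
  spec <- phantom_single_vein()
  vx <- spec$voxels
  d <- spec$design
  for (seed in 1:3) {
    pre <- single_vein_pre(seed)
    fsnr <- function(v, what) realized_fsnr(pre[[what]][v[1], v[2], v[3], ], d)
    expect_gt(fsnr(vx$vein, "magnitude"), 3)
    expect_lt(abs(fsnr(vx$vein, "phase")), 1.5)
    expect_lt(abs(fsnr(vx$adjacent, "magnitude")), 1.5)
    expect_gt(abs(fsnr(vx$adjacent, "phase")), 3)
    expect_lt(abs(fsnr(vx$far, "magnitude")), 1)
    expect_lt(abs(fsnr(vx$far, "phase")), 1)
  }
})

test_that("synthesized phantoms are deterministic, wrapped, and well-formed", {
  spec <- phantom_single_vein()
  st <- single_vein_states()
  a <- synthesize_phantom(spec$grid, spec$veins, spec$design, noise_sd = 0.005,
                          seed = 77, states = st)
  b <- synthesize_phantom(spec$grid, spec$veins, spec$design, noise_sd = 0.005,
                          seed = 77, states = st)
  expect_identical(a$magnitude, b$magnitude)
  expect_true(all(a$phase > -pi & a$phase <= pi))
  expect_true(all(a$magnitude >= 0))
  expect_equal(dim(a$magnitude)[4], spec$design$n_timepoints)
})

test_that("venogram mIP darkens and connects the vein", {
  vol <- array(1, c(6, 6, 5))
  expect_equal(venogram_mip(vol, 1), vol)
  vol[, , 3] <- 0.2
  m <- venogram_mip(vol, 3)
  expect_true(all(m[, , 2:4] == 0.2))
  expect_true(all(m[, , c(1, 5)] == 1))
  expect_error(venogram_mip(vol, 2), class = "phasereg_error_config")
  expect_error(venogram_mip(vol, 7), class = "phasereg_error_config")

  # phantom vein appears as a connected dark tube
  grid <- phantom_grid(dim = c(24, 16, 9), voxel_size = c(1, 1, 1))
  vm <- vein_model(center = c(12, 0, 4.5), radius = 0.5, theta = pi / 2,
                   azimuth = pi / 2, echo_time = 0.026)
  st <- phantom_signal(grid, vm, subdivisions = 9, echo_time = 0.026)
  mip <- venogram_mip(Mod(st$off), 3)
  tissue_mean <- mean(Mod(st$off)[20:24, , ])
  vein_line <- mip[12, , 5]
  expect_true(all(vein_line < 0.6 * tissue_mean))
})
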