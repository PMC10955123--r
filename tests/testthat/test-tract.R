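test_that("fractional anisotropy matches the closed form", {
  expect_equal(fractional_anisotropy(c(2, 2, 2) * 1e-3), 0)
  expect_equal(fractional_anisotropy(c(1, 0, 0)), 1)
  expect_equal(fractional_anisotropy(c(1.7, 0.2, 0.2) * 1e-3), 0.8704,
               tolerance = 5e-5)
  expect_error(fractional_anisotropy(c(0, 0, 0)), "all-zero")
  expect_error(fractional_anisotropy(c(-1, 1, 1)), ">= 0")
})

test_that("tensor fit round-trips noiseless signals to 1e-8", {
  set.seed(61)
  g <- sphere_directions(48)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  D0 <- R %*% diag(c(1.7e-3, 3e-4, 2e-4)) %*% t(R)
  S <- exp(-400 * rowSums((g %*% D0) * g))
  Dh <- fit_tensor_lls(S, g, 400, 1)
  expect_lt(max(abs(Dh - D0)) / max(abs(D0)), 1e-8)
  # equal signals in every direction -> isotropic tensor
  Di <- fit_tensor_lls(rep(0.5, 48), g, 400, 1)
  expect_equal(Di, diag(rep(Di[1, 1], 3)), tolerance = 1e-12)
  expect_error(fit_tensor_lls(rep(0.5, 5), g[1:5, ], 400, 1), "at least 6")
})

test_that("phantom eigenvalues realize the target FA exactly", {
  for (fa in c(0, 0.1, 0.3, sqrt(0.5), 0.9)) {
    ph <- simulate_phantom(phantom_spec(grid_shape = c(8L, 8L, 10L),
                                        fa_target = fa,
                                        fascicle_length_true = 10))
    expect_equal(fractional_anisotropy(ph$ground_truth$eigenvalues), fa,
                 tolerance = 1e-12)
  }
  expect_error(phantom_spec(fa_target = 1), "fa_target")
})

test_that("uniform straight field tracks a straight line across the slab", {
  ph <- simulate_phantom(phantom_spec(grid_shape = c(16L, 16L, 40L),
                                      voxel_size = 2,
                                      fascicle_length_true = 60))
  ctr <- ph$volume$dim * ph$volume$voxel_size / 2
  sl <- track_streamline(ph$volume, ctr, step = 1)
  expect_equal(sl$length, 60, tolerance = 2.5)
  # perfectly straight: all points share the seed's x and y
  expect_lt(max(abs(sweep(sl$points[, 1:2], 2, ctr[1:2]))), 1e-9)
  expect_lte(sl$length, 200)
})

test_that("tracking stop rules fire: FA bounds, mask exit, seed checks", {
  ph <- simulate_phantom(phantom_spec(grid_shape = c(10L, 10L, 12L),
                                      fa_target = 0.02,
                                      fascicle_length_true = 12))
  ctr <- ph$volume$dim * ph$volume$voxel_size / 2
  sl <- track_streamline(ph$volume, ctr, fa_min = 0.05)   # seed FA below band
  expect_equal(sl$length, 0)
  expect_error(track_streamline(ph$volume, c(-5, -5, -5)), "outside the mask")
})

test_that("phantom fascicle length is recovered within 5%", {
  ph <- simulate_phantom(phantom_spec(fascicle_length_true = 40))
  sls <- track_volume(ph$volume, max_seeds = 40)
  ts <- tract_statistics(sls, ph$volume)
  expect_equal(ts$fascicle_length, 40, tolerance = 0.05)
  expect_equal(ts$mean_fa, 0.3, tolerance = 1e-6)
  expect_lte(ts$fascicle_volume, ph$ground_truth$mask_volume)
})

test_that("RK4 endpoint error shrinks ~16x per step halving, Euler ~2x", {
  R <- 30
  arc_err <- function(step, method) {
    n <- round(pi * R / 2 / step)
    pts <- integrate_direction_field(circle_field, c(R, 0, 0), step, n, method)
    truth <- c(R * cos(n * step / R), R * sin(n * step / R), 0)
    sqrt(sum((pts[nrow(pts), ] - truth)^2))
  }
  r_rk4 <- arc_err(1, "rk4") / arc_err(0.5, "rk4")
  r_euler <- arc_err(1, "euler") / arc_err(0.5, "euler")
  expect_gte(r_rk4, 12)
  expect_equal(r_euler, 2, tolerance = 0.3)
})

test_that("tracking is invariant under a global axis rotation", {
  ph <- simulate_phantom(phantom_spec(grid_shape = c(20L, 20L, 20L),
                                      voxel_size = 2,
                                      fascicle_length_true = 24))
  ctr <- ph$volume$dim * ph$volume$voxel_size / 2
  l0 <- track_streamline(ph$volume, ctr)$length
  # rotate the whole volume 90 degrees: (x, y, z) -> (z, x, y)
  P <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3)   # new = P %*% old
  rot6 <- function(d6) mat_to_tensor6(P %*% tensor6_to_mat(d6) %*% t(P))
  tens <- ph$volume$tensors
  dm <- dim(tens)[1:3]
  tens_r <- array(0, c(dm, 6))
  mask_r <- array(0L, dm)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    # voxel (i,j,k) maps to (k,i,j) under P
    tens_r[k, i, j, ] <- rot6(tens[i, j, k, ])
    mask_r[k, i, j] <- ph$volume$mask[i, j, k]
  }
  vol_r <- tensor_volume(tens_r, mask_r, ph$volume$voxel_size)
  l1 <- track_streamline(vol_r, as.numeric(P %*% ctr))$length
  expect_equal(l1, l0, tolerance = 1e-6)
})

test_that("tract statistics aggregate lengths, volume and FA correctly", {
  sl <- structure(list(points = rbind(c(0, 0, 0), c(0, 0, 10)), length = 10,
                       mean_fa = 0.3, voxels = rbind(c(1L, 1L, 1L))),
                  class = "streamline")
  vol <- list(voxel_size = c(2, 2, 2))
  ts <- tract_statistics(list(sl), vol)
  expect_equal(ts$fascicle_length, 10)
  expect_equal(ts$fascicle_volume, 8)
  expect_equal(ts$mean_fa, 0.3)
  expect_error(tract_statistics(list(), vol), "empty")
})

test_that("noiseless phantom DWI refits to the generating tensor", {
  ph <- simulate_phantom(phantom_spec(grid_shape = c(6L, 6L, 8L),
                                      fascicle_length_true = 8,
                                      fa_target = 0.3, seed = 3),
                         with_dwi = TRUE)
  idx <- which(ph$volume$mask == 1L, arr.ind = TRUE)[1, ]
  S <- ph$dwi[idx[1], idx[2], idx[3], ]
  Dh <- fit_tensor_lls(S, ph$gradients, ph$b, ph$s0)
  D0 <- tensor6_to_mat(ph$volume$tensors[idx[1], idx[2], idx[3], ])
  expect_lt(max(abs(Dh - D0)) / max(abs(D0)), 1e-8)
})

test_that("phantom NIfTI writing round-trips volume and ground truth", {
  ph <- simulate_phantom(phantom_spec(grid_shape = c(6L, 6L, 8L),
                                      fascicle_length_true = 8, seed = 2))
  prefix <- tempfile("phantom")
  write_phantom_nifti(ph, prefix)
  ph2 <- read_phantom_nifti(prefix)
  expect_equal(ph2$volume$tensors, ph$volume$tensors, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sum(ph2$volume$mask), sum(ph$volume$mask))
  expect_equal(ph2$ground_truth$fa, ph$ground_truth$fa, tolerance = 1e-9)
})
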