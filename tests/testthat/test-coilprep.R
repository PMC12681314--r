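make_small_kspace <- function(n_coils = 4, seed = 20, noise = 0) {
  p <- make_phantom(32, 2, 2, motion = list(amplitude_px = 2, period_frames = 4),
                    seed = seed)
  cm <- make_coil_maps(32, 2, n_coils, seed = seed + 1)
  tr <- radial_trajectory("SMS_GA", 2, n_spokes = 20, points_per_spoke = 64,
                          spokes_per_frame = 10)
  acquire(p, cm, tr, noise_sigma = noise, seed = seed + 2)
}

test_that("PCA coil compression preserves energy and orders components", {
  ks <- make_small_kspace(n_coils = 4)
  # n_virtual = C: orthonormal rotation, Frobenius energy preserved
  full <- compress_coils(ks, 4)
  expect_lt(abs(sum(Mod(full$kspace$data)^2) - sum(Mod(ks$data)^2)) /
              sum(Mod(ks$data)^2), 1e-10)
  # rows of the compression matrix are orthonormal
  MMh <- full$matrix %*% Conj(t(full$matrix))
  expect_lt(max(Mod(MMh - diag(4))), 1e-10)
  # singular values reported non-increasing
  expect_true(all(diff(full$singular_values) <= 1e-8))
  # retained energy is non-decreasing in n_virtual
  energies <- vapply(1:4, function(v) {
    sum(Mod(compress_coils(ks, v)$kspace$data)^2)
  }, numeric(1))
  expect_true(all(diff(energies) >= -1e-8))
  expect_error(compress_coils(ks, 5), class = "radsms_invalid_argument")
})

test_that("a rank-1 coil set compresses into a single virtual channel", {
  ks <- make_small_kspace(n_coils = 4)
  base <- ks$data[, , 1]
  for (c in 1:4) ks$data[, , c] <- base * (c + 0.5i * c)
  comp <- compress_coils(ks, 4)
  e <- comp$singular_values^2
  expect_gte(e[1] / sum(e), 1 - 1e-10)
})

test_that("conjugate-phase demodulation behaves as a unitary phase map", {
  ks <- make_small_kspace()
  # single band: output equals input
  ks1 <- make_small_kspace()
  ks1$schedule <- caipirinha_schedule(1, 20)
  d1 <- motion_averaged_slice_kspace(ks1)
  expect_identical(d1[, , , 1], ks1$data)
  # demodulating then re-modulating returns the input
  d <- motion_averaged_slice_kspace(ks)
  for (i in 1:2) {
    remod <- d[, , , i] * rep(exp(1i * ks$schedule$phases_rad[1:20, i]),
                              each = 64)
    expect_lt(rel_err(remod, ks$data), 1e-12)
  }
  # schedule shorter than the data is rejected
  short <- caipirinha_schedule(2, 5)
  expect_error(motion_averaged_slice_kspace(ks, short),
               class = "radsms_invalid_argument")
})

test_that("slice coil images correlate with the motion-averaged phantom", {
  # single coil with uniform sensitivity: the density-compensated adjoint
  # image should track the (motion-averaged) phantom
  p <- make_phantom(32, 1, 4, motion = list(amplitude_px = 2, period_frames = 4),
                    seed = 30)
  cm <- as_coil_maps(array(1 + 0i, c(32, 32, 1, 1)))
  tr <- radial_trajectory("GA", 1, n_spokes = 60, points_per_spoke = 64,
                          spokes_per_frame = 15)
  y <- acquire(p, cm, tr)
  demod <- motion_averaged_slice_kspace(y)
  imgs <- slice_coil_images(demod, tr, 32)
  expect_equal(dim(imgs), c(32L, 32L, 1L, 1L))
  xbar <- apply(p$slices[[1]], c(1, 2), mean)
  rho <- Mod(sum(Conj(xbar) * imgs[, , 1, 1])) /
    sqrt(sum(Mod(xbar)^2) * sum(Mod(imgs[, , 1, 1])^2))
  expect_gt(rho, 0.95)
  # zero input -> zero images
  demod0 <- demod; demod0[] <- 0i
  expect_equal(max(Mod(slice_coil_images(demod0, tr, 32))), 0)
})

test_that("calibration extraction takes the centered 24x24 Cartesian block", {
  imgs <- array(0i, c(64, 64, 2, 1))
  imgs[, , 1, 1] <- 1 + 0i  # constant image: energy concentrated at DC
  imgs[, , 2, 1] <- rand_cx(64, 64)
  calib <- extract_calibration(imgs, 24)
  expect_equal(dim(calib), c(24L, 24L, 2L, 1L))
  e <- Mod(calib[, , 1, 1])^2
  expect_gt(e[13, 13] / sum(e), 0.99)  # DC bin at size/2 + 1
  # Parseval: the block holds exactly the central spectral energy
  spec <- radsms:::cfft2(imgs[, , 2, 1])
  expect_equal(sum(Mod(calib[, , 2, 1])^2), sum(Mod(spec[21:44, 21:44])^2))
  expect_error(extract_calibration(array(0i, c(16, 16, 1, 1)), 24),
               class = "radsms_invalid_argument")
})

test_that("ESPIRiT maps satisfy the operator bound and recover known maps", {
  # Cartesian calibration from known smooth maps: a controlled fixture
  n <- 64; nc <- 4
  cm <- make_coil_maps(n, 1, nc, seed = 5)$maps[, , , 1]
  ph <- make_phantom(n, 1, 2, motion = list(amplitude_px = 0, period_frames = 4),
                     seed = 6)
  m <- ph$slices[[1]][, , 1]
  imgs <- array(0i, c(n, n, nc, 1))
  for (c in seq_len(nc)) imgs[, , c, 1] <- cm[, , c] * m
  calib <- extract_calibration(imgs, 24)
  est <- espirit_maps(calib, n)
  ev <- attr(est, "eigenvalues")
  # leading eigenvalue of the normalised pixelwise operator is <= 1
  expect_lte(max(ev), 1 + 1e-6)
  mask <- Mod(m) > 0.3
  cmp <- map_comparison(est$maps[, , , 1], cm, mask)
  expect_gt(cmp$min_cor, 0.99)
  expect_lt(cmp$err, 0.05)
  # degenerate calibration is an explicit failure
  expect_error(espirit_maps(array(0i, c(24, 24, 2, 1)), n),
               class = "radsms_data_error")
})

test_that("a uniform single coil yields a flat unit-magnitude map", {
  n <- 64
  ph <- make_phantom(n, 1, 2, motion = list(amplitude_px = 0, period_frames = 4),
                     seed = 8)
  m <- ph$slices[[1]][, , 1]
  imgs <- array(m, c(n, n, 1, 1))
  calib <- extract_calibration(imgs, 24)
  est <- espirit_maps(calib, n)
  mask <- Mod(m) > 0.3
  mags <- Mod(est$maps[, , 1, 1])[mask]
  expect_lt(max(abs(mags - 1)), 0.01)
})

test_that("the full sensitivity pipeline recovers ground-truth maps", {
  ds_clean <- fx_dataset_clean()
  sens <- fx_sens_clean()
  ev <- attr(sens$maps, "eigenvalues")
  for (i in 1:3) {
    mask <- support_mask(ds_clean$phantom, i, 0.15)
    # rotate true maps into the virtual-coil basis used by the estimate
    nc <- ds_clean$maps$n_coils
    tm <- matrix(ds_clean$maps$maps[, , , i], ncol = nc) %*%
      t(sens$compression$matrix)
    cmp <- map_comparison(sens$maps$maps[, , , i],
                          array(tm, c(64, 64, nc)), mask)
    expect_gt(cmp$min_cor, 0.99)
    expect_lt(cmp$err, 0.1)
  }
  # compression at n_virtual = C is lossless for downstream use
  ds <- fx_dataset()
  comp <- compress_coils(ds$kspace, dim(ds$kspace$data)[3])
  back <- array(t(Conj(t(comp$matrix)) %*%
                    t(matrix(comp$kspace$data, ncol = dim(ds$kspace$data)[3]))),
                dim = dim(ds$kspace$data))
  expect_lt(rel_err(back, ds$kspace$data), 1e-8)
})
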