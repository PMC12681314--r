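test_that("phantom generation is deterministic and respects its invariants", {
  p1 <- make_phantom(seed = 5)
  p2 <- make_phantom(seed = 5)
  expect_identical(p1$slices, p2$slices)
  # magnitudes in [0, 1]
  for (i in seq_len(p1$n_slices)) {
    expect_gte(min(Mod(p1$slices[[i]])), 0)
    expect_lte(max(Mod(p1$slices[[i]])), 1)
  }
  # per-slice content differs: masked pairwise correlations well below 1
  for (i in 1:3) for (j in seq_len(i - 1)) {
    cc <- video_correlation(p1$slices[[i]], p1$slices[[j]],
                            support_mask(p1, i))
    expect_lt(cc, 0.8)
  }
  # temporal smoothness: frame-to-frame normalised change < 0.2
  for (i in seq_len(p1$n_slices)) {
    v <- p1$slices[[i]]
    for (t in seq_len(dim(v)[3] - 1)) {
      expect_lt(cnorm(v[, , t + 1] - v[, , t]) / cnorm(v[, , t]), 0.2)
    }
  }
})

test_that("zero motion amplitude freezes the phantom", {
  p <- make_phantom(48, 2, 6, motion = list(amplitude_px = 0, period_frames = 5),
                    seed = 2)
  for (i in 1:2) for (t in 2:6) {
    expect_identical(p$slices[[i]][, , t], p$slices[[i]][, , 1])
  }
})

test_that("the moving ellipse traverses twice its amplitude per half period", {
  amp <- 6
  p <- make_phantom(64, 1, 20, motion = list(amplitude_px = amp,
                                             period_frames = 20), seed = 3)
  est <- track_moving_centroid(p$slices[[1]])
  # centroid tracking on generated frames: peak-to-peak x excursion = 2*amp
  expect_lt(abs(diff(range(est[, "x"])) - 2 * amp), 1)
  # and the tracked trajectory matches the analytic ground truth
  tru <- phantom_centroids(p, 1)
  expect_lt(mean(sqrt(rowSums((est - tru)^2))), 1)
})

test_that("synthetic coil maps are positive-RSS, asymmetric and bandlimited", {
  cm <- make_coil_maps(64, 2, 8, seed = 4)
  expect_identical(cm$maps, make_coil_maps(64, 2, 8, seed = 4)$maps)
  rss <- sqrt(apply(Mod(cm$maps[, , , 1])^2, c(1, 2), sum))
  expect_gt(min(rss), 0)
  # two opposite lobes: left/right intensity asymmetry between coil images
  cm2 <- make_coil_maps(64, 1, 2, seed = 4)
  left <- Mod(cm2$maps[1:32, , 1, 1]); right <- Mod(cm2$maps[33:64, , 1, 1])
  left2 <- Mod(cm2$maps[1:32, , 2, 1]); right2 <- Mod(cm2$maps[33:64, , 2, 1])
  expect_gt(mean(right), mean(left))    # coil 1 sits at +x
  expect_gt(mean(left2), mean(right2))  # coil 2 opposite
  # spectral energy outside 1/8 of the grid bandwidth < 1% per map
  n <- 64
  ctr <- n / 2 + 1
  off <- abs(seq_len(n) - ctr)
  out_band <- outer(off, off, pmax) > n / 16  # |k| > 0.5/8 cycles/pixel
  for (c in seq_len(8)) {
    spec <- Mod(radsms:::cfft2(cm$maps[, , c, 1]))^2
    expect_lt(sum(spec[out_band]) / sum(spec), 0.01)
  }
})

test_that("acquisition of a zero phantom is pure complex Gaussian noise", {
  p <- make_phantom(32, 1, 4, motion = list(amplitude_px = 0, period_frames = 4),
                    seed = 1)
  for (i in seq_along(p$slices)) p$slices[[i]][] <- 0i
  cm <- make_coil_maps(32, 1, 2, seed = 1)
  tr <- radial_trajectory("GA", 1, n_spokes = 400, points_per_spoke = 128,
                          spokes_per_frame = 100)
  sigma <- 0.7
  y <- acquire(p, cm, tr, noise_sigma = sigma, seed = 9)
  expect_gte(length(y$data), 1e5)
  v <- stats::var(c(Re(y$data), Im(y$data)))
  expect_lt(abs(v - sigma^2) / sigma^2, 0.05)
  # total complex variance per sample is 2 sigma^2
  expect_lt(abs(mean(Mod(y$data)^2) - 2 * sigma^2) / (2 * sigma^2), 0.05)
})

test_that("single-band acquisition reduces to plain radial simulation", {
  p <- make_phantom(32, 1, 2, motion = list(amplitude_px = 2, period_frames = 4),
                    seed = 6)
  cm <- make_coil_maps(32, 1, 2, seed = 6)
  tr <- radial_trajectory("SMS_GA", 1, n_spokes = 8, points_per_spoke = 64,
                          spokes_per_frame = 4)
  y <- acquire(p, cm, tr, noise_sigma = 0)
  # direct frame-wise NUFFT of S * x, no phase factors
  for (sp in c(1, 5)) {
    f <- (sp - 1) %/% 4 + 1
    co <- trajectory_coords(tr, sp)
    for (c in 1:2) {
      ref <- nufft_forward(cm$maps[, , c, 1] * p$slices[[1]][, , f], co)
      expect_lt(rel_err(y$data[, sp, c], ref), 1e-10)
    }
  }
})

test_that("acquisition is linear in the phantom and deterministic", {
  pa <- make_phantom(32, 2, 2, motion = list(amplitude_px = 2, period_frames = 4),
                     seed = 10)
  pb <- make_phantom(32, 2, 2, motion = list(amplitude_px = 3, period_frames = 5),
                     seed = 11)
  psum <- pa
  for (i in 1:2) psum$slices[[i]] <- pa$slices[[i]] + pb$slices[[i]]
  cm <- make_coil_maps(32, 2, 3, seed = 12)
  tr <- radial_trajectory("SMS_GA", 2, n_spokes = 6, points_per_spoke = 64,
                          spokes_per_frame = 3)
  ya <- acquire(pa, cm, tr)
  yb <- acquire(pb, cm, tr)
  ys <- acquire(psum, cm, tr)
  expect_lt(rel_err(ys$data, ya$data + yb$data), 1e-12)
  # same seed, same noise
  y1 <- acquire(pa, cm, tr, noise_sigma = 0.1, seed = 3)
  y2 <- acquire(pa, cm, tr, noise_sigma = 0.1, seed = 3)
  expect_identical(y1$data, y2$data)
})

test_that("conjugate demodulation over full periods isolates each slice exactly", {
  # repeated-angle trajectory: each angle held for one schedule period so
  # the discrete orthogonality of the phase cycle cancels other slices
  ns <- 3L
  p <- make_phantom(48, ns, 2, motion = list(amplitude_px = 0, period_frames = 4),
                    seed = 7)
  cm <- make_coil_maps(48, ns, 4, seed = 8)
  n_ang <- 6L
  base <- spoke_angles(n_ang, angular_increment("GA", 1))
  tr <- radial_trajectory("SMS_GA", ns, n_spokes = n_ang * ns,
                          points_per_spoke = 32,
                          spokes_per_frame = n_ang * ns,
                          angles_deg = rep(base, each = ns))
  y <- acquire(p, cm, tr, noise_sigma = 0)
  demod <- motion_averaged_slice_kspace(y)
  for (i in seq_len(ns)) {
    avg <- array(0i, dim = c(32, n_ang, 4))
    for (g in seq_len(n_ang)) {
      idx <- ((g - 1) * ns + 1):(g * ns)
      avg[, g, ] <- apply(demod[, idx, , i, drop = FALSE], c(1, 3), mean)
    }
    # single-slice reference acquisition of slice i alone
    p1 <- p; p1$slices <- p$slices[i]; p1$n_slices <- 1L
    cm1 <- cm; cm1$maps <- cm$maps[, , , i, drop = FALSE]; cm1$n_slices <- 1L
    tr1 <- radial_trajectory("SMS_GA", 1, n_spokes = n_ang,
                             points_per_spoke = 32, spokes_per_frame = n_ang,
                             angles_deg = base)
    ref <- acquire(p1, cm1, tr1, noise_sigma = 0)
    expect_lt(rel_err(avg, ref$data), 1e-10)
  }
})

test_that("simulate_dataset assembles a consistent noisy dataset", {
  cfg <- run_config(grid_size = 32L, n_coils = 2L, n_frames = 4L,
                    spokes_per_frame = 5L, points_per_spoke = 64L,
                    noise_rel = 0.05)
  ds <- simulate_dataset(cfg)
  expect_s3_class(ds, "sms_dataset")
  expect_equal(dim(ds$kspace$data), c(64L, 20L, 2L))
  expect_gt(ds$kspace$noise_sigma, 0)
  # determinism end to end
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$kspace$data, ds2$kspace$data)
})
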