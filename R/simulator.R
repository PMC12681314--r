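#' Smooth-edged ellipse indicator on a centered grid
#'
#' Returns values in [0, 1]: ~1 inside, ~0 outside, with a logistic edge of
#' roughly `edge_px` pixels so that subpixel motion is resolvable.
#' @noRd
soft_ellipse <- function(n, cx, cy, a, b, angle_rad = 0, edge_px = 1.2) {
  off <- centered_offsets(n)
  x <- matrix(off, n, n) - cx
  y <- matrix(off, n, n, byrow = TRUE) - cy
  xr <- cos(angle_rad) * x + sin(angle_rad) * y
  yr <- -sin(angle_rad) * x + cos(angle_rad) * y
  d <- sqrt((xr / a)^2 + (yr / b)^2)
  1 / (1 + exp((d - 1) * min(a, b) / edge_px))
}

#' Dynamic digital phantom of the oral cavity
#'
#' A desk-scale stand-in for a moving silicone tongue phantom: each slice
#' holds a static "head" ellipse, a set of static circular markers, and one
#' moving "tongue" ellipse whose centroid translates sinusoidally
#' (protrusion/retraction analogue). Slices are deliberately distinct - the
#' head ellipse is reshaped per slice and carries an oriented sinusoidal
#' texture whose orientation rotates across slices, and markers and motion
#' phase differ - so that leakage between simultaneously excited slices is
#' detectable in reconstructions (images of different slices are mutually
#' decorrelated). The tongue's peak-to-peak excursion exceeds its width, so
#' its centroid is recoverable without bias by background subtraction. Each
#' slice carries a smooth, slice-specific spatial phase so the data are
#' genuinely complex-valued.
#'
#' @param grid_size Image grid size N (>= 32).
#' @param n_slices Number of slices (NSli).
#' @param n_frames Number of frames (>= 2).
#' @param motion List with `amplitude_px` (half peak-to-peak centroid
#'   excursion, pixels) and `period_frames` (frames per motion cycle).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Object of class `dynamic_phantom`: complex arrays
#'   `slices[[i]]` of dimension `N x N x n_frames` with magnitudes in [0, 1],
#'   plus analytic ground-truth tongue centroids per slice (`centroids`,
#'   centered pixel coordinates).
#' @export
make_phantom <- function(grid_size = 64L, n_slices = 3L, n_frames = 40L,
                         motion = list(amplitude_px = 6, period_frames = 20),
                         seed = 1L) {
  assert_scalar_num(grid_size, "grid_size", lower = 32, integerish = TRUE)
  assert_scalar_num(n_slices, "n_slices", lower = 1, integerish = TRUE)
  assert_scalar_num(n_frames, "n_frames", lower = 2, integerish = TRUE)
  amp <- motion$amplitude_px
  period <- motion$period_frames
  assert_scalar_num(amp, "motion$amplitude_px", lower = 0)
  assert_scalar_num(period, "motion$period_frames", lower = 1e-9)
  n <- as.integer(grid_size)

  with_seed(seed, {
    slices <- vector("list", n_slices)
    centroids <- vector("list", n_slices)
    off <- centered_offsets(n)
    xg <- matrix(off, n, n)
    yg <- matrix(off, n, n, byrow = TRUE)
    for (i in seq_len(n_slices)) {
      i0 <- i - 1L
      # static anatomy: reshaped head ellipse with an oriented sinusoidal
      # texture; the texture orientation rotates across slices so slice
      # images are mutually decorrelated (leakage is detectable)
      head_a <- 0.40 * n * (1 - 0.07 * i0)
      head_b <- 0.33 * n * (1 + 0.06 * i0)
      head_rot <- i0 * 50 * pi / 180
      theta <- (15 + 60 * i0) * pi / 180
      texture <- 1 + 0.32 * sin(2 * pi * 4 * (cos(theta) * xg +
                                                sin(theta) * yg) / n)
      head <- 0.68 * soft_ellipse(n, 0, 0, head_a, head_b, head_rot) * texture
      # static markers in the upper half, disjoint from the tongue's path
      static_img <- head
      n_mark <- i0 + 1L
      for (m in seq_len(n_mark)) {
        ang <- (80 + 55 * i0 + 65 * (m - 1)) * pi / 180
        r <- 0.20 * n
        static_img <- pmax(static_img,
                           0.9 * soft_ellipse(n, r * cos(ang), r * sin(ang),
                                              0.045 * n, 0.045 * n))
      }
      # smooth slice-specific spatial phase (low-order polynomial)
      cf <- runif(3, -1, 1)
      phase <- 1.5 * (cf[1] * xg / n + cf[2] * yg / n +
                        cf[3] * (xg^2 + yg^2) / n^2)
      # moving tongue ellipse: sinusoidal protrusion/retraction along x;
      # brightest structure, and narrower than its peak-to-peak excursion
      t_idx <- seq_len(n_frames) - 1
      phase_off <- 2 * pi * i0 / max(1L, n_slices)
      cx_t <- amp * sin(2 * pi * t_idx / period + phase_off)
      cy_t <- rep(-0.22 * n - 0.015 * n * i0, n_frames)
      # dark "mouth cavity" along the tongue's path: high contrast between
      # the mover and its background keeps centroid tracking unbiased
      cavity <- soft_ellipse(n, 0, cy_t[1], amp + 0.06 * n + 4, 0.05 * n + 3,
                             edge_px = 2)
      static_img <- static_img * (1 - 0.78 * cavity)
      vol <- array(0i, dim = c(n, n, n_frames))
      for (t in seq_len(n_frames)) {
        tongue <- soft_ellipse(n, cx_t[t], cy_t[t], 0.06 * n, 0.05 * n,
                               edge_px = 1)
        mag <- pmax(static_img, tongue)
        vol[, , t] <- mag * exp(1i * phase)
      }
      slices[[i]] <- vol
      centroids[[i]] <- cbind(x = cx_t, y = cy_t)
    }
    structure(list(slices = slices, centroids = centroids,
                   grid_size = n, n_slices = as.integer(n_slices),
                   n_frames = as.integer(n_frames),
                   motion = list(amplitude_px = amp, period_frames = period),
                   seed = seed),
              class = "dynamic_phantom")
  })
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  cat(sprintf("<dynamic_phantom> %dx%d, %d slice(s), %d frame(s), amplitude %.1f px / period %.0f frames\n",
              x$grid_size, x$grid_size, x$n_slices, x$n_frames,
              x$motion$amplitude_px, x$motion$period_frames))
  invisible(x)
}

#' Ground-truth centroid trajectory of the moving structure
#'
#' @param phantom A `dynamic_phantom`.
#' @param slice Slice index (1-based).
#' @return `n_frames x 2` matrix of (x, y) centroids in centered pixel
#'   coordinates.
#' @export
phantom_centroids <- function(phantom, slice = 1L) {
  phantom$centroids[[slice]]
}

#' Synthetic smooth coil-sensitivity maps
#'
#' Complex Gaussian lobes centred on a ring around the FOV (a generic
#' surrogate for a receive array), with a small per-coil linear phase and
#' mild per-slice variation. Lobes are evaluated with periodic (wrap-around)
#' distance so the maps are smooth under the DFT's circular topology:
#' spectral content stays well inside 1/8 of the grid bandwidth. The
#' root-sum-of-squares is strictly positive everywhere.
#'
#' @param grid_size Image grid size N.
#' @param n_slices Number of slices.
#' @param n_coils Number of receive channels (>= 2, up to 64).
#' @param seed Integer seed.
#' @return Object of class `coil_maps` wrapping a complex array
#'   `[N, N, n_coils, n_slices]`.
#' @export
make_coil_maps <- function(grid_size = 64L, n_slices = 3L, n_coils = 8L,
                           seed = 1L) {
  assert_scalar_num(grid_size, "grid_size", lower = 8, integerish = TRUE)
  assert_scalar_num(n_coils, "n_coils", lower = 2, integerish = TRUE)
  assert_scalar_num(n_slices, "n_slices", lower = 1, integerish = TRUE)
  n <- as.integer(grid_size)
  with_seed(seed, {
    off <- centered_offsets(n)
    xg <- matrix(off, n, n)
    yg <- matrix(off, n, n, byrow = TRUE)
    maps <- array(0i, dim = c(n, n, n_coils, n_slices))
    pdist2 <- function(g, c0) {
      d <- (g - c0 + n / 2) %% n - n / 2  # periodic (wrap-around) offset
      d^2
    }
    for (c in seq_len(n_coils)) {
      gamma <- 2 * pi * (c - 1) / n_coils
      # integer cycles across the FOV: an exact circular spectral shift,
      # so the linear phase does not leak energy out of band
      gx <- sample(-1:1, 1) / n
      gy <- sample(-1:1, 1) / n
      phi0 <- runif(1, 0, 2 * pi)
      for (i in seq_len(n_slices)) {
        jit <- 0.03 * (i - 1)
        cx <- 0.26 * n * cos(gamma + jit)
        cy <- 0.26 * n * sin(gamma + jit)
        sigma <- 0.28 * n * (1 + 0.05 * (i - 1))
        mag <- exp(-(pdist2(xg, cx) + pdist2(yg, cy)) / (2 * sigma^2))
        maps[, , c, i] <- mag * exp(1i * (2 * pi * (gx * xg + gy * yg) + phi0))
      }
    }
    structure(list(maps = maps, grid_size = n, n_coils = as.integer(n_coils),
                   n_slices = as.integer(n_slices), seed = seed),
              class = "coil_maps")
  })
}

#' Wrap a complex array as a coil-maps object
#'
#' @param maps Complex array `[N, N, coils, slices]` (slice dimension may be
#'   dropped for a single slice).
#' @return Object of class `coil_maps`.
#' @export
as_coil_maps <- function(maps) {
  d <- dim(maps)
  if (length(d) == 3L) {
    dim(maps) <- c(d, 1L)
    d <- dim(maps)
  }
  if (length(d) != 4L || d[1] != d[2]) {
    stop_invalid("`maps` must be [N, N, coils, slices]")
  }
  structure(list(maps = as_complex_array(maps), grid_size = d[1],
                 n_coils = d[3], n_slices = d[4], seed = NA_integer_),
            class = "coil_maps")
}

#' @export
print.coil_maps <- function(x, ...) {
  cat(sprintf("<coil_maps> %dx%d, %d coil(s) x %d slice(s)\n",
              x$grid_size, x$grid_size, x$n_coils, x$n_slices))
  invisible(x)
}

#' Simulate an SMS radial acquisition
#'
#' Runs the encoding model in the generative direction: for excitation n
#' (one spoke), coil c, the sample vector is
#' `y[c,n,.] = sum_i exp(1i * phase[n,i]) * F(S[i,c] * x_i(f(n))) + noise`,
#' where `F` is the NUFFT evaluated at spoke n's coordinates, `phase` is the
#' CAIPIRINHA schedule, `f(n)` is the phantom frame active at time `n * TR`
#' (all spokes of a frame see the same phantom state), and the noise is
#' i.i.d. circular complex Gaussian with per-component standard deviation
#' `noise_sigma`.
#'
#' @param phantom A `dynamic_phantom`.
#' @param maps A `coil_maps` with matching grid and slice count.
#' @param trajectory A `radial_trajectory`; its `n_spokes` must not exceed
#'   `phantom$n_frames * spokes_per_frame`.
#' @param schedule Optional `phase_schedule`; defaults to the CAIPIRINHA
#'   schedule for the trajectory's slice count.
#' @param noise_sigma Per-component noise standard deviation (default 0).
#' @param seed Integer seed for the noise.
#' @return Object of class `mc_kspace`: complex array `data`
#'   `[points, spokes, coils]` plus the trajectory, schedule, and metadata.
#' @export
acquire <- function(phantom, maps, trajectory, schedule = NULL,
                    noise_sigma = 0, seed = NULL) {
  if (!inherits(phantom, "dynamic_phantom")) stop_invalid("`phantom` must be a dynamic_phantom")
  if (!inherits(maps, "coil_maps")) stop_invalid("`maps` must be a coil_maps")
  if (maps$grid_size != phantom$grid_size ||
      maps$n_slices != phantom$n_slices) {
    stop_invalid("phantom (%dpx, %d slices) and maps (%dpx, %d slices) do not match",
                 phantom$grid_size, phantom$n_slices, maps$grid_size, maps$n_slices)
  }
  if (trajectory$n_slices != phantom$n_slices) {
    stop_invalid("trajectory NSli (%d) does not match phantom slices (%d)",
                 trajectory$n_slices, phantom$n_slices)
  }
  assert_scalar_num(noise_sigma, "noise_sigma", lower = 0)
  n_spokes <- trajectory$n_spokes
  spf <- trajectory$spokes_per_frame
  if (n_spokes > phantom$n_frames * spf) {
    stop_invalid("trajectory has %d spokes but the phantom covers only %d x %d excitations",
                 n_spokes, phantom$n_frames, spf)
  }
  if (is.null(schedule)) {
    schedule <- caipirinha_schedule(phantom$n_slices, n_spokes)
  }
  if (schedule$n_excitations < n_spokes) {
    stop_invalid("schedule covers %d excitations but trajectory has %d spokes",
                 schedule$n_excitations, n_spokes)
  }
  n <- phantom$grid_size
  p <- trajectory$points_per_spoke
  n_coils <- maps$n_coils
  n_slices <- phantom$n_slices
  y <- array(0i, dim = c(p, n_spokes, n_coils))
  # phantom frame active for each spoke (frame rate = spokes_per_frame * TR)
  frame_of <- pmin((seq_len(n_spokes) - 1L) %/% spf + 1L, phantom$n_frames)
  for (f in unique(frame_of)) {
    sp <- which(frame_of == f)
    plan <- nufft_plan(trajectory_coords(trajectory, sp), n)
    for (i in seq_len(n_slices)) {
      imgs <- maps$maps[, , , i, drop = FALSE]
      dim(imgs) <- c(n, n, n_coils)
      xi <- phantom$slices[[i]][, , f]
      for (c in seq_len(n_coils)) imgs[, , c] <- imgs[, , c] * xi
      pred <- nufft_forward(imgs, plan)  # [p*length(sp), n_coils]
      ph <- exp(1i * rep(schedule$phases_rad[sp, i], each = p))
      y[, sp, ] <- y[, sp, , drop = FALSE] +
        array(pred * ph, dim = c(p, length(sp), n_coils))
    }
  }
  if (noise_sigma > 0) {
    y <- y + with_seed(seed, {
      array(complex(real = rnorm(length(y), sd = noise_sigma),
                    imaginary = rnorm(length(y), sd = noise_sigma)),
            dim = dim(y))
    })
  }
  structure(list(data = y, trajectory = trajectory, schedule = schedule,
                 n_slices = n_slices, n_coils = n_coils,
                 noise_sigma = noise_sigma),
            class = "mc_kspace")
}

#' Construct a multi-coil k-space object
#'
#' Wraps raw complex samples with their trajectory and CAIPIRINHA schedule.
#' Used by the simulator and for importing externally generated data.
#'
#' @param data Complex array `[points, spokes, coils]`.
#' @param trajectory A `radial_trajectory` with matching spoke/point counts.
#' @param schedule Optional `phase_schedule` (default: CAIPIRINHA schedule
#'   for the trajectory's slice count).
#' @param noise_sigma Per-component noise SD recorded with the data.
#' @return Object of class `mc_kspace`.
#' @export
mc_kspace <- function(data, trajectory, schedule = NULL, noise_sigma = 0) {
  d <- dim(data)
  if (length(d) != 3L) stop_invalid("`data` must be [points, spokes, coils]")
  if (d[1] != trajectory$points_per_spoke || d[2] != trajectory$n_spokes) {
    stop_invalid("data (%d x %d) does not match trajectory (%d points x %d spokes)",
                 d[1], d[2], trajectory$points_per_spoke, trajectory$n_spokes)
  }
  if (is.null(schedule)) {
    schedule <- caipirinha_schedule(trajectory$n_slices, d[2])
  }
  structure(list(data = as_complex_array(data), trajectory = trajectory,
                 schedule = schedule, n_slices = trajectory$n_slices,
                 n_coils = d[3], noise_sigma = noise_sigma),
            class = "mc_kspace")
}

#' @export
print.mc_kspace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mc_kspace> %d point(s) x %d spoke(s) x %d coil(s), %s, NSli=%d, sigma=%.3g\n",
              d[1], d[2], d[3], x$trajectory$scheme, x$n_slices, x$noise_sigma))
  invisible(x)
}

#' Simulate a complete SMS rtMRI dataset
#'
#' Convenience wrapper tying the generator together: phantom, coil maps,
#' trajectory, CAIPIRINHA schedule and noisy multi-coil k-space, with the
#' noise level set relative to the RMS k-space signal magnitude.
#'
#' @param config A [run_config()] list (or overrides merged into it).
#' @return Object of class `sms_dataset` with elements `phantom`, `maps`,
#'   `kspace` and `config`.
#' @export
simulate_dataset <- function(config = run_config()) {
  config <- run_config_validate(config)
  phantom <- make_phantom(config$grid_size, config$n_slices, config$n_frames,
                          motion = list(amplitude_px = config$motion_amplitude_px,
                                        period_frames = config$motion_period_frames),
                          seed = config$seed)
  maps <- make_coil_maps(config$grid_size, config$n_slices, config$n_coils,
                         seed = config$seed + 1L)
  trajectory <- radial_trajectory(config$scheme, config$n_slices,
                                  n_spokes = config$n_frames * config$spokes_per_frame,
                                  points_per_spoke = config$points_per_spoke,
                                  spokes_per_frame = config$spokes_per_frame,
                                  tr_ms = config$tr_ms, fov_mm = config$fov_mm)
  kspace <- acquire(phantom, maps, trajectory, noise_sigma = 0)
  if (config$noise_rel > 0) {
    sigma <- config$noise_rel * sqrt(mean(Mod(kspace$data)^2) / 2)
    kspace$data <- kspace$data + with_seed(config$seed + 2L, {
      array(complex(real = rnorm(length(kspace$data), sd = sigma),
                    imaginary = rnorm(length(kspace$data), sd = sigma)),
            dim = dim(kspace$data))
    })
    kspace$noise_sigma <- sigma
  }
  structure(list(phantom = phantom, maps = maps, kspace = kspace,
                 config = config),
            class = "sms_dataset")
}

#' @export
print.sms_dataset <- function(x, ...) {
  cat("<sms_dataset>\n")
  print(x$phantom); print(x$maps); print(x$kspace)
  invisible(x)
}
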