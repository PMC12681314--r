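#' PCA coil compression to virtual channels
#'
#' Computes the leading left singular vectors of the coil-by-sample data
#' matrix over the entire time series (no mean-centering: MR k-space is
#' DC-dominated) and projects the physical channels onto them. With
#' `n_virtual` equal to the physical coil count the transform is a lossless
#' orthonormal rotation.
#'
#' @param kspace An `mc_kspace`.
#' @param n_virtual Number of virtual channels (<= physical coils).
#' @return List of class `coil_compression`: `kspace` (compressed
#'   `mc_kspace`), `matrix` (`n_virtual x n_coils`, orthonormal rows) and
#'   `singular_values` (all, non-increasing).
#' @export
compress_coils <- function(kspace, n_virtual) {
  if (!inherits(kspace, "mc_kspace")) stop_invalid("`kspace` must be an mc_kspace")
  d <- dim(kspace$data)
  n_coils <- d[3]
  assert_scalar_num(n_virtual, "n_virtual", lower = 1, integerish = TRUE)
  if (n_virtual > n_coils) {
    stop_invalid("n_virtual (%d) exceeds physical coil count (%d)",
                 n_virtual, n_coils)
  }
  X <- t(matrix(kspace$data, d[1] * d[2], n_coils))  # coils x samples
  G <- X %*% Conj(t(X))                              # coils x coils Gram
  eg <- eigen(G, symmetric = TRUE)
  sv <- sqrt(pmax(Re(eg$values), 0))
  U <- eg$vectors[, seq_len(n_virtual), drop = FALSE]
  M <- Conj(t(U))                                    # n_virtual x coils
  Y <- M %*% X
  out <- kspace
  out$data <- array(t(Y), dim = c(d[1], d[2], n_virtual))
  out$n_coils <- as.integer(n_virtual)
  structure(list(kspace = out, matrix = M, singular_values = sv),
            class = "coil_compression")
}

#' Conjugate-phase demodulation to motion-averaged per-slice k-space
#'
#' Multiplying spoke n of the SMS data by the conjugate CAIPIRINHA phase of
#' slice i aligns that slice's contribution across excitations while the
#' other slices keep cycling phases that interfere destructively when the
#' spokes are aggregated - the basis of calibration-less sensitivity
#' estimation. All spokes are retained with their angles for a single
#' time-collapsed adjoint reconstruction per slice.
#'
#' @param kspace An `mc_kspace` (or plain `[points, spokes, coils]` array
#'   with `schedule` supplied).
#' @param schedule Optional `phase_schedule`; defaults to the one attached to
#'   `kspace`. Must cover at least as many excitations as there are spokes.
#' @return Complex array `[points, spokes, coils, n_slices]`.
#' @export
motion_averaged_slice_kspace <- function(kspace, schedule = NULL) {
  if (inherits(kspace, "mc_kspace")) {
    if (is.null(schedule)) schedule <- kspace$schedule
    data <- kspace$data
  } else {
    data <- kspace
    if (is.null(schedule)) stop_invalid("`schedule` is required for raw array input")
  }
  d <- dim(data)
  if (schedule$n_excitations < d[2]) {
    stop_invalid("schedule covers %d excitations but data has %d spokes",
                 schedule$n_excitations, d[2])
  }
  n_slices <- schedule$n_slices
  out <- array(0i, dim = c(d, n_slices))
  for (i in seq_len(n_slices)) {
    demod <- exp(-1i * schedule$phases_rad[seq_len(d[2]), i])
    out[, , , i] <- data * rep(demod, each = d[1])
  }
  out
}

#' Per-slice coil images from motion-averaged k-space
#'
#' Adjoint NUFFT of all spokes with ramp density-compensation weights, per
#' slice and coil. The result is a motion-averaged coil-weighted image of
#' each slice, the input to calibration extraction.
#'
#' @param slice_kspace Array `[points, spokes, coils, n_slices]` from
#'   [motion_averaged_slice_kspace()].
#' @param trajectory The `radial_trajectory` the data was acquired with.
#' @param grid_size Output image grid size.
#' @return Complex array `[grid_size, grid_size, coils, n_slices]`.
#' @export
slice_coil_images <- function(slice_kspace, trajectory, grid_size) {
  d <- dim(slice_kspace)
  if (length(d) != 4L) stop_invalid("`slice_kspace` must be [points, spokes, coils, slices]")
  if (d[1] != trajectory$points_per_spoke || d[2] != trajectory$n_spokes) {
    stop_invalid("slice_kspace (%d x %d) does not match trajectory (%d x %d)",
                 d[1], d[2], trajectory$points_per_spoke, trajectory$n_spokes)
  }
  spokes <- seq_len(d[2])
  plan <- nufft_plan(trajectory_coords(trajectory, spokes), grid_size)
  w <- radial_density_weights(trajectory, spokes = spokes)
  out <- array(0i, dim = c(grid_size, grid_size, d[3], d[4]))
  vals <- matrix(0i, d[1] * d[2], d[3])
  for (i in seq_len(d[4])) {
    vals[] <- slice_kspace[, , , i]
    out[, , , i] <- nufft_adjoint(vals, plan, weights = w)
  }
  out
}

#' Extract the central Cartesian calibration region
#'
#' FFT of each coil image to Cartesian k-space, then the centered
#' `size x size` block (DC bin at block index `size/2 + 1`, matching the
#' package's FFT-shift convention).
#'
#' @param coil_images Array `[N, N, coils, slices]` (or `[N, N, coils]`).
#' @param size Calibration block size (default 24).
#' @return Complex array `[size, size, coils, slices]`.
#' @export
extract_calibration <- function(coil_images, size = 24L) {
  d <- dim(coil_images)
  if (length(d) == 3L) {
    dim(coil_images) <- c(d, 1L)
    d <- dim(coil_images)
  }
  assert_scalar_num(size, "size", lower = 2, integerish = TRUE)
  if (d[1] < size || d[2] < size) {
    stop_invalid("grid (%d x %d) too small for a %d x %d calibration region",
                 d[1], d[2], size, size)
  }
  ctr <- d[1] %/% 2L + 1L
  rows <- (ctr - size %/% 2L):(ctr + size %/% 2L - 1L)
  out <- array(0i, dim = c(size, size, d[3], d[4]))
  for (i in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      spec <- cfft2(coil_images[, , c, i])
      out[, , c, i] <- spec[rows, rows]
    }
  }
  out
}

#' ESPIRiT coil-sensitivity estimation from a calibration region
#'
#' Standard single-map ESPIRiT: build the block-Hankel calibration matrix
#' from sliding `kernel_size` windows, SVD, retain the right-singular vectors
#' with singular value at least `sv_threshold` times the largest, transform
#' the retained kernels to image space, and take the leading eigenvector of
#' the pixelwise operator as the sensitivity. The leading eigenvalue is at
#' most 1 (up to rounding); pixels whose eigenvalue falls below
#' `eig_threshold` are outside the support and zeroed. Per-pixel phase is
#' fixed by rotating so coil 1's component is real and non-negative.
#'
#' @param calibration Array `[size, size, coils, slices]` from
#'   [extract_calibration()].
#' @param grid_size Output map grid size N.
#' @param kernel_size ESPIRiT kernel width (default 6, must be <= block size).
#' @param sv_threshold Relative singular-value cutoff (default 0.01).
#' @param eig_threshold Support eigenvalue cutoff (default 0.85).
#' @return A `coil_maps` object; attribute `eigenvalues` holds the per-pixel
#'   leading eigenvalue maps `[N, N, slices]`.
#' @export
espirit_maps <- function(calibration, grid_size, kernel_size = 6L,
                         sv_threshold = 0.01, eig_threshold = 0.85) {
  d <- dim(calibration)
  if (length(d) == 3L) {
    dim(calibration) <- c(d, 1L)
    d <- dim(calibration)
  }
  assert_scalar_num(kernel_size, "kernel_size", lower = 2, integerish = TRUE)
  if (kernel_size > d[1]) {
    stop_invalid("kernel_size (%d) exceeds calibration block (%d)", kernel_size, d[1])
  }
  if (all(Mod(calibration) == 0)) stop_data("degenerate calibration region (all zeros)")
  nc <- d[3]; ns <- d[4]; ks <- as.integer(kernel_size)
  n <- as.integer(grid_size)
  maps <- array(0i, dim = c(n, n, nc, ns))
  eig <- array(0, dim = c(n, n, ns))
  npos <- d[1] - ks + 1L
  for (s in seq_len(ns)) {
    # block-Hankel calibration matrix: one row per window position
    A <- matrix(0i, npos * npos, ks * ks * nc)
    r <- 0L
    for (p2 in seq_len(npos)) {
      for (p1 in seq_len(npos)) {
        r <- r + 1L
        A[r, ] <- calibration[p1:(p1 + ks - 1L), p2:(p2 + ks - 1L), , s]
      }
    }
    sv <- svd(A, nu = 0)
    keep <- which(sv$d >= sv_threshold * sv$d[1])
    V <- sv$v[, keep, drop = FALSE]  # (ks*ks*nc) x J, orthonormal columns
    J <- length(keep)
    # image-space kernels: flip + conjugate, zero-pad to N, centered FFT / ks
    ctr <- n %/% 2L + 1L
    rows <- (ctr - ks %/% 2L):(ctr + ks %/% 2L - 1L + ks %% 2L)
    kerimg <- array(0i, dim = c(n * n, nc, J))
    pad <- matrix(0i, n, n)
    for (j in seq_len(J)) {
      kern <- array(V[, j], dim = c(ks, ks, nc))
      for (c in seq_len(nc)) {
        pad[] <- 0i
        pad[rows, rows] <- Conj(kern[ks:1, ks:1, c])
        kerimg[, c, j] <- cfft2(pad) / ks
      }
    }
    # pixelwise Gram matrix G(x) = ker(x) ker(x)^H, leading eigenpair
    Gp <- array(0i, dim = c(n * n, nc, nc))
    for (a in seq_len(nc)) {
      for (b in seq_len(a)) {
        v <- rowSums(kerimg[, a, , drop = FALSE] *
                       Conj(kerimg[, b, , drop = FALSE]))
        Gp[, a, b] <- v
        if (a != b) Gp[, b, a] <- Conj(v)
      }
    }
    mp <- matrix(0i, n * n, nc)
    ev <- numeric(n * n)
    for (px in seq_len(n * n)) {
      e <- eigen(matrix(Gp[px, , ], nc, nc), symmetric = TRUE)
      ev[px] <- Re(e$values[1])
      u <- e$vectors[, 1]
      ref <- u[1]
      if (Mod(ref) > 0) u <- u * Conj(ref) / Mod(ref)
      mp[px, ] <- u
    }
    mask <- ev >= eig_threshold
    mp[!mask, ] <- 0i
    maps[, , , s] <- array(mp, dim = c(n, n, nc))
    eig[, , s] <- matrix(ev, n, n)
  }
  out <- structure(list(maps = maps, grid_size = n, n_coils = nc,
                        n_slices = ns, seed = NA_integer_),
                   class = "coil_maps")
  attr(out, "eigenvalues") <- eig
  out
}

#' Gridding modulation transfer of a sampled radial trajectory
#'
#' The Cartesian spectrum of a density-compensated adjoint reconstruction is
#' the object's k-space multiplied (approximately, for smooth objects) by
#' the sampling pattern's modulation transfer `W(k)` - the FFT of the
#' point-spread function of the weighted adjoint. `W` is computed exactly
#' from the trajectory by transforming all-ones samples, and is used to
#' normalise the calibration block before ESPIRiT so that ramp-weighting and
#' coverage fluctuations do not bias the sensitivity estimate.
#'
#' @param trajectory A `radial_trajectory`.
#' @param grid_size Image grid size.
#' @param size Calibration block size (default 24).
#' @return Complex `size x size` matrix `W` (centered at DC).
#' @export
calibration_transfer <- function(trajectory, grid_size, size = 24L) {
  spokes <- seq_len(trajectory$n_spokes)
  plan <- nufft_plan(trajectory_coords(trajectory, spokes), grid_size)
  w <- radial_density_weights(trajectory, spokes = spokes)
  psf <- nufft_adjoint(rep(1 + 0i, length(w)), plan, weights = w)
  Wk <- cfft2(psf)
  ctr <- grid_size %/% 2L + 1L
  rows <- (ctr - size %/% 2L):(ctr + size %/% 2L - 1L)
  Wk[rows, rows]
}

#' Calibration-less sensitivity estimation pipeline
#'
#' Composes the preprocessing chain: PCA coil compression, conjugate-phase
#' demodulation to motion-averaged per-slice k-space, density-compensated
#' adjoint NUFFT, Cartesian calibration extraction, and ESPIRiT.
#'
#' @param kspace An `mc_kspace`.
#' @param grid_size Map grid size.
#' @param n_virtual Virtual channels (default: all physical channels, capped
#'   at 16 as in routine use).
#' @param calib_size Calibration block (default 24).
#' @param kernel_size,sv_threshold,eig_threshold Passed to [espirit_maps()].
#' @return List of class `sensitivity_estimate`: `maps` (`coil_maps` in the
#'   virtual-coil basis), `compression` (the `coil_compression`), and
#'   `kspace` (the compressed data reused by reconstruction).
#' @export
estimate_sensitivities <- function(kspace, grid_size,
                                   n_virtual = min(16L, dim(kspace$data)[3]),
                                   calib_size = 24L, kernel_size = 6L,
                                   sv_threshold = 0.01, eig_threshold = 0.85) {
  comp <- compress_coils(kspace, n_virtual)
  demod <- motion_averaged_slice_kspace(comp$kspace)
  imgs <- slice_coil_images(demod, comp$kspace$trajectory, grid_size)
  calib <- extract_calibration(imgs, calib_size)
  # undo the sampling pattern's modulation of the calibration spectrum
  Wk <- calibration_transfer(comp$kspace$trajectory, grid_size, calib_size)
  ok <- Mod(Wk) > 1e-6 * max(Mod(Wk))
  for (i in seq_len(dim(calib)[4])) {
    for (c in seq_len(dim(calib)[3])) {
      blk <- calib[, , c, i]
      blk[ok] <- blk[ok] / Wk[ok]
      blk[!ok] <- 0i
      calib[, , c, i] <- blk
    }
  }
  maps <- espirit_maps(calib, grid_size, kernel_size, sv_threshold,
                       eig_threshold)
  structure(list(maps = maps, compression = comp, kspace = comp$kspace),
            class = "sensitivity_estimate")
}
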