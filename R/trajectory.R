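#' Golden ratio
#' @noRd
GOLDEN_RATIO <- (1 + sqrt(5)) / 2

#' Angular increment between successive radial spokes
#'
#' For the plain golden-angle (GA) scheme the increment is 180/GR degrees
#' (about 111.25 degrees), independent of the multiband factor. For the SMS
#' golden-angle scheme (SMS-GA) the increment is divided by the number of
#' simultaneously excited slices, 180/(GR * NSli), which distributes the
#' spokes of the CAIPIRINHA phase cycle more evenly over angle and improves
#' the destructive interference between slices.
#'
#' @param scheme `"GA"` or `"SMS_GA"`.
#' @param n_slices Number of simultaneously excited slices (NSli, >= 1).
#' @return Angular increment in degrees.
#' @examples
#' angular_increment("GA", 3)      # 111.2461...
#' angular_increment("SMS_GA", 3)  # 37.0820...
#' @export
angular_increment <- function(scheme = c("SMS_GA", "GA"), n_slices = 1L) {
  scheme <- match.arg(scheme)
  assert_scalar_num(n_slices, "n_slices", lower = 1, integerish = TRUE)
  if (scheme == "GA") 180 / GOLDEN_RATIO else 180 / (GOLDEN_RATIO * n_slices)
}

#' Spoke angles for a radial acquisition
#'
#' The m-th spoke (m starting at 0) lies at `mod(m * increment, 360)` degrees,
#' measured counter-clockwise from the +x axis.
#'
#' @param n_spokes Number of spokes (>= 1).
#' @param increment_deg Angular increment in degrees.
#' @return Numeric vector of angles in `[0, 360)`.
#' @export
spoke_angles <- function(n_spokes, increment_deg) {
  assert_scalar_num(n_spokes, "n_spokes", lower = 1, integerish = TRUE)
  assert_scalar_num(increment_deg, "increment_deg")
  ((seq_len(n_spokes) - 1) * increment_deg) %% 360
}

#' CAIPIRINHA phase-cycling schedule
#'
#' For excitation n (0-based) the inter-slice phase difference is
#' `phi_n = mod(2*pi/NSli * n, 2*pi)`; slice i (0-based) is excited with phase
#' `mod(i * phi_n, 2*pi)`, so slice 0 is always the zero-phase reference. The
#' schedule is periodic in n with period NSli, and over one period the phase
#' factors of distinct slices are discretely orthogonal - the property that
#' makes the simultaneously excited slices separable.
#'
#' @param n_slices Number of slices (>= 1).
#' @param n_excitations Number of excitations (>= 1).
#' @return Object of class `phase_schedule` with matrix `phases_rad`
#'   (`n_excitations` x `n_slices`, values in `[0, 2*pi)`).
#' @export
caipirinha_schedule <- function(n_slices, n_excitations) {
  assert_scalar_num(n_slices, "n_slices", lower = 1, integerish = TRUE)
  assert_scalar_num(n_excitations, "n_excitations", lower = 1, integerish = TRUE)
  n <- seq_len(n_excitations) - 1
  i <- seq_len(n_slices) - 1
  phases <- outer(n, i, function(n, i) (2 * pi * i * n / n_slices) %% (2 * pi))
  structure(list(n_slices = as.integer(n_slices),
                 n_excitations = as.integer(n_excitations),
                 phases_rad = phases),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf("<phase_schedule> %d slice(s), %d excitation(s), period %d\n",
              x$n_slices, x$n_excitations, x$n_slices))
  invisible(x)
}

#' Per-sample k-space coordinates of radial spokes
#'
#' Each spoke is a full diameter through k-space center: samples lie at
#' `k_r * (cos a, sin a)` with `k_r` spanning `[-0.5, +0.5)` cycles/pixel in
#' `points_per_spoke` uniform steps (endpoint-exclusive at +0.5, so an even
#' number of points places one sample exactly at k = 0).
#'
#' @param angles_deg Vector of spoke angles in degrees.
#' @param points_per_spoke Number of readout points per spoke (>= 2).
#' @return Array `[points_per_spoke, 2, n_angles]` of (kx, ky) coordinates in
#'   cycles/pixel.
#' @export
sample_coordinates <- function(angles_deg, points_per_spoke) {
  assert_scalar_num(points_per_spoke, "points_per_spoke", lower = 2,
                    integerish = TRUE)
  if (!is.numeric(angles_deg) || length(angles_deg) < 1L) {
    stop_invalid("`angles_deg` must be a non-empty numeric vector")
  }
  p <- as.integer(points_per_spoke)
  kr <- -0.5 + (seq_len(p) - 1) / p
  a <- angles_deg * pi / 180
  out <- array(0, dim = c(p, 2L, length(a)))
  for (m in seq_along(a)) {
    out[, 1L, m] <- kr * cos(a[m])
    out[, 2L, m] <- kr * sin(a[m])
  }
  out
}

#' Radial trajectory for a full acquisition
#'
#' Bundles the sampling scheme, spoke angles, readout geometry and frame
#' binning of one acquisition. Angles follow the scheme's golden-angle
#' increment unless `angles_deg` is supplied explicitly (used e.g. for
#' repeated-angle separability experiments).
#'
#' @param scheme `"SMS_GA"` or `"GA"`.
#' @param n_slices Multiband factor NSli.
#' @param n_spokes Total number of spokes (one excitation each).
#' @param points_per_spoke Readout points per spoke (default 128).
#' @param spokes_per_frame Retrospective binning factor (default 25).
#' @param tr_ms Repetition time in milliseconds (default 2.5).
#' @param fov_mm Field of view in millimetres (default 280).
#' @param angles_deg Optional explicit spoke angles overriding the scheme.
#' @return Object of class `radial_trajectory`.
#' @export
radial_trajectory <- function(scheme = c("SMS_GA", "GA"), n_slices = 3L,
                              n_spokes = 1000L, points_per_spoke = 128L,
                              spokes_per_frame = 25L, tr_ms = 2.5,
                              fov_mm = 280, angles_deg = NULL) {
  scheme <- match.arg(scheme)
  assert_scalar_num(n_spokes, "n_spokes", lower = 1, integerish = TRUE)
  assert_scalar_num(spokes_per_frame, "spokes_per_frame", lower = 1,
                    integerish = TRUE)
  assert_scalar_num(tr_ms, "tr_ms", lower = 1e-9)
  increment <- angular_increment(scheme, n_slices)
  if (is.null(angles_deg)) {
    angles_deg <- spoke_angles(n_spokes, increment)
  } else if (length(angles_deg) != n_spokes) {
    stop_invalid("`angles_deg` must have length n_spokes (%d)", n_spokes)
  }
  structure(list(scheme = scheme,
                 n_slices = as.integer(n_slices),
                 n_spokes = as.integer(n_spokes),
                 points_per_spoke = as.integer(points_per_spoke),
                 angles_deg = angles_deg,
                 increment_deg = increment,
                 spokes_per_frame = as.integer(spokes_per_frame),
                 tr_ms = tr_ms,
                 fov_mm = fov_mm),
            class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  bins <- bin_spokes(x$n_spokes, x$spokes_per_frame)
  cat(sprintf(
    "<radial_trajectory> %s, NSli=%d, %d spokes x %d points, %d/frame (%d frames, %.1f ms/frame)\n",
    x$scheme, x$n_slices, x$n_spokes, x$points_per_spoke, x$spokes_per_frame,
    bins$n_frames, frame_duration(x$spokes_per_frame, x$tr_ms)))
  invisible(x)
}

#' Stacked sample coordinates for a set of spokes
#'
#' @param trajectory A `radial_trajectory`.
#' @param spokes Integer vector of spoke indices (1-based); default all.
#' @return Matrix `[points_per_spoke * length(spokes), 2]`, points varying
#'   fastest within each spoke.
#' @export
trajectory_coords <- function(trajectory, spokes = NULL) {
  if (is.null(spokes)) spokes <- seq_len(trajectory$n_spokes)
  co <- sample_coordinates(trajectory$angles_deg[spokes],
                           trajectory$points_per_spoke)
  matrix(aperm(co, c(1L, 3L, 2L)), ncol = 2L)
}

#' Retrospective binning of spokes into frames
#'
#' Spoke m (0-based) maps to frame `floor(m / spokes_per_frame)`; trailing
#' spokes beyond the last complete frame are discarded so every frame has the
#' same duration.
#'
#' @param n_spokes Total number of spokes.
#' @param spokes_per_frame Spokes per reconstructed frame (>= 1).
#' @return List with `n_frames`, `frame_index` (1-based frame per spoke, `NA`
#'   for discarded spokes) and `n_discarded`.
#' @export
bin_spokes <- function(n_spokes, spokes_per_frame) {
  assert_scalar_num(n_spokes, "n_spokes", lower = 1, integerish = TRUE)
  assert_scalar_num(spokes_per_frame, "spokes_per_frame", lower = 1,
                    integerish = TRUE)
  n_frames <- n_spokes %/% spokes_per_frame
  idx <- (seq_len(n_spokes) - 1L) %/% as.integer(spokes_per_frame) + 1L
  idx[idx > n_frames] <- NA_integer_
  list(n_frames = as.integer(n_frames),
       frame_index = idx,
       n_discarded = as.integer(n_spokes - n_frames * spokes_per_frame))
}

#' Duration of one reconstructed frame
#'
#' @param spokes_per_frame Spokes per frame.
#' @param tr_ms Repetition time in milliseconds.
#' @return Frame duration in milliseconds (`spokes_per_frame * tr_ms`).
#' @examples
#' frame_duration(25, 2.5)  # 62.5 ms
#' @export
frame_duration <- function(spokes_per_frame, tr_ms) {
  assert_scalar_num(spokes_per_frame, "spokes_per_frame", lower = 1e-9)
  assert_scalar_num(tr_ms, "tr_ms", lower = 1e-9)
  spokes_per_frame * tr_ms
}

#' In-plane pixel size
#'
#' @param fov_mm Field of view in millimetres.
#' @param n_pixels Number of pixels across the FOV (readout points per spoke).
#' @return Pixel size in millimetres.
#' @examples
#' pixel_size_mm(280, 128)  # 2.1875 mm, ~2.2 mm
#' @export
pixel_size_mm <- function(fov_mm = 280, n_pixels = 128) {
  assert_scalar_num(fov_mm, "fov_mm", lower = 1e-9)
  assert_scalar_num(n_pixels, "n_pixels", lower = 1, integerish = TRUE)
  fov_mm / n_pixels
}
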