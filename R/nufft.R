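#' Kaiser-Bessel kernel parameters for a requested accuracy
#'
#' Width grows with the number of requested accurate digits; beta follows
#' Beatty's formula for 2x oversampling.
#' @noRd
nufft_params <- function(tol = 1e-6) {
  assert_scalar_num(tol, "tol", lower = 1e-15)
  osf <- 2L
  width <- as.integer(max(3, min(16, ceiling(-log10(tol)) + 2)))
  beta <- pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
  list(osf = osf, width = width, beta = beta)
}

check_coords <- function(coords) {
  if (is.null(dim(coords)) || ncol(coords) != 2L) {
    stop_invalid("`coords` must be a K x 2 matrix of (kx, ky) in cycles/pixel")
  }
  r <- sqrt(coords[, 1L]^2 + coords[, 2L]^2)
  if (any(!is.finite(r)) || max(r) > 0.5 * sqrt(2) * (1 + 1e-9)) {
    stop_invalid("k-space coordinates out of bounds: max |k| must be <= 0.5*sqrt(2) cycles/pixel")
  }
  storage.mode(coords) <- "double"
  coords
}

#' Precomputed NUFFT interpolation plan
#'
#' Computes the Kaiser-Bessel interpolation indices and weights for a fixed
#' set of sample coordinates and grid size, so that repeated transforms (as
#' in iterative reconstruction) pay only for the FFT and a table-driven
#' gather/scatter.
#'
#' @param coords `K x 2` matrix of k-space coordinates in cycles/pixel.
#' @param grid_size Image grid size `N`.
#' @param tol Requested relative accuracy (default `1e-6`).
#' @return Object of class `nufft_plan`, accepted by [nufft_forward()] and
#'   [nufft_adjoint()] in place of raw coordinates.
#' @export
nufft_plan <- function(coords, grid_size, tol = 1e-6) {
  coords <- check_coords(coords)
  assert_scalar_num(grid_size, "grid_size", lower = 8, integerish = TRUE)
  p <- nufft_params(tol)
  tab <- cpp_nufft_plan(coords, as.integer(grid_size), p$osf, p$width, p$beta)
  structure(list(coords = coords, grid_size = as.integer(grid_size),
                 n_samples = nrow(coords), params = p, tab = tab),
            class = "nufft_plan")
}

#' @export
print.nufft_plan <- function(x, ...) {
  cat(sprintf("<nufft_plan> %d samples -> %dx%d grid (width %d, 2x oversampled)\n",
              x$n_samples, x$grid_size, x$grid_size, x$params$width))
  invisible(x)
}

as_plan <- function(coords, grid_size, tol) {
  if (inherits(coords, "nufft_plan")) {
    if (!is.null(grid_size) && coords$grid_size != grid_size) {
      stop_invalid("plan grid size (%d) does not match requested grid size (%d)",
                   coords$grid_size, grid_size)
    }
    coords
  } else {
    nufft_plan(coords, grid_size, tol)
  }
}

#' Forward NUFFT (image grid to non-uniform k-space samples)
#'
#' Evaluates `s(k) = sum_r x(r) exp(-2i*pi*k.r)` with `r` integer pixel
#' offsets centred on the grid midpoint (index `N/2`, zero-based) and `k` in
#' cycles/pixel, via Kaiser-Bessel interpolation on a 2x oversampled FFT grid.
#' Accuracy relative to the direct sum is controlled by `tol`. No `1/N^2`
#' normalisation is applied (nor in the adjoint); scaling is handled
#' explicitly by callers where needed.
#'
#' @param image Complex `N x N` matrix, or `N x N x M` array to transform
#'   several images at the shared sample locations.
#' @param coords `K x 2` matrix of sample coordinates in cycles/pixel, or a
#'   [nufft_plan()].
#' @param tol Requested relative accuracy (default `1e-6`; ignored when a
#'   plan is supplied).
#' @return Complex vector of length `K` (or `K x M` matrix for array input).
#' @export
nufft_forward <- function(image, coords, tol = 1e-6) {
  was_matrix <- is.matrix(image)
  if (was_matrix) dim(image) <- c(dim(image), 1L)
  if (length(dim(image)) != 3L || dim(image)[1L] != dim(image)[2L]) {
    stop_invalid("`image` must be a square N x N matrix or N x N x M array")
  }
  plan <- as_plan(coords, dim(image)[1L], tol)
  if (plan$grid_size != dim(image)[1L]) {
    stop_invalid("plan grid size (%d) does not match image size (%d)",
                 plan$grid_size, dim(image)[1L])
  }
  image <- as_complex_array(image)
  p <- plan$params
  out <- cpp_nufft_forward(image, plan$tab$i1, plan$tab$i2, plan$tab$w1,
                           plan$tab$w2, p$osf, p$width, p$beta)
  if (was_matrix) as.vector(out) else out
}

#' Adjoint NUFFT (non-uniform samples to image grid)
#'
#' Exact adjoint of [nufft_forward()] under the standard inner product:
#' `x(r) = sum_k w_k y_k exp(+2i*pi*k.r)`. With unit weights the dot-product
#' identity `<Fx, y> = <x, F^H y>` holds to near machine precision. Optional
#' non-negative per-sample `weights` (density compensation) turn the adjoint
#' into an approximate inverse for display and calibration purposes.
#'
#' @param values Complex vector of length `K`, or `K x M` matrix.
#' @param coords `K x 2` matrix of sample coordinates in cycles/pixel, or a
#'   [nufft_plan()].
#' @param grid_size Output grid size `N` (may be omitted with a plan).
#' @param weights Optional non-negative vector of length `K`.
#' @param tol Requested relative accuracy (default `1e-6`).
#' @return Complex `N x N` matrix (or `N x N x M` array for matrix input).
#' @export
nufft_adjoint <- function(values, coords, grid_size = NULL, weights = NULL,
                          tol = 1e-6) {
  if (!inherits(coords, "nufft_plan")) {
    assert_scalar_num(grid_size, "grid_size", lower = 8, integerish = TRUE)
  }
  plan <- as_plan(coords, grid_size, tol)
  was_vector <- is.null(dim(values))
  if (was_vector) dim(values) <- c(length(values), 1L)
  if (nrow(values) != plan$n_samples) {
    stop_invalid("`values` and `coords` must have matching lengths (%d vs %d)",
                 nrow(values), plan$n_samples)
  }
  if (is.null(weights)) {
    weights <- numeric(0)
  } else {
    if (length(weights) != plan$n_samples) {
      stop_invalid("`weights` must have one entry per sample (%d vs %d)",
                   length(weights), plan$n_samples)
    }
    if (any(weights < 0)) stop_invalid("`weights` must be non-negative")
    storage.mode(weights) <- "double"
  }
  values <- as_complex_array(values)
  p <- plan$params
  out <- cpp_nufft_adjoint(values, plan$tab$i1, plan$tab$i2, plan$tab$w1,
                           plan$tab$w2, plan$grid_size, p$osf, p$width,
                           p$beta, weights)
  if (was_vector) out[, , 1L] else out
}

#' Density-compensation weights for radial sampling
#'
#' Radial spokes oversample the k-space centre; the classic ramp filter
#' re-weights each sample proportionally to its radius `|k_r|`, with the DC
#' sample assigned half the first ring's weight. Weights are normalised to
#' sum to the number of samples, so the ramp profile does not depend on the
#' number of spokes. The ramp alone leaves a low-frequency reconstruction
#' bias of several percent, so by default it is refined by a few Pipe-Menon
#' fixed-point iterations (`w <- w / |F F^H w|`), which drive the weighted
#' point-spread function towards a delta; set `pipe_iterations = 0` for the
#' plain ramp.
#'
#' @param trajectory A `radial_trajectory`.
#' @param frame Frame index whose spokes are weighted (default 1). Use
#'   `spokes` to weight an arbitrary spoke set instead.
#' @param spokes Optional explicit spoke indices overriding `frame`.
#' @param pipe_iterations Pipe-Menon refinement iterations (default 10).
#' @param grid_size Grid used by the refinement (default
#'   `points_per_spoke / 2`, the natural image grid of a full-diameter
#'   readout).
#' @return Numeric weight vector, one entry per sample (points varying
#'   fastest), matching [trajectory_coords()] ordering.
#' @export
radial_density_weights <- function(trajectory, frame = 1L, spokes = NULL,
                                   pipe_iterations = 10L, grid_size = NULL) {
  if (is.null(spokes)) {
    bins <- bin_spokes(trajectory$n_spokes, trajectory$spokes_per_frame)
    spokes <- which(!is.na(bins$frame_index) & bins$frame_index == frame)
  }
  if (length(spokes) < 1L) {
    stop_invalid("frame %s has no spokes", format(frame))
  }
  assert_scalar_num(pipe_iterations, "pipe_iterations", lower = 0,
                    integerish = TRUE)
  p <- trajectory$points_per_spoke
  kr <- abs(-0.5 + (seq_len(p) - 1) / p)
  kr[kr == 0] <- 0.5 / p  # DC sample: half the first ring's weight
  w <- rep(kr, times = length(spokes))
  w <- w * length(w) / sum(w)
  if (pipe_iterations > 0) {
    if (is.null(grid_size)) grid_size <- max(8L, p %/% 2L)
    plan <- nufft_plan(trajectory_coords(trajectory, spokes), grid_size)
    for (it in seq_len(pipe_iterations)) {
      s <- Mod(nufft_forward(nufft_adjoint(complex(real = w), plan), plan))
      w <- w / pmax(s, 1e-12 * max(s))
      w <- w * length(w) / sum(w)
    }
  }
  w
}
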