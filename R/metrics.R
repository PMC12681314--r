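get_video <- function(video, slice = NULL) {
  if (inherits(video, "sms_recon")) video <- video$x
  d <- dim(video)
  if (length(d) == 4L) {
    if (is.null(slice)) {
      if (d[3] == 1L) slice <- 1L
      else stop_invalid("4-D input: specify `slice`")
    }
    video <- video[, , slice, ]
  }
  video
}

#' Temporal signal-to-noise ratio map
#'
#' Per-pixel temporal mean of the magnitude divided by the temporal standard
#' deviation (sample SD, denominator `T - 1`). Pixels with zero temporal SD
#' are flagged invalid (`NA`).
#'
#' @param video Complex array `[N, N, frames]` (or `sms_recon` / 4-D array
#'   with `slice`).
#' @param slice Slice index for 4-D input.
#' @return Matrix of class `tsnr_map` with `NA` at invalid pixels.
#' @export
tsnr <- function(video, slice = NULL) {
  v <- Mod(get_video(video, slice))
  d <- dim(v)
  if (length(d) != 3L || d[3] < 2L) {
    stop_invalid("tSNR needs a video with at least 2 frames")
  }
  nt <- d[3]
  m <- matrix(v, ncol = nt)
  mu <- rowMeans(m)
  ss <- rowSums((m - mu)^2)
  sdv <- sqrt(ss / (nt - 1))
  out <- mu / sdv
  out[sdv == 0] <- NA_real_
  structure(matrix(out, d[1], d[2]), class = "tsnr_map")
}

#' @export
print.tsnr_map <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<tsnr_map> %dx%d, median %.1f (%d invalid pixel(s))\n",
              nrow(v), ncol(v), median(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Root-mean-square error between two images or videos
#'
#' `sqrt(mean(|a - b|^2))` over all elements; magnitude difference for
#' complex input of mixed phase conventions is obtained by passing `Mod(a)`,
#' `Mod(b)`.
#'
#' @param a,b Arrays of identical shape.
#' @return Non-negative scalar.
#' @export
rmse <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop_invalid("`a` and `b` must have identical shapes")
  }
  sqrt(mean(Mod(a - b)^2))
}

#' Zero-mean ROI signal trace and its RMS
#'
#' Per-frame mean magnitude over a region of interest, centered to zero
#' temporal mean; the RMS of the centered trace quantifies frame-to-frame
#' intensity variation (e.g. residual CAIPIRINHA interference).
#'
#' @param video Complex array `[N, N, frames]` (or `sms_recon` / 4-D with
#'   `slice`).
#' @param roi_mask Logical `N x N` matrix, at least one `TRUE`.
#' @param slice Slice index for 4-D input.
#' @return List with `trace` (zero-mean, length `frames`) and `rms`.
#' @export
roi_trace <- function(video, roi_mask, slice = NULL) {
  v <- Mod(get_video(video, slice))
  d <- dim(v)
  if (!is.logical(roi_mask) || !identical(dim(roi_mask), d[1:2])) {
    stop_invalid("`roi_mask` must be a logical %d x %d matrix", d[1], d[2])
  }
  if (!any(roi_mask)) stop_invalid("`roi_mask` is empty")
  m <- matrix(v, ncol = d[3])
  tr <- colMeans(m[as.vector(roi_mask), , drop = FALSE])
  tr <- tr - mean(tr)
  list(trace = tr, rms = sqrt(mean(tr^2)))
}

#' Space-time (x-t) profile
#'
#' Magnitude along a fixed pixel line, stacked over frames - the standard
#' visualization of articulator or bolus motion.
#'
#' @param video Complex array `[N, N, frames]` (or `sms_recon` / 4-D with
#'   `slice`).
#' @param line List with `orientation` (`"row"` or `"col"`) and `index`
#'   (1-based pixel index of the line).
#' @param slice Slice index for 4-D input.
#' @return Matrix `[line length, frames]`.
#' @export
xt_profile <- function(video, line = list(orientation = "row", index = NULL),
                       slice = NULL) {
  v <- Mod(get_video(video, slice))
  d <- dim(v)
  orientation <- match.arg(line$orientation, c("row", "col"))
  idx <- line$index
  if (is.null(idx)) idx <- d[1] %/% 2L + 1L
  lim <- if (orientation == "row") d[2] else d[1]
  if (idx < 1L || idx > lim) {
    stop_invalid("line index %d outside the image (1..%d)", idx, lim)
  }
  if (orientation == "row") v[, idx, ] else v[idx, , ]
}

#' Track the centroid of the moving structure in a video
#'
#' Subtracts the per-pixel temporal median (static background: the mover
#' occupies any given pixel less than half the time when its excursion
#' exceeds its width) and computes the intensity-weighted centroid of the
#' remaining moving component per frame, in centered pixel coordinates -
#' comparable directly with [phantom_centroids()].
#'
#' @param video Complex array `[N, N, frames]` (or `sms_recon` / 4-D with
#'   `slice`).
#' @param slice Slice index for 4-D input.
#' @param threshold Fraction of the per-frame peak below which moving-signal
#'   pixels are ignored (default 0.3).
#' @return `frames x 2` matrix of (x, y) centroids (centered pixel units).
#' @export
track_moving_centroid <- function(video, slice = NULL, threshold = 0.3) {
  v <- Mod(get_video(video, slice))
  d <- dim(v)
  base <- apply(v, c(1, 2), median)
  off <- centered_offsets(d[1])
  xg <- matrix(off, d[1], d[2])
  yg <- matrix(centered_offsets(d[2]), d[1], d[2], byrow = TRUE)
  out <- matrix(NA_real_, d[3], 2L, dimnames = list(NULL, c("x", "y")))
  for (t in seq_len(d[3])) {
    mov <- pmax(v[, , t] - base, 0)
    mov[mov < threshold * max(mov)] <- 0
    s <- sum(mov)
    if (s > 0) out[t, ] <- c(sum(mov * xg), sum(mov * yg)) / s
  }
  out
}

#' Masked correlation between the magnitudes of two videos
#'
#' Pearson correlation of `|a|` and `|b|` over the pixels of `mask` (all
#' frames pooled). Used for ground-truth recovery and slice-leakage checks.
#'
#' @param a,b Complex arrays `[N, N, frames]`.
#' @param mask Optional logical `N x N` matrix; default all pixels.
#' @return Correlation coefficient.
#' @export
video_correlation <- function(a, b, mask = NULL) {
  a <- Mod(a); b <- Mod(b)
  if (!identical(dim(a), dim(b))) stop_invalid("shapes differ")
  if (!is.null(mask)) {
    keep <- as.vector(mask)
    a <- matrix(a, ncol = dim(a)[3])[keep, , drop = FALSE]
    b <- matrix(b, ncol = dim(b)[3])[keep, , drop = FALSE]
  }
  stats::cor(as.vector(a), as.vector(b))
}
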