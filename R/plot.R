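show_image <- function(m, main = "", zlim = NULL) {
  m <- Mod(m)
  if (is.null(zlim)) zlim <- range(m)
  if (diff(zlim) == 0) zlim <- zlim + c(0, 1e-12)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::gray.colors(256, 0, 1), zlim = zlim,
                  asp = 1, axes = FALSE, xlab = "", ylab = "", main = main,
                  useRaster = TRUE)
}

#' @export
plot.sms_recon <- function(x, frame = 1L, slices = NULL, ...) {
  d <- dim(x$x)
  if (is.null(slices)) slices <- seq_len(d[3])
  op <- graphics::par(mfrow = c(1, length(slices)), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  for (i in slices) {
    show_image(x$x[, , i, frame], main = sprintf("slice %d / frame %d", i, frame))
  }
  invisible(x)
}

#' @export
plot.dynamic_phantom <- function(x, frame = 1L, ...) {
  op <- graphics::par(mfrow = c(1, x$n_slices), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  for (i in seq_len(x$n_slices)) {
    show_image(x$slices[[i]][, , frame], main = sprintf("slice %d", i))
  }
  invisible(x)
}

#' @export
plot.coil_maps <- function(x, slice = 1L, ...) {
  nc <- x$n_coils
  op <- graphics::par(mfrow = c(ceiling(nc / 4), min(nc, 4)),
                      mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  for (c in seq_len(nc)) {
    show_image(x$maps[, , c, slice], main = sprintf("coil %d", c))
  }
  invisible(x)
}

#' @export
plot.tsnr_map <- function(x, ...) {
  show_image(unclass(x), main = "tSNR")
  invisible(x)
}

#' Plot an x-t profile
#'
#' @param profile Matrix from [xt_profile()] (space x time).
#' @param ... Passed to [graphics::image()].
#' @export
plot_xt <- function(profile, ...) {
  graphics::image(seq_len(ncol(profile)), seq_len(nrow(profile)), t(profile),
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "frame", ylab = "position (px)", useRaster = TRUE, ...)
  invisible(profile)
}
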