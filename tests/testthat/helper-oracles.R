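# Brute-force discrete Fourier oracles, independent of the gridding path.
# O(N^2 K) direct sums; only usable on tiny grids.

dft_forward <- function(img, coords) {
  n <- nrow(img)
  r <- seq_len(n) - 1 - n %/% 2
  out <- complex(length.out = nrow(coords))
  for (k in seq_len(nrow(coords))) {
    ph <- exp(-2i * pi * outer(r * coords[k, 1], r * coords[k, 2], "+"))
    out[k] <- sum(img * ph)
  }
  out
}

dft_adjoint <- function(vals, coords, n, weights = NULL) {
  r <- seq_len(n) - 1 - n %/% 2
  if (is.null(weights)) weights <- rep(1, length(vals))
  out <- matrix(0i, n, n)
  for (k in seq_along(vals)) {
    ph <- exp(+2i * pi * outer(r * coords[k, 1], r * coords[k, 2], "+"))
    out <- out + weights[k] * vals[k] * ph
  }
  out
}

rel_err <- function(got, ref) {
  sqrt(sum(Mod(got - ref)^2)) / sqrt(sum(Mod(ref)^2))
}

rand_cx <- function(...) {
  d <- c(...)
  array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), dim = d)
}

# masked, per-pixel phase-aligned comparison of sensitivity maps; both sets
# are referenced to their first coil's phase and normalised per pixel
map_comparison <- function(est_maps, true_maps, mask) {
  nc <- dim(true_maps)[3]
  tm <- matrix(true_maps, ncol = nc)
  em <- matrix(est_maps, ncol = nc)
  refT <- tm[, 1]; refE <- em[, 1]
  tm <- tm * Conj(refT) / pmax(Mod(refT), 1e-12)
  em <- em * Conj(refE) / pmax(Mod(refE), 1e-12)
  tm <- tm / pmax(sqrt(rowSums(Mod(tm)^2)), 1e-12)
  keep <- as.vector(mask)
  err <- sqrt(sum(Mod(em[keep, ] - tm[keep, ])^2) / sum(Mod(tm[keep, ])^2))
  cors <- vapply(seq_len(nc), function(c) {
    a <- c(Re(tm[keep, c]), Im(tm[keep, c]))
    b <- c(Re(em[keep, c]), Im(em[keep, c]))
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  list(err = err, min_cor = min(cors))
}

support_mask <- function(phantom, slice, level = 0.1) {
  apply(Mod(phantom$slices[[slice]]), c(1, 2), mean) > level
}

# random complex image bandlimited to the k-space disc radial spokes cover
disc_bandlimited_image <- function(n, n_modes) {
  kk <- matrix(runif(6 * n_modes, -0.45, 0.45), ncol = 2)
  kk <- kk[sqrt(rowSums(kk^2)) <= 0.42, , drop = FALSE][seq_len(n_modes), ]
  x <- nufft_adjoint(as.vector(rand_cx(n_modes)), kk, n)
  x / sqrt(mean(Mod(x)^2))
}
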