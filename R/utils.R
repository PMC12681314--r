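#' @noRd
stop_invalid <- function(...) {
  stop(errorCondition(sprintf(...),
                      class = c("radsms_invalid_argument", "radsms_config_error")))
}

#' @noRd
stop_config <- function(...) {
  stop(errorCondition(sprintf(...), class = "radsms_config_error"))
}

#' @noRd
stop_data <- function(...) {
  stop(errorCondition(sprintf(...), class = "radsms_data_error"))
}

assert_scalar_num <- function(x, name, lower = -Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (x < lower) stop_invalid("`%s` must be >= %g (got %g)", name, lower, x)
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_invalid("`%s` must be an integer (got %g)", name, x)
  }
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generation inside the
#' package does not disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Centered pixel offsets for an N-point grid
#'
#' Zero-based index i maps to offset i - N/2, so the grid midpoint (index
#' N/2, 1-based N/2 + 1) is offset 0. This is the convention shared by the
#' NUFFT operators, the FFT shift helpers and the phantom geometry.
#' @noRd
centered_offsets <- function(n) seq_len(n) - 1L - n %/% 2L

#' @noRd
fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((n1 %/% 2L + 1L):n1, 1L:(n1 %/% 2L)), c((n2 %/% 2L + 1L):n2, 1L:(n2 %/% 2L))]
}

#' @noRd
ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  h1 <- n1 - n1 %/% 2L; h2 <- n2 - n2 %/% 2L
  x[c((h1 + 1L):n1, 1L:h1), c((h2 + 1L):n2, 1L:h2)]
}

#' Centered 2-D DFT (DC at index N/2 + 1), unnormalised
#' @noRd
cfft2 <- function(x) fftshift2(stats::fft(ifftshift2(x)))

#' Centered 2-D inverse DFT, normalised by 1/N^2
#' @noRd
cifft2 <- function(x) fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / length(x)

#' Frobenius norm of a complex array
#' @noRd
cnorm <- function(x) sqrt(sum(Mod(x)^2))

#' Real inner product <a, b> = Re(sum(conj(a) * b))
#' @noRd
cdot <- function(a, b) sum(Conj(a) * b)

#' @noRd
as_complex_array <- function(x) {
  if (!is.complex(x)) {
    storage.mode(x) <- "double"
    x <- x + 0i
  }
  x
}
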