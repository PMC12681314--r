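#' Solver configuration for the ADMM reconstruction
#'
#' ADMM internals with residual-balancing penalty adaptation. `rho_init` is
#' the initial penalty; when the primal/dual residual ratio exceeds
#' `residual_balance_mu`, the penalty is multiplied or divided by
#' `residual_balance_tau` (and the scaled dual variable rescaled
#' accordingly). `tolerance` stops the outer loop on the relative primal
#' residual.
#'
#' @param max_iterations Outer ADMM iterations (default 50).
#' @param inner_cg_iterations Conjugate-gradient iterations per x-update
#'   (default 10).
#' @param rho_init Initial penalty parameter (default 0.1).
#' @param residual_balance_mu Residual-ratio trigger (default 10).
#' @param residual_balance_tau Penalty rescale factor (default 2).
#' @param tolerance Relative primal-residual stopping tolerance (default 1e-5).
#' @param seed Optional seed (reserved; the solver itself is deterministic).
#' @return List of class `recon_config`.
#' @export
recon_config <- function(max_iterations = 50L, inner_cg_iterations = 10L,
                         rho_init = 0.1, residual_balance_mu = 10,
                         residual_balance_tau = 2, tolerance = 1e-5,
                         seed = NULL) {
  assert_scalar_num(max_iterations, "max_iterations", lower = 1, integerish = TRUE)
  assert_scalar_num(inner_cg_iterations, "inner_cg_iterations", lower = 1,
                    integerish = TRUE)
  assert_scalar_num(rho_init, "rho_init", lower = 1e-12)
  assert_scalar_num(residual_balance_mu, "residual_balance_mu", lower = 1)
  assert_scalar_num(residual_balance_tau, "residual_balance_tau", lower = 1)
  assert_scalar_num(tolerance, "tolerance", lower = 0)
  if (tolerance >= 1) stop_invalid("`tolerance` must be < 1")
  structure(list(max_iterations = as.integer(max_iterations),
                 inner_cg_iterations = as.integer(inner_cg_iterations),
                 rho_init = rho_init,
                 residual_balance_mu = residual_balance_mu,
                 residual_balance_tau = residual_balance_tau,
                 tolerance = tolerance, seed = seed),
            class = "recon_config")
}

#' Frame-wise SMS reconstruction problem
#'
#' Bins the spokes of an acquisition into frames, attaches per-frame NUFFT
#' plans, CAIPIRINHA phases per spoke, and the coil-sensitivity maps, and
#' fixes the regularization weight. This is the container both solvers
#' operate on; the encoding operator is [sms_forward()] / [sms_adjoint()].
#'
#' @param kspace An `mc_kspace` (typically coil-compressed).
#' @param maps A `coil_maps` whose coil count matches the data.
#' @param lambda Temporal finite-difference regularization weight (>= 0,
#'   default 0.04 on the normalized data scale).
#' @param spokes_per_frame Binning factor; defaults to the trajectory's.
#' @param tol NUFFT accuracy (default 1e-6).
#' @return Object of class `recon_problem`.
#' @export
recon_problem <- function(kspace, maps, lambda = 0.04,
                          spokes_per_frame = NULL, tol = 1e-6) {
  if (!inherits(kspace, "mc_kspace")) stop_invalid("`kspace` must be an mc_kspace")
  if (!inherits(maps, "coil_maps")) stop_invalid("`maps` must be a coil_maps")
  assert_scalar_num(lambda, "lambda", lower = 0)
  traj <- kspace$trajectory
  if (is.null(spokes_per_frame)) spokes_per_frame <- traj$spokes_per_frame
  d <- dim(kspace$data)
  if (d[3] != maps$n_coils) {
    stop_invalid("data has %d coils but maps have %d", d[3], maps$n_coils)
  }
  if (kspace$n_slices != maps$n_slices) {
    stop_invalid("data has %d slices but maps have %d",
                 kspace$n_slices, maps$n_slices)
  }
  bins <- bin_spokes(d[2], spokes_per_frame)
  if (bins$n_frames < 1L) {
    stop_data("not enough spokes (%d) for a single frame of %d",
              d[2], spokes_per_frame)
  }
  n <- maps$grid_size
  p <- d[1]; nc <- d[3]; ns <- maps$n_slices
  nf <- bins$n_frames
  y <- array(0i, dim = c(p, spokes_per_frame, nc, nf))
  plans <- vector("list", nf)
  phases <- vector("list", nf)
  for (f in seq_len(nf)) {
    sp <- which(!is.na(bins$frame_index) & bins$frame_index == f)
    y[, , , f] <- kspace$data[, sp, ]
    plans[[f]] <- nufft_plan(trajectory_coords(traj, sp), n, tol)
    ph <- kspace$schedule$phases_rad[sp, , drop = FALSE]
    phases[[f]] <- exp(1i * ph[rep(seq_along(sp), each = p), , drop = FALSE])
  }
  mapsflat <- maps$maps
  dim(mapsflat) <- c(n, n, nc * ns)
  structure(list(y = y, plans = plans, phases = phases,
                 maps = maps$maps, mapsflat = mapsflat,
                 conj_mapsflat = Conj(mapsflat),
                 grid_size = n, n_points = p, n_coils = nc, n_slices = ns,
                 n_frames = nf, spokes_per_frame = as.integer(spokes_per_frame),
                 lambda = lambda, trajectory = traj),
            class = "recon_problem")
}

#' @export
print.recon_problem <- function(x, ...) {
  cat(sprintf("<recon_problem> %d frame(s) x %d spoke(s) x %d coil(s), NSli=%d, N=%d, lambda=%g\n",
              x$n_frames, x$spokes_per_frame, x$n_coils, x$n_slices,
              x$grid_size, x$lambda))
  invisible(x)
}

frame_forward <- function(x_f, problem, f) {
  # x_f: [N, N, n_slices] -> [K, n_coils]
  nc <- problem$n_coils; ns <- problem$n_slices; n <- problem$grid_size
  dim(x_f) <- c(n, n, ns)
  xrep <- x_f[, , rep(seq_len(ns), each = nc), drop = FALSE]
  pred <- nufft_forward(problem$mapsflat * xrep, problem$plans[[f]])
  K <- nrow(pred)
  ph <- problem$phases[[f]]
  yf <- matrix(0i, K, nc)
  for (i in seq_len(ns)) {
    cols <- (i - 1L) * nc + seq_len(nc)
    yf <- yf + pred[, cols, drop = FALSE] * ph[, i]
  }
  yf
}

frame_adjoint <- function(y_f, problem, f) {
  # y_f: [K, n_coils] -> [N, N, n_slices]
  nc <- problem$n_coils; ns <- problem$n_slices; n <- problem$grid_size
  ph <- problem$phases[[f]]
  K <- nrow(y_f)
  inmat <- matrix(0i, K, nc * ns)
  for (i in seq_len(ns)) {
    inmat[, (i - 1L) * nc + seq_len(nc)] <- y_f * Conj(ph[, i])
  }
  adj <- nufft_adjoint(inmat, problem$plans[[f]])
  prod <- problem$conj_mapsflat * adj
  dim(prod) <- c(n * n, nc * ns)
  out <- array(0i, dim = c(n, n, ns))
  for (i in seq_len(ns)) {
    cols <- (i - 1L) * nc + seq_len(nc)
    out[, , i] <- rowSums(prod[, cols, drop = FALSE])
  }
  out
}

#' Frame-wise SMS encoding operator
#'
#' Predicted k-space for a slice-video set: per frame t, coil c and spoke n,
#' `yhat = sum_i exp(1i*phase[n,i]) * F(S[i,c] * x_i[t])` evaluated at spoke
#' n's coordinates.
#'
#' @param x Complex array `[N, N, n_slices, n_frames]`.
#' @param problem A `recon_problem`.
#' @return Complex array `[points, spokes_per_frame, coils, frames]`.
#' @export
sms_forward <- function(x, problem) {
  d <- dim(x)
  if (length(d) != 4L || d[1] != problem$grid_size || d[3] != problem$n_slices ||
      d[4] != problem$n_frames) {
    stop_invalid("`x` must be [%d, %d, %d, %d]", problem$grid_size,
                 problem$grid_size, problem$n_slices, problem$n_frames)
  }
  x <- as_complex_array(x)
  out <- array(0i, dim = dim(problem$y))
  for (f in seq_len(problem$n_frames)) {
    xf <- x[, , , f, drop = FALSE]
    dim(xf) <- dim(x)[1:3]
    out[, , , f] <- frame_forward(xf, problem, f)
  }
  out
}

#' Adjoint of the SMS encoding operator
#'
#' Conjugate phase, adjoint NUFFT, conjugate maps, sum over coils - the
#' exact adjoint of [sms_forward()], used by both solvers.
#'
#' @param kspace Complex array `[points, spokes_per_frame, coils, frames]`.
#' @param problem A `recon_problem`.
#' @return Complex array `[N, N, n_slices, n_frames]`.
#' @export
sms_adjoint <- function(kspace, problem) {
  d <- dim(kspace)
  if (!identical(d, dim(problem$y))) {
    stop_invalid("`kspace` must match the problem's data dimensions")
  }
  kspace <- as_complex_array(kspace)
  n <- problem$grid_size
  out <- array(0i, dim = c(n, n, problem$n_slices, problem$n_frames))
  K <- problem$n_points * problem$spokes_per_frame
  for (f in seq_len(problem$n_frames)) {
    yf <- kspace[, , , f]
    dim(yf) <- c(K, problem$n_coils)
    out[, , , f] <- frame_adjoint(yf, problem, f)
  }
  out
}

#' Temporal finite differences (and adjoint)
#'
#' Forward difference along the last (time) dimension, no wrap-around:
#' `d[t] = x[t+1] - x[t]`. The adjoint is the negative divergence with
#' Neumann ends. A single-frame input yields a zero-length difference (the
#' regularization term is then inert).
#'
#' @param x Complex array (3-D or 4-D) whose last dimension is time.
#' @return Array with the time dimension shortened by one.
#' @export
temporal_diff <- function(x) {
  d <- dim(x)
  nd <- length(d)
  if (nd != 3L && nd != 4L) stop_invalid("`x` must be a 3-D or 4-D array")
  nt <- d[nd]
  if (nt < 2L) return(array(0i, dim = c(d[-nd], 0L)))
  # flatten leading dims; difference along time
  m <- matrix(x, ncol = nt)
  out <- m[, 2:nt, drop = FALSE] - m[, 1:(nt - 1L), drop = FALSE]
  array(out, dim = c(d[-nd], nt - 1L))
}

#' @rdname temporal_diff
#' @param d Array of temporal differences (last dimension `T - 1`).
#' @param n_frames Number of frames `T` of the adjoint's output.
#' @export
temporal_diff_adjoint <- function(d, n_frames) {
  dd <- dim(d)
  nd <- length(dd)
  nt1 <- dd[nd]
  out_dim <- c(dd[-nd], n_frames)
  if (nt1 == 0L) return(array(0i, dim = out_dim))
  m <- matrix(d, ncol = nt1)
  out <- matrix(0i, nrow(m), n_frames)
  # adjoint of forward difference: out[1] = -d[1]; out[t] = d[t-1] - d[t];
  # out[T] = d[T-1]
  out[, 1L] <- -m[, 1L]
  if (nt1 >= 2L) {
    out[, 2:nt1] <- m[, 1:(nt1 - 1L), drop = FALSE] - m[, 2:nt1, drop = FALSE]
  }
  out[, n_frames] <- m[, nt1]
  array(out, dim = out_dim)
}

#' Complex soft-thresholding (magnitude shrinkage)
#'
#' Proximal operator of `tau * ||.||_1` for complex values:
#' `z * max(|z| - tau, 0) / |z|` (0 where `z = 0`).
#'
#' @param z Complex array.
#' @param tau Non-negative threshold.
#' @return Array of the same shape.
#' @export
soft_threshold <- function(z, tau) {
  assert_scalar_num(tau, "tau", lower = 0)
  mag <- Mod(z)
  sc <- ifelse(mag > 0, pmax(mag - tau, 0) / mag, 0)
  z * sc
}

#' Spectral norm of the per-frame normal operator
#'
#' Power iteration on `A^H A` restricted to one frame (all frames share the
#' spoke count, so their norms agree to within the angle-dependent sampling
#' fluctuation). Used to normalise the encoding operator so that the
#' regularization weight acts on an O(1) image scale.
#'
#' @param problem A `recon_problem`.
#' @param frame Frame whose operator is probed (default 1).
#' @param n_iter Power iterations (default 12).
#' @return Estimate of the largest eigenvalue of `A^H A`.
#' @export
operator_norm <- function(problem, frame = 1L, n_iter = 12L) {
  n <- problem$grid_size
  ns <- problem$n_slices
  v <- with_seed(1L, array(complex(real = rnorm(n * n * ns),
                                   imaginary = rnorm(n * n * ns)),
                           dim = c(n, n, ns)))
  v <- v / cnorm(v)
  lam <- 0
  for (it in seq_len(n_iter)) {
    w <- frame_adjoint(frame_forward(v, problem, frame), problem, frame)
    lam <- cnorm(w)
    if (lam == 0) return(0)
    v <- w / lam
  }
  lam
}

normal_op <- function(x, problem, rho = 0) {
  out <- sms_adjoint(sms_forward(x, problem), problem)
  if (rho > 0 && problem$n_frames > 1L) {
    out <- out + rho * temporal_diff_adjoint(temporal_diff(x), problem$n_frames)
  }
  out
}

cg_solve <- function(rhs, x0, apply_op, n_iter, tol = 1e-10) {
  x <- x0
  r <- rhs - apply_op(x)
  p <- r
  rs <- Re(cdot(r, r))
  rhs_norm <- cnorm(rhs)
  resid <- numeric(0)
  for (it in seq_len(n_iter)) {
    resid <- c(resid, sqrt(rs))
    if (sqrt(rs) <= tol * max(rhs_norm, 1e-300)) break
    Ap <- apply_op(p)
    pAp <- Re(cdot(p, Ap))
    if (pAp <= 0) break
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- Re(cdot(r, r))
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = x, resid = c(resid, cnorm(rhs - apply_op(x))))
}

#' ADMM compressed-sensing SMS reconstruction
#'
#' Approximately minimizes
#' `0.5 * sum_i ||phi_i F S_i x_i - y||_2^2 + lambda * ||T x||_1`
#' by variable splitting `z = Tx`: the x-update solves the regularized
#' normal equations by inner conjugate gradient, the z-update is complex
#' soft-thresholding with threshold `lambda/rho`, and the penalty `rho` is
#' adapted by residual balancing. Data are normalized so the zero-filled
#' adjoint has unit maximum magnitude (making `lambda` transferable across
#' fixtures); the scaling is undone on output.
#'
#' @param problem A `recon_problem` (carries `lambda`).
#' @param config A [recon_config()].
#' @return Object of class `sms_recon`: complex array `x`
#'   `[N, N, n_slices, n_frames]`, a per-iteration `trace` data frame
#'   (objective, primal/dual residuals, rho), and a `converged` flag (with a
#'   warning if the tolerance was not reached).
#' @export
admm_reconstruct <- function(problem, config = recon_config()) {
  if (!inherits(problem, "recon_problem")) stop_invalid("`problem` must be a recon_problem")
  if (!inherits(config, "recon_config")) stop_invalid("`config` must be a recon_config")
  lambda <- problem$lambda
  nf <- problem$n_frames
  Aty <- sms_adjoint(problem$y, problem)
  M0 <- max(Mod(Aty))
  L <- operator_norm(problem)
  if (M0 == 0 || L == 0) {
    return(structure(list(x = Aty * 0, trace = NULL, converged = TRUE,
                          lambda = lambda, scale = 0, config = config),
                     class = "sms_recon"))
  }
  # normalise the encoding operator to unit spectral norm and the data so
  # the zero-filled adjoint has unit max magnitude: the solution is O(1)
  # and lambda is transferable across fixtures
  m_out <- M0 / L
  Atyn <- Aty / M0  # = (A/sqrt(L))^H (y / (sqrt(L) m_out))
  x <- array(0i, dim = dim(Aty))
  z <- temporal_diff(x)
  u <- z
  rho <- config$rho_init
  trace <- vector("list", config$max_iterations)
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    rhs <- Atyn
    if (nf > 1L) rhs <- rhs + rho * temporal_diff_adjoint(z - u, nf)
    apply_op <- function(v) {
      out <- sms_adjoint(sms_forward(v, problem), problem) / L
      if (rho > 0 && nf > 1L) {
        out <- out + rho * temporal_diff_adjoint(temporal_diff(v), nf)
      }
      out
    }
    sol <- cg_solve(rhs, x, apply_op, config$inner_cg_iterations)
    x <- sol$x
    Tx <- temporal_diff(x)
    z_old <- z
    z <- soft_threshold(Tx + u, lambda / rho)
    u <- u + Tx - z
    r_norm <- cnorm(Tx - z)
    s_norm <- rho * cnorm(temporal_diff_adjoint(z - z_old, nf))
    resid <- (sms_forward(x, problem) - problem$y / m_out) / sqrt(L)
    obj <- 0.5 * sum(Mod(resid)^2) + lambda * sum(Mod(Tx))
    trace[[it]] <- data.frame(iteration = it, objective = obj,
                              primal = r_norm, dual = s_norm, rho = rho)
    primal_rel <- r_norm / max(cnorm(Tx), cnorm(z), 1e-12)
    dual_rel <- s_norm / max(rho * cnorm(temporal_diff_adjoint(u, nf)), 1e-12)
    if (nf > 1L && primal_rel < config$tolerance &&
        dual_rel < config$tolerance) {
      converged <- TRUE
      break
    }
    if (nf == 1L) {  # no splitting variable: plain regularized LS, one solve
      converged <- TRUE
      break
    }
    if (r_norm > config$residual_balance_mu * s_norm) {
      rho <- rho * config$residual_balance_tau
      u <- u / config$residual_balance_tau
    } else if (s_norm > config$residual_balance_mu * r_norm) {
      rho <- rho / config$residual_balance_tau
      u <- u * config$residual_balance_tau
    }
  }
  if (!converged) {
    warning("ADMM did not reach the requested tolerance within max_iterations; returning best iterate",
            call. = FALSE)
  }
  structure(list(x = x * m_out, trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
                 converged = converged, lambda = lambda, scale = m_out,
                 config = config),
            class = "sms_recon")
}

#' CG-SENSE baseline reconstruction
#'
#' Frame-independent conjugate gradient on the normal equations of the data
#' term only (no regularization; `lambda` in the problem is ignored). The
#' historical baseline runs 15 iterations.
#'
#' @param problem A `recon_problem`.
#' @param n_iterations CG iterations per frame (default 15).
#' @return Object of class `sms_recon`; `trace` holds per-frame residual
#'   norms (`frame`, `iteration`, `residual`).
#' @export
cg_sense <- function(problem, n_iterations = 15L) {
  if (!inherits(problem, "recon_problem")) stop_invalid("`problem` must be a recon_problem")
  assert_scalar_num(n_iterations, "n_iterations", lower = 1, integerish = TRUE)
  n <- problem$grid_size
  ns <- problem$n_slices
  x <- array(0i, dim = c(n, n, ns, problem$n_frames))
  K <- problem$n_points * problem$spokes_per_frame
  traces <- vector("list", problem$n_frames)
  for (f in seq_len(problem$n_frames)) {
    yf <- problem$y[, , , f]
    dim(yf) <- c(K, problem$n_coils)
    rhs <- frame_adjoint(yf, problem, f)
    op <- function(v) frame_adjoint(frame_forward(v, problem, f), problem, f)
    sol <- cg_solve(rhs, array(0i, dim = c(n, n, ns)), op, n_iterations)
    x[, , , f] <- sol$x
    traces[[f]] <- data.frame(frame = f, iteration = seq_along(sol$resid) - 1L,
                              residual = sol$resid)
  }
  structure(list(x = x, trace = do.call(rbind, traces), converged = TRUE,
                 lambda = 0, scale = 1,
                 config = list(n_iterations = as.integer(n_iterations))),
            class = "sms_recon")
}

#' @export
print.sms_recon <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<sms_recon> %dx%d, %d slice(s) x %d frame(s), lambda=%g, converged=%s\n",
              d[1], d[2], d[3], d[4], x$lambda, x$converged))
  invisible(x)
}

med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

filter_mag_video <- function(mag, width) {
  nt <- dim(mag)[3]
  h <- width %/% 2L
  out <- mag
  for (t in seq_len(nt)) {
    win <- max(1L, t - h):min(nt, t + h)
    if (length(win) == 1L) {
      out[, , t] <- mag[, , win]
    } else if (length(win) == 2L) {
      out[, , t] <- (mag[, , win[1]] + mag[, , win[2]]) / 2
    } else if (length(win) == 3L) {
      out[, , t] <- med3(mag[, , win[1]], mag[, , win[2]], mag[, , win[3]])
    } else {
      m <- matrix(mag[, , win], ncol = length(win))
      out[, , t] <- apply(m, 1L, median)
    }
  }
  out
}

#' Temporal median filter
#'
#' Suppresses residual undersampling flicker: the per-pixel magnitude is
#' replaced by the median over an odd-width temporal window (shrunken at the
#' edges); the phase of the centre frame is retained.
#'
#' @param video Complex array `[N, N, frames]` or `[N, N, slices, frames]`,
#'   or an `sms_recon` (filtered in place).
#' @param width Odd window width (default 3; width 1 is the identity).
#' @return Same type as the input.
#' @export
temporal_median_filter <- function(video, width = 3L) {
  assert_scalar_num(width, "width", lower = 1, integerish = TRUE)
  if (width %% 2L == 0L) stop_invalid("`width` must be odd (got %d)", width)
  if (inherits(video, "sms_recon")) {
    video$x <- temporal_median_filter(video$x, width)
    return(video)
  }
  if (width == 1L) return(video)
  d <- dim(video)
  if (length(d) == 4L) {
    for (i in seq_len(d[3])) {
      video[, , i, ] <- temporal_median_filter(video[, , i, ], width)
    }
    return(video)
  }
  if (length(d) != 3L) stop_invalid("`video` must be a 3-D or 4-D array")
  mag <- filter_mag_video(Mod(video), width)
  mag * exp(1i * Arg(video))
}
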