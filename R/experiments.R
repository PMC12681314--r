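log_info <- function(fmt, ...) {
  message(sprintf("[radsms %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Simulate a dataset and write it to a container (CLI: `simulate`)
#'
#' @param config A [run_config()] (or named list of overrides).
#' @param out Output container path.
#' @return The `sms_dataset`, invisibly.
#' @export
cmd_simulate <- function(config = run_config(), out) {
  config <- run_config_validate(config)
  t0 <- Sys.time()
  ds <- simulate_dataset(config)
  save_dataset(ds, out)
  log_info("simulated %s -> %s (%.1f s)",
           paste(dim(ds$kspace$data), collapse = "x"), out,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(ds)
}

prep_problem <- function(ds, config, lambda = NULL, spokes_per_frame = NULL) {
  sens <- estimate_sensitivities(
    ds$kspace, config$grid_size, n_virtual = config$n_virtual,
    kernel_size = config$espirit_kernel,
    sv_threshold = config$espirit_sv_threshold,
    eig_threshold = config$espirit_eig_threshold)
  recon_problem(sens$kspace, sens$maps,
                lambda = if (is.null(lambda)) config$lambda else lambda,
                spokes_per_frame = spokes_per_frame)
}

#' Reconstruct a container's k-space (CLI: `recon`)
#'
#' Runs coil preparation (compression + ESPIRiT), the chosen solver, and the
#' temporal median filter, then stores the result in the container.
#'
#' @param path Container with k-space (from [cmd_simulate()]).
#' @param method `"admm"` (default) or `"cgsense"`.
#' @param overrides Named list of config overrides (only the named fields
#'   change; the difference is logged).
#' @return The filtered `sms_recon`, invisibly.
#' @export
cmd_reconstruct <- function(path, method = c("admm", "cgsense"),
                            overrides = list()) {
  method <- match.arg(method)
  ds <- load_dataset(path)
  config <- ds$config
  if (length(overrides)) {
    for (nm in names(overrides)) {
      log_info("override: %s = %s -> %s", nm, format(config[[nm]]),
               format(overrides[[nm]]))
    }
    config <- run_config_validate(do.call(
      run_config, modifyList(as.list(unclass(config)), overrides)))
  }
  t0 <- Sys.time()
  sens <- estimate_sensitivities(
    ds$kspace, config$grid_size, n_virtual = config$n_virtual,
    kernel_size = config$espirit_kernel,
    sv_threshold = config$espirit_sv_threshold,
    eig_threshold = config$espirit_eig_threshold)
  log_info("sensitivities estimated (%.1f s)",
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  problem <- recon_problem(sens$kspace, sens$maps, lambda = config$lambda,
                           spokes_per_frame = config$spokes_per_frame)
  t1 <- Sys.time()
  rec <- if (method == "admm") {
    admm_reconstruct(problem, recon_config(
      max_iterations = config$max_iterations,
      inner_cg_iterations = config$inner_cg_iterations,
      rho_init = config$rho_init,
      residual_balance_mu = config$residual_balance_mu,
      residual_balance_tau = config$residual_balance_tau,
      tolerance = config$tolerance))
  } else {
    cg_sense(problem, config$cg_sense_iterations)
  }
  if (!is.null(rec$trace)) {
    log_info("%s: %d iteration(s), %.1f s", method,
             max(rec$trace$iteration),
             as.numeric(difftime(Sys.time(), t1, units = "secs")))
  }
  rec <- temporal_median_filter(rec, config$median_width)
  save_recon(path, rec, maps = sens$maps, method = method)
  invisible(rec)
}

edge_sharpness <- function(img) {
  m <- Mod(img)
  gx <- m[-1, ] - m[-nrow(m), ]
  gy <- m[, -1] - m[, -ncol(m)]
  (mean(abs(gx)) + mean(abs(gy))) / 2
}

recon_quality <- function(rec, ds, spokes_per_frame = NULL) {
  # RMSE against time-matched ground truth plus tSNR / sharpness proxies
  truth <- ds$phantom
  spf0 <- ds$kspace$trajectory$spokes_per_frame
  if (is.null(spokes_per_frame)) spokes_per_frame <- spf0
  nf <- dim(rec$x)[4]
  err <- 0; npx <- 0
  tsnr_mean <- numeric(0)
  sharp <- numeric(0)
  for (i in seq_len(dim(rec$x)[3])) {
    tr_frames <- pmin(((seq_len(nf) - 0.5) * spokes_per_frame) %/% spf0 + 1L,
                      truth$n_frames)
    tv <- truth$slices[[i]][, , tr_frames, drop = FALSE]
    err <- err + sum((Mod(rec$x[, , i, ]) - Mod(tv))^2)
    npx <- npx + length(tv)
    if (nf >= 2L) {
      ts <- tsnr(rec$x[, , i, ])
      tsnr_mean <- c(tsnr_mean, median(unclass(ts), na.rm = TRUE))
    }
    sharp <- c(sharp, edge_sharpness(rec$x[, , i, nf %/% 2L + 1L]))
  }
  list(rmse = sqrt(err / npx),
       tsnr_median = if (length(tsnr_mean)) mean(tsnr_mean) else NA_real_,
       sharpness = mean(sharp))
}

#' Regularization-weight search (CLI: `lambda-search`)
#'
#' Reconstructs the container's data over a grid of lambda values - coarse
#' (`1e-4, 1e-3, 1e-2, 1e-1`, logarithmic) or fine (`0.01` to `0.1` in steps
#' of `0.01`) - and tabulates ground-truth RMSE, median tSNR and an
#' edge-sharpness proxy per value.
#'
#' @param path Container with k-space and ground truth.
#' @param mode `"coarse"` or `"fine"`.
#' @param overrides Named list of config overrides (e.g. smaller iteration
#'   counts for quick searches).
#' @return Data frame with one row per lambda.
#' @export
lambda_grid <- function(mode = c("coarse", "fine")) {
  mode <- match.arg(mode)
  # coarse: logarithmic 1e-4..1e-1; fine: 0.01..0.1 in steps of 0.01
  if (mode == "coarse") 10^seq(-4, -1) else seq(0.01, 0.1, by = 0.01)
}

cmd_lambda_search <- function(path, mode = c("coarse", "fine"),
                              overrides = list()) {
  mode <- match.arg(mode)
  lambdas <- lambda_grid(mode)
  ds <- load_dataset(path)
  config <- ds$config
  if (length(overrides)) {
    config <- run_config_validate(do.call(
      run_config, modifyList(as.list(unclass(config)), overrides)))
  }
  sens <- estimate_sensitivities(
    ds$kspace, config$grid_size, n_virtual = config$n_virtual,
    kernel_size = config$espirit_kernel,
    sv_threshold = config$espirit_sv_threshold,
    eig_threshold = config$espirit_eig_threshold)
  rcfg <- recon_config(max_iterations = config$max_iterations,
                       inner_cg_iterations = config$inner_cg_iterations,
                       rho_init = config$rho_init,
                       residual_balance_mu = config$residual_balance_mu,
                       residual_balance_tau = config$residual_balance_tau,
                       tolerance = config$tolerance)
  rows <- lapply(lambdas, function(lam) {
    problem <- recon_problem(sens$kspace, sens$maps, lambda = lam,
                             spokes_per_frame = config$spokes_per_frame)
    rec <- temporal_median_filter(admm_reconstruct(problem, rcfg),
                                  config$median_width)
    q <- recon_quality(rec, ds)
    log_info("lambda %.4g: rmse %.4g, tSNR %.3g", lam, q$rmse, q$tsnr_median)
    data.frame(lambda = lam, rmse = q$rmse, tsnr_median = q$tsnr_median,
               sharpness = q$sharpness)
  })
  out <- do.call(rbind, rows)
  save_metric(path, paste0("lambda_search_", mode), out)
  out
}

#' Parameter sweeps (CLI: `sweep`)
#'
#' Re-runs the reconstruction along one axis and tabulates image quality:
#' \describe{
#'   \item{spokes_per_frame}{re-bins the same k-space at each temporal
#'     resolution; RMSE is against time-matched ground truth.}
#'   \item{n_virtual}{varies coil compression; RMSE is against the
#'     reconstruction from all physical channels (the uncompressed
#'     reference).}
#'   \item{n_slices}{re-simulates with the stored config at each multiband
#'     factor.}
#' }
#' Invalid values for the axis are skipped with a logged warning.
#'
#' @param path Container with k-space (+ truth for RMSE).
#' @param axis One of `"spokes_per_frame"`, `"n_virtual"`, `"n_slices"`.
#' @param values Numeric vector of axis values.
#' @param overrides Named list of config overrides.
#' @return Data frame with one row per (valid) value.
#' @export
cmd_sweep <- function(path, axis = c("spokes_per_frame", "n_virtual", "n_slices"),
                      values, overrides = list()) {
  axis <- match.arg(axis)
  ds <- load_dataset(path)
  config <- ds$config
  if (length(overrides)) {
    config <- run_config_validate(do.call(
      run_config, modifyList(as.list(unclass(config)), overrides)))
  }
  rcfg <- recon_config(max_iterations = config$max_iterations,
                       inner_cg_iterations = config$inner_cg_iterations,
                       rho_init = config$rho_init,
                       residual_balance_mu = config$residual_balance_mu,
                       residual_balance_tau = config$residual_balance_tau,
                       tolerance = config$tolerance)
  n_spokes <- dim(ds$kspace$data)[2]
  n_coils <- dim(ds$kspace$data)[3]
  ref_rec <- NULL
  if (axis == "n_virtual") {
    sens <- estimate_sensitivities(ds$kspace, config$grid_size,
                                   n_virtual = n_coils)
    problem <- recon_problem(sens$kspace, sens$maps, lambda = config$lambda,
                             spokes_per_frame = config$spokes_per_frame)
    ref_rec <- temporal_median_filter(admm_reconstruct(problem, rcfg),
                                      config$median_width)
  }
  rows <- list()
  for (v in values) {
    valid <- switch(axis,
      spokes_per_frame = v >= 1 && v <= n_spokes,
      n_virtual = v >= 1 && v <= n_coils,
      n_slices = v >= 1)
    if (!valid || abs(v - round(v)) > 1e-9) {
      warning(sprintf("skipping invalid %s value: %s", axis, format(v)),
              call. = FALSE)
      next
    }
    v <- as.integer(v)
    row <- switch(axis,
      spokes_per_frame = {
        sens <- estimate_sensitivities(ds$kspace, config$grid_size,
                                       n_virtual = config$n_virtual)
        problem <- recon_problem(sens$kspace, sens$maps,
                                 lambda = config$lambda, spokes_per_frame = v)
        rec <- temporal_median_filter(admm_reconstruct(problem, rcfg),
                                      config$median_width)
        q <- recon_quality(rec, ds, spokes_per_frame = v)
        data.frame(value = v, rmse = q$rmse, tsnr_median = q$tsnr_median,
                   frame_ms = frame_duration(v, ds$kspace$trajectory$tr_ms))
      },
      n_virtual = {
        sens <- estimate_sensitivities(ds$kspace, config$grid_size,
                                       n_virtual = v)
        problem <- recon_problem(sens$kspace, sens$maps,
                                 lambda = config$lambda,
                                 spokes_per_frame = config$spokes_per_frame)
        rec <- temporal_median_filter(admm_reconstruct(problem, rcfg),
                                      config$median_width)
        data.frame(value = v,
                   rmse = rmse(Mod(rec$x), Mod(ref_rec$x)),
                   energy_retained = NA_real_)
      },
      n_slices = {
        cfg_v <- run_config_validate(do.call(run_config, modifyList(
          as.list(unclass(config)), list(n_slices = v))))
        ds_v <- simulate_dataset(cfg_v)
        problem <- prep_problem(ds_v, cfg_v)
        rec <- temporal_median_filter(admm_reconstruct(problem, rcfg),
                                      cfg_v$median_width)
        q <- recon_quality(rec, ds_v)
        data.frame(value = v, rmse = q$rmse, tsnr_median = q$tsnr_median)
      })
    log_info("sweep %s = %d done", axis, v)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  save_metric(path, paste0("sweep_", axis), out)
  out
}

#' Compute and store standard metrics for a container (CLI: `metrics`)
#'
#' Per-slice median-filtered tSNR maps and, when ground truth is present,
#' magnitude RMSE per slice. Results land under `metrics/` in the container
#' and (optionally) as a CSV table.
#'
#' @param path Container with a reconstruction.
#' @param csv Optional CSV output path for the summary table.
#' @return Data frame of per-slice summary metrics.
#' @export
cmd_metrics <- function(path, csv = NULL) {
  ds <- load_dataset(path)
  rec <- load_recon(path)
  ns <- dim(rec$x)[3]
  rows <- lapply(seq_len(ns), function(i) {
    ts <- tsnr(rec$x[, , i, ])
    save_metric(path, sprintf("tsnr_slice%d", i - 1L), unclass(ts))
    rm <- NA_real_
    if (!is.null(ds$phantom)) {
      nf <- min(dim(rec$x)[4], ds$phantom$n_frames)
      rm <- rmse(Mod(rec$x[, , i, seq_len(nf)]),
                 Mod(ds$phantom$slices[[i]][, , seq_len(nf)]))
    }
    data.frame(slice = i - 1L, tsnr_median = median(unclass(ts), na.rm = TRUE),
               rmse_vs_truth = rm)
  })
  out <- do.call(rbind, rows)
  save_metric(path, "summary", out)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

#' Export reconstructed frames as PNG images (CLI: `export-video`)
#'
#' Writes one grayscale PNG per frame and slice, magnitudes normalised to
#' the global maximum.
#'
#' @param path Container with a reconstruction.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"frame"`).
#' @return Character vector of files written, invisibly.
#' @export
cmd_export_video <- function(path, out_dir, prefix = "frame") {
  rec <- load_recon(path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(Mod(rec$x))
  if (mx == 0) mx <- 1
  files <- character(0)
  d <- dim(rec$x)
  for (i in seq_len(d[3])) {
    for (t in seq_len(d[4])) {
      img <- t(Mod(rec$x[, , i, t]))[d[2]:1, , drop = FALSE] / mx
      f <- file.path(out_dir, sprintf("%s_s%02d_t%04d.png", prefix, i, t))
      png::writePNG(img, f)
      files <- c(files, f)
    }
  }
  log_info("wrote %d PNG frame(s) to %s", length(files), out_dir)
  invisible(files)
}
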