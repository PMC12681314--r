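#' Default run configuration
#'
#' Collects every tunable of the pipeline with its default. The defaults
#' define the desk-scale study conditions: a 64-pixel grid, 8 coils, 3
#' simultaneously excited slices, 40 frames of 25 spokes at TR 2.5 ms
#' (62.5 ms/frame), SMS-GA sampling, 5% relative complex Gaussian noise and
#' the method's standard regularization weight lambda = 0.04. Readout geometry
#' (128 points/spoke, 280 mm FOV) matches the acquisition protocol the
#' package emulates.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    # geometry / acquisition
    grid_size = 64L, n_slices = 3L, n_coils = 8L, n_frames = 40L,
    scheme = "SMS_GA", spokes_per_frame = 25L, points_per_spoke = 128L,
    tr_ms = 2.5, fov_mm = 280,
    # phantom motion and noise
    motion_amplitude_px = 6, motion_period_frames = 20, noise_rel = 0.05,
    # coil prep (n_virtual NA: resolved to min(16, n_coils))
    n_virtual = NA_integer_, espirit_kernel = 6L, espirit_sv_threshold = 0.01,
    espirit_eig_threshold = 0.85,
    # solver
    lambda = 0.04, max_iterations = 50L, inner_cg_iterations = 10L,
    rho_init = 0.1, residual_balance_mu = 10, residual_balance_tau = 2,
    tolerance = 1e-5, cg_sense_iterations = 15L, median_width = 3L,
    # reproducibility
    seed = 1L)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop_config("unknown config field(s): %s",
                                 paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "run_config")
}

#' @noRd
run_config_validate <- function(config) {
  if (!inherits(config, "run_config")) {
    if (!is.list(config)) stop_config("`config` must be a run_config or named list")
    config <- do.call(run_config, config)
  }
  if (!config$scheme %in% c("GA", "SMS_GA")) {
    stop_config("scheme must be 'GA' or 'SMS_GA' (got '%s')", config$scheme)
  }
  if (is.na(config$n_virtual)) {
    config$n_virtual <- min(16L, as.integer(config$n_coils))
  }
  for (f in c("grid_size", "n_slices", "n_coils", "n_frames",
              "spokes_per_frame", "points_per_spoke", "n_virtual", "seed")) {
    assert_scalar_num(config[[f]], f, lower = 1, integerish = TRUE)
    config[[f]] <- as.integer(config[[f]])
  }
  if (config$n_virtual > config$n_coils) {
    stop_config("n_virtual (%d) cannot exceed n_coils (%d)",
                config$n_virtual, config$n_coils)
  }
  config
}

#' Write a run configuration to a YAML file
#'
#' The file round-trips losslessly through [read_config()]; every run driven
#' by the command-line interface records its fully resolved configuration.
#'
#' @param config A [run_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- run_config_validate(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' Unknown fields are rejected; missing fields take their defaults.
#'
#' @param path YAML file written by [write_config()] (or hand-edited).
#' @return A validated [run_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  run_config_validate(do.call(run_config, vals))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
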