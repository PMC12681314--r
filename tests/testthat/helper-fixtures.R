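# Shared fixtures, built once per test run and cached across test files.
# Sizes are desk-scale: the default study fixture is N=64, C=8, NSli=3,
# 40 frames x 25 spokes; comparison fixtures run at N=48, C=4 to keep the
# suite fast. Solver runs use 12x6 (outer x inner) iterations, at which the
# recovery metrics plateau on these fixtures.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

test_recon_config <- function(...) {
  recon_config(max_iterations = 12L, inner_cg_iterations = 6L, ...)
}

# default study fixture (noisy, moving)
fx_dataset <- function() {
  fixture("dataset", function() simulate_dataset(run_config()))
}

# same conditions without noise (sensitivity-recovery reference)
fx_dataset_clean <- function() {
  fixture("dataset_clean", function() simulate_dataset(run_config(noise_rel = 0)))
}

fx_sens <- function() {
  fixture("sens", function() {
    ds <- fx_dataset()
    estimate_sensitivities(ds$kspace, ds$config$grid_size,
                           n_virtual = ds$config$n_virtual)
  })
}

fx_sens_clean <- function() {
  fixture("sens_clean", function() {
    ds <- fx_dataset_clean()
    estimate_sensitivities(ds$kspace, ds$config$grid_size,
                           n_virtual = ds$config$n_virtual)
  })
}

fx_admm <- function() {
  fixture("admm", function() {
    sens <- fx_sens()
    problem <- recon_problem(sens$kspace, sens$maps, lambda = 0.04)
    rec <- suppressWarnings(admm_reconstruct(problem, test_recon_config()))
    temporal_median_filter(rec)
  })
}

# small comparison fixture config: N=48, C=4, 15 spokes/frame
small_config <- function(...) {
  run_config(grid_size = 48L, n_coils = 4L, n_frames = 40L,
             spokes_per_frame = 15L, points_per_spoke = 96L, ...)
}

# matched GA / SMS-GA pair (same phantom, maps and noise seed)
fx_scheme_pair <- function() {
  fixture("scheme_pair", function() {
    out <- lapply(c("SMS_GA", "GA"), function(sch) {
      ds <- simulate_dataset(small_config(scheme = sch))
      sens <- estimate_sensitivities(ds$kspace, ds$config$grid_size,
                                     n_virtual = ds$config$n_virtual)
      problem <- recon_problem(sens$kspace, sens$maps, lambda = 0.04)
      rec <- suppressWarnings(admm_reconstruct(problem, test_recon_config()))
      list(ds = ds, rec = temporal_median_filter(rec))
    })
    names(out) <- c("SMS_GA", "GA")
    out
  })
}

# static-phantom undersampling sweep: one acquisition, re-binned
fx_spoke_sweep <- function() {
  fixture("spoke_sweep", function() {
    cfg <- small_config(motion_amplitude_px = 0, n_frames = 10L,
                        spokes_per_frame = 95L)
    ds <- simulate_dataset(cfg)  # 950 spokes, static truth
    sens <- estimate_sensitivities(ds$kspace, ds$config$grid_size,
                                   n_virtual = ds$config$n_virtual)
    truth <- ds$phantom$slices[[1]][, , 1]  # static: frame 1 is the truth
    truths <- lapply(seq_len(cfg$n_slices),
                     function(i) ds$phantom$slices[[i]][, , 1])
    rows <- lapply(c(10L, 15L, 20L, 45L, 95L), function(spf) {
      problem <- recon_problem(sens$kspace, sens$maps, lambda = 0.04,
                               spokes_per_frame = spf)
      rec <- temporal_median_filter(suppressWarnings(
        admm_reconstruct(problem, test_recon_config())))
      err <- 0; npx <- 0
      for (i in seq_along(truths)) {
        nf <- dim(rec$x)[4]
        tv <- array(truths[[i]], dim = c(dim(truths[[i]]), nf))
        err <- err + sum((Mod(rec$x[, , i, ]) - Mod(tv))^2)
        npx <- npx + length(tv)
      }
      data.frame(spokes_per_frame = spf, rmse = sqrt(err / npx))
    })
    do.call(rbind, rows)
  })
}
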