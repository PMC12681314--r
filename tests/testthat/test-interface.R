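tiny_config <- function(...) {
  run_config(grid_size = 32L, n_coils = 3L, n_frames = 4L,
             spokes_per_frame = 8L, points_per_spoke = 64L,
             max_iterations = 6L, inner_cg_iterations = 4L, ...)
}

test_that("run configurations round-trip losslessly through YAML", {
  cfg <- tiny_config(lambda = 0.02, noise_rel = 0.03)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(radsms:::run_config_validate(cfg)))
  expect_error(run_config(nonsense_field = 1), class = "radsms_config_error")
  expect_error(read_config("/nonexistent/x.yaml"), class = "radsms_config_error")
})

test_that("dataset containers round-trip and reject unknown schema versions", {
  ds <- simulate_dataset(tiny_config())
  path <- withr::local_tempfile(fileext = ".h5")
  save_dataset(ds, path)
  back <- load_dataset(path)
  expect_equal(back$kspace$data, ds$kspace$data)
  expect_equal(back$kspace$trajectory$angles_deg, ds$kspace$trajectory$angles_deg)
  expect_equal(back$kspace$schedule$phases_rad, ds$kspace$schedule$phases_rad)
  expect_equal(back$phantom$slices, ds$phantom$slices)
  expect_equal(back$maps$maps, ds$maps$maps)
  # corrupt the schema major version
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5deleteAttribute(fid, "/", "schema_version")
  rhdf5::h5writeAttribute("99.0", fid, "schema_version")
  rhdf5::H5Fclose(fid)
  expect_error(load_dataset(path), class = "radsms_data_error")
})

test_that("cmd_simulate writes deterministic containers, any multiband factor", {
  path1 <- withr::local_tempfile(fileext = ".h5")
  path2 <- withr::local_tempfile(fileext = ".h5")
  suppressMessages(cmd_simulate(tiny_config(), path1))
  suppressMessages(cmd_simulate(tiny_config(), path2))
  d1 <- load_dataset(path1); d2 <- load_dataset(path2)
  expect_identical(d1$kspace$data, d2$kspace$data)
  # five-band acquisition is accepted and shaped correctly
  path5 <- withr::local_tempfile(fileext = ".h5")
  ds5 <- suppressMessages(cmd_simulate(tiny_config(n_slices = 5L), path5))
  expect_equal(ds5$phantom$n_slices, 5L)
  expect_equal(dim(ds5$kspace$data), c(64L, 32L, 3L))
  expect_equal(ds5$kspace$schedule$n_slices, 5L)
})

test_that("cmd_reconstruct runs the pipeline and honours overrides", {
  path <- withr::local_tempfile(fileext = ".h5")
  suppressMessages(cmd_simulate(tiny_config(), path))
  rec <- suppressMessages(suppressWarnings(
    cmd_reconstruct(path, "cgsense")))
  expect_s3_class(rec, "sms_recon")
  expect_equal(dim(rec$x), c(32L, 32L, 3L, 4L))
  # default CG-SENSE depth is the historical 15 iterations
  expect_equal(max(rec$trace$iteration), 15L)
  back <- load_recon(path)
  expect_equal(dim(back$x), dim(rec$x))
  # overrides change only the named parameter
  rec2 <- suppressMessages(suppressWarnings(
    cmd_reconstruct(path, "cgsense", overrides = list(cg_sense_iterations = 5L))))
  expect_equal(max(rec2$trace$iteration), 5L)
  # admm path stores a filtered video
  rec3 <- suppressMessages(suppressWarnings(cmd_reconstruct(path, "admm")))
  expect_s3_class(rec3, "sms_recon")
})

test_that("the lambda grids match the two-stage search protocol", {
  path <- withr::local_tempfile(fileext = ".h5")
  suppressMessages(cmd_simulate(tiny_config(n_slices = 1L, n_coils = 2L), path))
  tab <- suppressMessages(suppressWarnings(
    cmd_lambda_search(path, "coarse",
                      overrides = list(max_iterations = 3L,
                                       inner_cg_iterations = 3L))))
  expect_equal(tab$lambda, c(1e-4, 1e-3, 1e-2, 1e-1))
  expect_true(all(is.finite(tab$rmse)))
  # fine grid: 0.01..0.1 in steps of 0.01 (10 values)
  expect_equal(seq(0.01, 0.1, by = 0.01), radsms:::lambda_grid("fine"))
})

test_that("cmd_sweep accepts the standard spoke list and skips bad values", {
  path <- withr::local_tempfile(fileext = ".h5")
  suppressMessages(cmd_simulate(tiny_config(n_frames = 6L), path))
  warns <- character(0)
  tab <- suppressMessages(withCallingHandlers(
    cmd_sweep(path, "spokes_per_frame", c(8L, 16L, 9999L),
              overrides = list(max_iterations = 3L, inner_cg_iterations = 3L)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  expect_true(any(grepl("skipping", warns)))
  expect_equal(tab$value, c(8L, 16L))
  expect_equal(tab$frame_ms, c(frame_duration(8, 2.5), frame_duration(16, 2.5)))
  # n_virtual sweep at full coil count: zero RMSE against the reference
  tab2 <- suppressMessages(suppressWarnings(cmd_sweep(
    path, "n_virtual", 3L,
    overrides = list(max_iterations = 3L, inner_cg_iterations = 3L))))
  expect_lt(tab2$rmse[1], 1e-10)
})

test_that("metrics and PNG export round out the container workflow", {
  path <- withr::local_tempfile(fileext = ".h5")
  suppressMessages(cmd_simulate(tiny_config(), path))
  suppressMessages(suppressWarnings(cmd_reconstruct(path, "cgsense")))
  tab <- suppressMessages(cmd_metrics(path))
  expect_equal(nrow(tab), 3L)
  expect_true(all(is.finite(tab$rmse_vs_truth)))
  dir <- withr::local_tempdir()
  files <- suppressMessages(cmd_export_video(path, dir))
  expect_equal(length(files), 3L * 4L)
  expect_true(all(file.exists(files)))
  img <- png::readPNG(files[1])
  expect_equal(dim(img), c(32L, 32L))
})
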