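CONTAINER_SCHEMA <- "1.0"

ensure_group <- function(path, group) {
  parts <- strsplit(group, "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  cur <- ""
  ls <- rhdf5::h5ls(path)
  existing <- if (nrow(ls)) paste(ls$group, ls$name, sep = "/") else character(0)
  existing <- sub("^//", "/", existing)
  for (p in parts) {
    cur <- paste0(cur, "/", p)
    if (!cur %in% existing) {
      rhdf5::h5createGroup(path, cur)
      existing <- c(existing, cur)
    }
  }
  invisible(cur)
}

h5_write <- function(x, path, name) {
  grp <- dirname(name)
  if (grp != "." && grp != "/") ensure_group(path, grp)
  if (is.complex(x)) {
    # complex data as paired real/imag datasets for portability
    ensure_group(path, name)
    rhdf5::h5write(Re(x), path, paste0(name, "/real"))
    rhdf5::h5write(Im(x), path, paste0(name, "/imag"))
  } else {
    rhdf5::h5write(x, path, name)
  }
}

h5_read_cx <- function(path, name) {
  re <- rhdf5::h5read(path, paste0(name, "/real"))
  im <- rhdf5::h5read(path, paste0(name, "/imag"))
  out <- complex(real = re, imaginary = im)
  dim(out) <- dim(re)
  out
}

h5_exists <- function(path, name) {
  ls <- rhdf5::h5ls(path)
  if (!nrow(ls)) return(FALSE)
  full <- file.path(ls$group, ls$name)
  full <- sub("^//", "/", full)
  sub("^/", "", name) %in% sub("^/", "", full)
}

container_create <- function(path, overwrite = TRUE) {
  if (file.exists(path)) {
    if (!overwrite) stop_data("container already exists: %s", path)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(CONTAINER_SCHEMA, fid, "schema_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Check a container's schema version
#'
#' Containers are versioned `major.minor`; readers reject files whose major
#' version they do not understand.
#'
#' @param path Container file.
#' @return The version string, invisibly.
#' @export
container_check <- function(path) {
  if (!file.exists(path)) stop_data("container not found: %s", path)
  at <- rhdf5::h5readAttributes(path, "/")
  ver <- at$schema_version
  if (is.null(ver)) stop_data("not a radsms container (no schema_version): %s", path)
  major <- strsplit(as.character(ver), ".", fixed = TRUE)[[1]][1]
  ours <- strsplit(CONTAINER_SCHEMA, ".", fixed = TRUE)[[1]][1]
  if (!identical(major, ours)) {
    stop_data("container schema major version %s not supported (reader understands %s.x)",
              major, ours)
  }
  invisible(as.character(ver))
}

#' Write a simulated dataset to an HDF5 container
#'
#' Stores k-space, trajectory, schedule, ground-truth videos, true coil maps
#' and the fully resolved configuration. Complex data are stored as paired
#' real/imag datasets.
#'
#' @param dataset An `sms_dataset` from [simulate_dataset()].
#' @param path Output `.h5` file.
#' @param overwrite Replace an existing file (default TRUE).
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path, overwrite = TRUE) {
  if (!inherits(dataset, "sms_dataset")) stop_invalid("`dataset` must be an sms_dataset")
  container_create(path, overwrite)
  traj <- dataset$kspace$trajectory
  h5_write(yaml::as.yaml(unclass(dataset$config)), path, "config/yaml")
  h5_write(traj$angles_deg, path, "trajectory/angles_deg")
  h5_write(sample_coordinates(traj$angles_deg, traj$points_per_spoke),
           path, "trajectory/coords")
  for (f in c("scheme", "n_slices", "n_spokes", "points_per_spoke",
              "spokes_per_frame", "tr_ms", "fov_mm")) {
    h5_write(traj[[f]], path, paste0("trajectory/", f))
  }
  h5_write(dataset$kspace$schedule$phases_rad, path, "schedule/phases_rad")
  h5_write(dataset$kspace$data, path, "kspace/data")
  h5_write(dataset$kspace$noise_sigma, path, "kspace/noise_sigma")
  for (i in seq_len(dataset$phantom$n_slices)) {
    h5_write(dataset$phantom$slices[[i]], path, sprintf("truth/slice%d", i - 1L))
    h5_write(dataset$phantom$centroids[[i]], path,
             sprintf("truth/centroids%d", i - 1L))
  }
  h5_write(dataset$maps$maps, path, "truth/maps")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a dataset container
#'
#' @param path Container written by [save_dataset()].
#' @return An `sms_dataset` (ground truth included if present).
#' @export
load_dataset <- function(path) {
  container_check(path)
  cfg <- run_config_validate(do.call(run_config, yaml::yaml.load(
    rhdf5::h5read(path, "config/yaml"))))
  angles <- as.numeric(rhdf5::h5read(path, "trajectory/angles_deg"))
  traj <- radial_trajectory(
    scheme = as.character(rhdf5::h5read(path, "trajectory/scheme")),
    n_slices = as.integer(rhdf5::h5read(path, "trajectory/n_slices")),
    n_spokes = as.integer(rhdf5::h5read(path, "trajectory/n_spokes")),
    points_per_spoke = as.integer(rhdf5::h5read(path, "trajectory/points_per_spoke")),
    spokes_per_frame = as.integer(rhdf5::h5read(path, "trajectory/spokes_per_frame")),
    tr_ms = as.numeric(rhdf5::h5read(path, "trajectory/tr_ms")),
    fov_mm = as.numeric(rhdf5::h5read(path, "trajectory/fov_mm")),
    angles_deg = angles)
  phases <- rhdf5::h5read(path, "schedule/phases_rad")
  schedule <- caipirinha_schedule(traj$n_slices, nrow(phases))
  schedule$phases_rad <- phases
  data <- h5_read_cx(path, "kspace/data")
  kspace <- structure(list(data = data, trajectory = traj, schedule = schedule,
                           n_slices = traj$n_slices, n_coils = dim(data)[3],
                           noise_sigma = as.numeric(rhdf5::h5read(path, "kspace/noise_sigma"))),
                      class = "mc_kspace")
  phantom <- NULL
  if (h5_exists(path, "truth/slice0")) {
    slices <- list(); centroids <- list()
    i <- 0L
    while (h5_exists(path, sprintf("truth/slice%d", i))) {
      slices[[i + 1L]] <- h5_read_cx(path, sprintf("truth/slice%d", i))
      cen <- rhdf5::h5read(path, sprintf("truth/centroids%d", i))
      colnames(cen) <- c("x", "y")
      centroids[[i + 1L]] <- cen
      i <- i + 1L
    }
    phantom <- structure(list(slices = slices, centroids = centroids,
                              grid_size = dim(slices[[1]])[1],
                              n_slices = length(slices),
                              n_frames = dim(slices[[1]])[3],
                              motion = list(amplitude_px = cfg$motion_amplitude_px,
                                            period_frames = cfg$motion_period_frames),
                              seed = cfg$seed),
                         class = "dynamic_phantom")
  }
  maps <- NULL
  if (h5_exists(path, "truth/maps")) {
    m <- h5_read_cx(path, "truth/maps")
    maps <- structure(list(maps = m, grid_size = dim(m)[1],
                           n_coils = dim(m)[3], n_slices = dim(m)[4],
                           seed = cfg$seed + 1L),
                      class = "coil_maps")
  }
  rhdf5::h5closeAll()
  structure(list(phantom = phantom, maps = maps, kspace = kspace,
                 config = cfg),
            class = "sms_dataset")
}

#' Add a reconstruction (and the maps used) to a container
#'
#' @param path Existing container.
#' @param recon An `sms_recon`.
#' @param maps Optional estimated `coil_maps` to store under `maps/`.
#' @param method Label (`"admm"` or `"cgsense"`).
#' @return `path`, invisibly.
#' @export
save_recon <- function(path, recon, maps = NULL, method = "admm") {
  container_check(path)
  for (grp in c("recon")) {
    if (h5_exists(path, grp)) rhdf5::h5delete(path, grp)
  }
  ns <- dim(recon$x)[3]
  for (i in seq_len(ns)) {
    h5_write(recon$x[, , i, ], path, sprintf("recon/slice%d", i - 1L))
  }
  h5_write(method, path, "recon/method")
  h5_write(recon$lambda, path, "recon/lambda")
  if (!is.null(recon$trace)) {
    for (cl in names(recon$trace)) {
      h5_write(recon$trace[[cl]], path, paste0("recon/trace/", cl))
    }
  }
  if (!is.null(maps)) {
    if (h5_exists(path, "maps")) rhdf5::h5delete(path, "maps")
    for (i in seq_len(maps$n_slices)) {
      h5_write(maps$maps[, , , i], path, sprintf("maps/slice%d", i - 1L))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a reconstruction from a container
#'
#' @param path Container holding a `recon/` group.
#' @return An `sms_recon` (trace restored if stored).
#' @export
load_recon <- function(path) {
  container_check(path)
  if (!h5_exists(path, "recon/slice0")) stop_data("container has no reconstruction: %s", path)
  slices <- list()
  i <- 0L
  while (h5_exists(path, sprintf("recon/slice%d", i))) {
    slices[[i + 1L]] <- h5_read_cx(path, sprintf("recon/slice%d", i))
    i <- i + 1L
  }
  d <- dim(slices[[1]])
  x <- array(0i, dim = c(d[1], d[2], length(slices), d[3]))
  for (s in seq_along(slices)) x[, , s, ] <- slices[[s]]
  trace <- NULL
  if (h5_exists(path, "recon/trace")) {
    ls <- rhdf5::h5ls(path)
    cols <- ls$name[ls$group == "/recon/trace"]
    trace <- as.data.frame(lapply(stats::setNames(cols, cols), function(cl) {
      as.vector(rhdf5::h5read(path, paste0("recon/trace/", cl)))
    }))
  }
  lambda <- as.numeric(rhdf5::h5read(path, "recon/lambda"))
  rhdf5::h5closeAll()
  structure(list(x = x, trace = trace, converged = NA, lambda = lambda,
                 scale = NA_real_, config = NULL),
            class = "sms_recon")
}

#' Store a metric table or array under `metrics/`
#'
#' @param path Container file.
#' @param name Dataset name (under `metrics/`).
#' @param value Numeric array/vector or data frame (stored column-wise).
#' @return `path`, invisibly.
#' @export
save_metric <- function(path, name, value) {
  container_check(path)
  full <- paste0("metrics/", name)
  if (h5_exists(path, full)) rhdf5::h5delete(path, full)
  if (is.data.frame(value)) {
    for (cl in names(value)) h5_write(value[[cl]], path, paste0(full, "/", cl))
  } else {
    h5_write(value, path, full)
  }
  rhdf5::h5closeAll()
  invisible(path)
}
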