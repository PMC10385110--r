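#' Write a trajectory as CSV
#'
#' Columns `k, x, y` with `k = 0` for the path origin when the trajectory
#' includes it (odd-length convention is the caller's: pass what you want
#' written).
#'
#' @param traj n x 2 matrix of positions.
#' @param path output file path.
#' @param k optional step indices; defaults to `seq_len(nrow(traj)) - 1`.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, k = NULL) {
  traj <- as.matrix(traj)
  if (is.null(k)) k <- seq_len(nrow(traj)) - 1L
  utils::write.csv(data.frame(k = k, x = traj[, 1], y = traj[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV with columns `k, x, y` (as written by
#'   [write_trajectory_csv()]).
#' @return matrix with columns `x`, `y`, ordered by `k`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$k), ]
  as.matrix(df[, c("x", "y")])
}

#' Write per-step polar measurements as CSV
#'
#' Columns `k, r, phi`, one row per step (k starting at 1).
#'
#' @param steps n x 2 matrix with columns `r`, `phi`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_steps_csv <- function(steps, path) {
  utils::write.csv(data.frame(k = seq_len(nrow(steps)), r = steps[, 1],
                              phi = steps[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory as a GPX track
#'
#' Maps the local east-north meter frame onto latitude/longitude through a
#' flat local-tangent-plane approximation anchored at the given origin
#' (adequate for walks of a few kilometers).
#'
#' @param traj n x 2 matrix of positions, meters east/north of the origin.
#' @param path output `.gpx` file path.
#' @param origin_lat,origin_lon geodetic anchor of the local frame, degrees.
#' @param name track name written into the file.
#' @return the path, invisibly.
#' @export
write_gpx <- function(traj, path, origin_lat = 0, origin_lon = 0,
                      name = "gaitmff track") {
  traj <- as.matrix(traj)
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(origin_lat * pi / 180)
  lat <- origin_lat + traj[, 2] / m_per_deg_lat
  lon <- origin_lon + traj[, 1] / m_per_deg_lon
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gpx version=\"1.1\" creator=\"gaitmff\" xmlns=\"http://www.topografix.com/GPX/1/1\">",
    paste0("  <trk><name>", name, "</name><trkseg>"),
    sprintf("    <trkpt lat=\"%.8f\" lon=\"%.8f\"/>", lat, lon),
    "  </trkseg></trk>",
    "</gpx>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' Keys mirror the arguments of [scenario_config()]; nested keys configure
#' the sub-objects. All keys are optional -- anything absent keeps its
#' default. Recognized top-level keys: `n_steps`, `coeff`, `sigma_r_true`,
#' `sigma_phi_true`, `s_scale`, `g_scale`, `sigma_r_model`,
#' `sigma_phi_model`, `n_particles`, `resample_every`, `gps_dropout`,
#' `seed`; maps `heading` (base, amplitude, period, phase), `population`
#' (arguments of [kinematic_population()]), `sensors` (arguments of
#' [sensor_spec()]; covariances as row-major length-4 vectors), `mff`
#' (arguments of [mff_config()]).
#'
#' @param path YAML file path.
#' @param seed optional master-seed override.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path, seed = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  args <- list()
  for (key in c("n_steps", "coeff", "sigma_r_true", "sigma_phi_true",
                "s_scale", "g_scale", "sigma_r_model", "sigma_phi_model",
                "n_particles", "resample_every", "gps_dropout", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$heading)) args$heading <- raw$heading
  if (!is.null(raw$population)) {
    args$population <- do.call(kinematic_population, raw$population)
  }
  if (!is.null(raw$sensors)) {
    s <- raw$sensors
    for (nm in c("imu_step_cov", "gps_cov")) {
      if (!is.null(s[[nm]])) s[[nm]] <- matrix(as.numeric(s[[nm]]), 2L, 2L,
                                               byrow = TRUE)
    }
    args$sensors <- do.call(sensor_spec, s)
  }
  if (!is.null(raw$mff)) args$mff <- do.call(mff_config, raw$mff)
  if (!is.null(seed)) args$seed <- seed
  do.call(scenario_config, args)
}

#' Write a filter run summary as JSON
#'
#' Contains only deterministic quantities (wall-clock timings live in the
#' profile report instead), so a rerun under the same master seed produces a
#' bit-identical file.
#'
#' @param result a `"filter_result"` (with `rmse`/`combo` fields filled by
#'   [run_combination()]).
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_run_summary <- function(result, path) {
  stopifnot(inherits(result, "filter_result"))
  summary <- list(combo = result$combo, method = result$method,
                  n_steps = nrow(result$estimates),
                  rmse_m = result$rmse)
  if (result$method == "mff") {
    summary$mean_iterations <- mean(result$diagnostics$iterations)
    summary$all_converged <- all(result$diagnostics$converged)
  }
  if (result$method == "pf") {
    summary$min_ess <- min(result$diagnostics$ess)
  }
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
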