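#' Root-mean-square trajectory error
#'
#' `sqrt(mean_k ||est_k - truth_k||^2)`: the RMS of the Euclidean error norm
#' over aligned steps.
#'
#' @param est n x 2 matrix of estimated positions.
#' @param truth n x 2 matrix of true positions.
#' @return RMSE in meters (0 iff identical).
#' @export
rmse <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth))) {
    stop("rmse: trajectory length mismatch (", nrow(est), " vs ",
         nrow(truth), ")")
  }
  sqrt(mean(rowSums((est - truth)^2)))
}

# Raw (filter-free) estimates for a sensor set: verbatim measurements for a
# single sensor, per-step information-form fusion for both.
raw_estimates <- function(sim, sensors) {
  n <- sim$cfg$n_steps
  if (setequal(sensors, "imu")) {
    return(sim$imu$track[-1, , drop = FALSE])
  }
  if (setequal(sensors, "gps")) {
    return(sim$gps$fixes)
  }
  est <- matrix(NA_real_, n, 2L)
  for (k in seq_len(n)) {
    g <- sim$gps$beliefs[[k]]
    est[k, ] <- if (is.null(g)) {
      sim$imu$beliefs[[k]]$mean
    } else {
      fuse_gaussians(sim$imu$beliefs[[k]], g)$mean
    }
  }
  est
}

#' Run one sensor/filter combination on a simulated scenario
#'
#' Simulates the scenario defined by `cfg` (deterministically, from its
#' master seed) and produces the trajectory estimate for the requested
#' sensor subset and filter: `"none"` returns raw measurements (or their
#' per-step fusion when both sensors are selected), `"mff"` runs the
#' mode-finding filter, `"pf"` the particle filter.
#'
#' @param cfg a [scenario_config()].
#' @param sensors character subset of `c("imu", "gps")`, non-empty.
#' @param filter one of `"none"`, `"mff"`, `"pf"`.
#' @param sim optional pre-simulated scenario (output of
#'   [simulate_scenario()] on `cfg`) to reuse across combinations.
#' @return a `"filter_result"` with `rmse` (meters vs. truth), `combo` label,
#'   `estimates`, diagnostics and stage timings.
#' @export
run_combination <- function(cfg, sensors, filter = c("none", "mff", "pf"),
                            sim = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  filter <- match.arg(filter)
  if (length(sensors) == 0L) stop("run_combination: empty sensor set")
  sensors <- unique(match.arg(sensors, c("imu", "gps"), several.ok = TRUE))
  if (is.null(sim)) sim <- simulate_scenario(cfg)
  obs_seq <- list()
  if ("imu" %in% sensors) obs_seq$imu <- sim$imu$beliefs
  if ("gps" %in% sensors) obs_seq$gps <- sim$gps$beliefs
  res <- switch(filter,
    none = {
      t0 <- proc.time()[["elapsed"]]
      est <- raw_estimates(sim, sensors)
      structure(list(estimates = est, x0 = c(0, 0),
                     diagnostics = data.frame(step = seq_len(nrow(est))),
                     timing = c(fuse = proc.time()[["elapsed"]] - t0),
                     method = "none"),
                class = "filter_result")
    },
    mff = run_mff(obs_seq, sim$step_template, cfg$mff,
                  x0 = sim$truth$trajectory[1, ],
                  adapt = cfg$adapt, adapt_rate = cfg$adapt_rate),
    pf = {
      set.seed(derive_seed(cfg$seed, "pf"))
      run_pf(obs_seq, sim$step_template, n_particles = cfg$n_particles,
             resample_every = cfg$resample_every,
             x0 = sim$truth$trajectory[1, ],
             adapt = cfg$adapt, adapt_rate = cfg$adapt_rate)
    })
  truth_pts <- sim$truth$trajectory[-1, , drop = FALSE]
  ok <- stats::complete.cases(res$estimates)
  res$rmse <- rmse(res$estimates[ok, , drop = FALSE],
                   truth_pts[ok, , drop = FALSE])
  res$combo <- paste0(paste(toupper(sort(sensors)), collapse = "+"),
                      if (filter != "none") paste0("+", toupper(filter)))
  res
}

#' Sweep RMSE over a grid of sensor noise scales
#'
#' Runs every requested sensor/filter combination at every pair of IMU and
#' GPS covariance scale factors. Each grid cell is an independent simulation
#' whose seed derives from the scenario's master seed through a counter, so
#' cells are mutually independent yet the whole sweep is reproducible.
#'
#' @param cfg a [scenario_config()] (its `s_scale`/`g_scale` are overridden
#'   cell by cell).
#' @param s_scales,g_scales numeric vectors of scale factors for the IMU step
#'   covariance and GPS covariance.
#' @param combos list of combinations, each a list with elements `sensors`
#'   and `filter`; defaults to the full nine-way grid (each sensor set with
#'   no filter, the MFF and the PF).
#' @return a data frame of class `"sweep_table"` with columns `combo`,
#'   `s_scale`, `g_scale`, `rmse`.
#' @export
sweep_noise_grid <- function(cfg,
                             s_scales = c(0.25, 0.5, 1, 2, 4),
                             g_scales = c(0.25, 0.5, 1, 2, 4),
                             combos = default_combos()) {
  stopifnot(inherits(cfg, "scenario_config"))
  rows <- list()
  cell <- 0L
  for (s in s_scales) {
    for (g in g_scales) {
      cell <- cell + 1L
      cfg_cell <- cfg
      cfg_cell$s_scale <- s
      cfg_cell$g_scale <- g
      cfg_cell$seed <- derive_seed(cfg$seed, "cell", cell)
      sim <- simulate_scenario(cfg_cell)
      for (cb in combos) {
        res <- run_combination(cfg_cell, cb$sensors, cb$filter, sim = sim)
        rows[[length(rows) + 1L]] <-
          data.frame(combo = res$combo, s_scale = s, g_scale = g,
                     rmse = res$rmse)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Default sensor/filter combinations for sweeps
#'
#' The nine-way grid: IMU-only, GPS-only and GPS+IMU, each raw, under the
#' mode-finding filter, and under the particle filter.
#'
#' @return list of `list(sensors=, filter=)` entries.
#' @export
default_combos <- function() {
  combos <- list()
  for (sensors in list("imu", "gps", c("gps", "imu"))) {
    for (filter in c("none", "mff", "pf")) {
      combos[[length(combos) + 1L]] <- list(sensors = sensors,
                                            filter = filter)
    }
  }
  combos
}

#' Reshape a noise sweep into a wide RMSE table
#'
#' One row per combination, one column per GPS scale, blocks stacked by IMU
#' scale -- the conventional layout for reporting a sensor-noise study.
#'
#' @param tab a `"sweep_table"` from [sweep_noise_grid()].
#' @return data frame with columns `s_scale`, `combo`, and one `g_<scale>`
#'   column per GPS scale factor.
#' @export
sweep_table_wide <- function(tab) {
  g_levels <- sort(unique(tab$g_scale))
  s_levels <- sort(unique(tab$s_scale))
  combos <- unique(tab$combo)
  rows <- list()
  for (s in s_levels) {
    for (cb in combos) {
      sub <- tab[tab$s_scale == s & tab$combo == cb, ]
      vals <- vapply(g_levels,
                     function(g) sub$rmse[match(g, sub$g_scale)],
                     numeric(1))
      row <- data.frame(s_scale = s, combo = cb)
      row[paste0("g_", g_levels)] <- as.list(vals)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Sweep filter resolution against accuracy and runtime
#'
#' Reruns the same scenario under increasing particle counts (PF) and
#' decreasing gradient-ascent step sizes (MFF), recording RMSE and wall time.
#' Accuracy is expected to be essentially flat across resolution; the timing
#' column is informational only (hardware-dependent).
#'
#' @param cfg a [scenario_config()].
#' @param particle_counts integer vector of PF sizes.
#' @param deltas numeric vector of MFF ascent step sizes.
#' @return data frame with columns `filter`, `resolution`, `rmse`, `seconds`.
#' @export
sweep_resolution <- function(cfg,
                             particle_counts = c(100L, 1000L, 10000L),
                             deltas = 2^-(2:4)) {
  stopifnot(inherits(cfg, "scenario_config"))
  sim <- simulate_scenario(cfg)
  rows <- list()
  for (np in particle_counts) {
    cfg_i <- cfg; cfg_i$n_particles <- as.integer(np)
    t0 <- proc.time()[["elapsed"]]
    res <- run_combination(cfg_i, c("gps", "imu"), "pf", sim = sim)
    rows[[length(rows) + 1L]] <-
      data.frame(filter = "pf", resolution = np, rmse = res$rmse,
                 seconds = proc.time()[["elapsed"]] - t0)
  }
  for (d in deltas) {
    cfg_i <- cfg
    cfg_i$mff <- mff_config(delta = d, tol = cfg$mff$tol,
                            max_iter = cfg$mff$max_iter,
                            ascent_space = cfg$mff$ascent_space)
    t0 <- proc.time()[["elapsed"]]
    res <- run_combination(cfg_i, c("gps", "imu"), "mff", sim = sim)
    rows[[length(rows) + 1L]] <-
      data.frame(filter = "mff", resolution = d, rmse = res$rmse,
                 seconds = proc.time()[["elapsed"]] - t0)
  }
  do.call(rbind, rows)
}

#' Per-stage timing report for a filter run
#'
#' Informational wall-time accounting: one row per filter stage plus a total
#' row equal to their sum. Never part of any accuracy assertion.
#'
#' @param result a `"filter_result"`.
#' @return data frame with columns `stage`, `seconds`.
#' @export
profile_stages <- function(result) {
  stopifnot(inherits(result, "filter_result"))
  df <- data.frame(stage = names(result$timing),
                   seconds = unname(result$timing))
  rbind(df, data.frame(stage = "total", seconds = sum(df$seconds)))
}
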