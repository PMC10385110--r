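#' Sensor error specification
#'
#' Per-step error model for the two simulated sensors. The IMU delivers each
#' physical step as a polar measurement corrupted by a constant bias and
#' Gaussian noise with the given polar covariance; dead-reckoning these steps
#' yields a global position whose stated covariance grows linearly in the
#' step count. The GPS delivers Cartesian fixes with a stationary covariance.
#' Defaults are characterization values for a foot-mounted inertial unit
#' processed by a zero-velocity-update step detector and a wearable 1 Hz GPS.
#'
#' @param imu_bias polar step bias `(delta_r m, delta_phi rad)`.
#' @param imu_step_cov 2x2 polar per-step covariance (m^2, m rad, rad^2).
#' @param gps_bias Cartesian bias, meters.
#' @param gps_cov 2x2 Cartesian covariance, m^2.
#' @param imu_growth_coeff dimensionless `c`: the IMU global belief
#'   covariance at step k is `c * k * (J Sigma_s J')` with J the
#'   polar-to-Cartesian Jacobian at the measured step.
#' @return object of class `"sensor_spec"`.
#' @export
sensor_spec <- function(imu_bias = c(-0.0531, 0.000193),
                        imu_step_cov = matrix(c(0.0618, 0.0018,
                                                0.0018, 0.0532), 2L, 2L),
                        gps_bias = c(0, 0),
                        gps_cov = diag(c(21.846, 24.445)),
                        imu_growth_coeff = 1) {
  check_spd <- function(S, nm) {
    S <- as.matrix(S)
    if (!all(dim(S) == c(2L, 2L)) || any(!is.finite(S))) {
      stop("sensor_spec: '", nm, "' must be a finite 2x2 matrix")
    }
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("sensor_spec: '", nm, "' must be SPD")
    (S + t(S)) / 2
  }
  if (!is.finite(imu_growth_coeff) || imu_growth_coeff <= 0) {
    stop("sensor_spec: 'imu_growth_coeff' must be > 0")
  }
  structure(list(imu_bias = as.numeric(imu_bias),
                 imu_step_cov = check_spd(imu_step_cov, "imu_step_cov"),
                 gps_bias = as.numeric(gps_bias),
                 gps_cov = check_spd(gps_cov, "gps_cov"),
                 imu_growth_coeff = imu_growth_coeff),
            class = "sensor_spec")
}

#' Kinematic population for sampling simulated subjects
#'
#' Gaussian leg-length population (truncated at zero) plus fixed stance
#' angles. The default hip range of 39.2 degrees, split symmetrically between
#' extension and flexion, follows published motion-capture statistics of
#' healthy gait; the knee stance angles and the leg-length means/sds are
#' synthetic population stand-ins chosen from standard adult anthropometry.
#'
#' @param l_u_mean,l_u_sd upper-leg length mean and sd, meters.
#' @param l_l_mean,l_l_sd lower-leg length mean and sd, meters.
#' @param theta_he,theta_hf,theta_ke,theta_kf stance angles, radians.
#' @return object of class `"kinematic_population"`.
#' @export
kinematic_population <- function(l_u_mean = 0.44, l_u_sd = 0.02,
                                 l_l_mean = 0.43, l_l_sd = 0.02,
                                 theta_he = 19.6 * pi / 180,
                                 theta_hf = 19.6 * pi / 180,
                                 theta_ke = 8 * pi / 180,
                                 theta_kf = 15 * pi / 180) {
  if (any(c(l_u_sd, l_l_sd) < 0)) {
    stop("kinematic_population: sds must be >= 0")
  }
  if (any(c(l_u_mean, l_l_mean) <= 0)) {
    stop("kinematic_population: mean lengths must be > 0")
  }
  structure(list(l_u_mean = l_u_mean, l_u_sd = l_u_sd,
                 l_l_mean = l_l_mean, l_l_sd = l_l_sd,
                 theta_he = theta_he, theta_hf = theta_hf,
                 theta_ke = theta_ke, theta_kf = theta_kf),
            class = "kinematic_population")
}

#' Draw a simulated subject's kinematics from a population
#'
#' Leg lengths are sampled from the population Gaussians, redrawing any
#' non-positive values; stance angles are taken as the population values.
#' Uses the ambient RNG stream.
#'
#' @param population a [kinematic_population()].
#' @return a [kinematic_params()] object.
#' @export
sample_kinematics <- function(population) {
  stopifnot(inherits(population, "kinematic_population"))
  draw_pos <- function(mean, sd) {
    if (sd == 0) return(mean)
    x <- stats::rnorm(1, mean, sd)
    while (x <= 0) x <- stats::rnorm(1, mean, sd)
    x
  }
  kinematic_params(l_u = draw_pos(population$l_u_mean, population$l_u_sd),
                   l_l = draw_pos(population$l_l_mean, population$l_l_sd),
                   theta_he = population$theta_he,
                   theta_hf = population$theta_hf,
                   theta_ke = population$theta_ke,
                   theta_kf = population$theta_kf)
}

#' Scenario configuration
#'
#' Bundles everything a Monte Carlo experiment needs: walk length, subject
#' population, truth variability, the sinusoidal heading path, sensor error
#' spec and scale factors, the step-model standard deviations the filters
#' assume, filter settings, and a master seed from which every stochastic
#' stream derives its own seed.
#'
#' @param n_steps number of physical steps to simulate (default 5000).
#' @param population a [kinematic_population()].
#' @param coeff per-term multipliers passed to [mean_step_size()].
#' @param sigma_r_true,sigma_phi_true true per-step variability of the
#'   simulated walker (m, rad).
#' @param heading list with `base` (rad), `amplitude` (rad), `period`
#'   (steps) and `phase` (rad) of the low-frequency sinusoidal mean heading.
#' @param sensors a [sensor_spec()].
#' @param s_scale,g_scale multipliers on the IMU step covariance and the GPS
#'   covariance (the noise-grid axes).
#' @param sigma_r_model,sigma_phi_model step-model standard deviations the
#'   filters assume (m, rad).
#' @param mff an [mff_config()].
#' @param adapt,adapt_rate online step-variance adaptation settings shared by
#'   both filters (see [run_mff()]).
#' @param n_particles,resample_every particle-filter settings.
#' @param gps_dropout probability that a GPS fix is missing at a step.
#' @param seed master seed; per-stream seeds derive from it via
#'   [derive_seed()].
#' @return object of class `"scenario_config"`.
#' @export
scenario_config <- function(n_steps = 5000L,
                            population = kinematic_population(),
                            coeff = c(1, 1),
                            sigma_r_true = 0.05, sigma_phi_true = 0.05,
                            heading = list(base = 0, amplitude = 0.5,
                                           period = 1000, phase = 0),
                            sensors = sensor_spec(),
                            s_scale = 1, g_scale = 1,
                            sigma_r_model = 0.1, sigma_phi_model = 0.1,
                            mff = mff_config(),
                            adapt = TRUE, adapt_rate = 0.05,
                            n_particles = 1000L, resample_every = 1L,
                            gps_dropout = 0,
                            seed = 1L) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) {
    stop("scenario_config: 'n_steps' must be >= 1")
  }
  if (s_scale <= 0 || g_scale <= 0) {
    stop("scenario_config: scale factors must be > 0")
  }
  if (gps_dropout < 0 || gps_dropout >= 1) {
    stop("scenario_config: 'gps_dropout' must be in [0, 1)")
  }
  stopifnot(inherits(population, "kinematic_population"),
            inherits(sensors, "sensor_spec"), inherits(mff, "mff_config"))
  h <- list(base = 0, amplitude = 0.5, period = 1000, phase = 0)
  h[names(heading)] <- heading
  structure(list(n_steps = n_steps, population = population,
                 coeff = as.numeric(coeff),
                 sigma_r_true = sigma_r_true,
                 sigma_phi_true = sigma_phi_true,
                 heading = h, sensors = sensors,
                 s_scale = s_scale, g_scale = g_scale,
                 sigma_r_model = sigma_r_model,
                 sigma_phi_model = sigma_phi_model,
                 mff = mff, adapt = isTRUE(adapt), adapt_rate = adapt_rate,
                 n_particles = as.integer(n_particles),
                 resample_every = as.integer(resample_every),
                 gps_dropout = gps_dropout,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Fixed identifiers for the package's stochastic streams.
.stream_ids <- c(kinematics = 1L, truth = 2L, imu = 3L, gps = 4L, pf = 5L,
                 cell = 6L)

#' Derive a stream seed from a master seed
#'
#' Deterministic arithmetic derivation (no RNG involved):
#' `(master * 31 + stream_id * 1299709 + index * 7919) mod (2^31 - 1)`,
#' so every stochastic stream (kinematics, truth, imu, gps, pf) and every
#' sweep cell gets its own reproducible seed below 2^31.
#'
#' @param master master seed, integer.
#' @param stream one of `"kinematics"`, `"truth"`, `"imu"`, `"gps"`, `"pf"`,
#'   `"cell"`.
#' @param index counter for indexed streams such as sweep cells (default 0).
#' @return integer seed in `[1, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stream, index = 0L) {
  id <- .stream_ids[[match.arg(stream, names(.stream_ids))]]
  s <- (as.double(master) * 31 + as.double(id) * 1299709 +
        as.double(index) * 7919) %% 2147483647
  as.integer(s) + 1L
}

#' Generate a ground-truth walking trajectory
#'
#' Step k has direction
#' `phi_k = base + A * sin(2 pi k / P + phase) + N(0, sigma_phi_true)` and
#' length `r_k = N(r_bar(kin), sigma_r_true)` truncated positive, where
#' `r_bar(kin)` comes from [mean_step_size()]. The walk starts at the origin
#' of the local east-north frame. Uses the ambient RNG stream.
#'
#' @param cfg a [scenario_config()].
#' @param kin a [kinematic_params()] subject.
#' @return list with `trajectory` ((n_steps + 1) x 2 matrix, row 1 = origin)
#'   and `steps` (n_steps x 2 matrix, columns `r`, `phi`).
#' @export
generate_truth <- function(cfg, kin) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(kin, "kinematic_params"))
  n <- cfg$n_steps
  r_bar <- mean_step_size(kin, cfg$coeff)
  h <- cfg$heading
  k <- seq_len(n)
  phi <- h$base + h$amplitude * sin(2 * pi * k / h$period + h$phase)
  if (cfg$sigma_phi_true > 0) phi <- phi + stats::rnorm(n, 0, cfg$sigma_phi_true)
  phi <- wrap_angle(phi)
  r <- if (cfg$sigma_r_true > 0) stats::rnorm(n, r_bar, cfg$sigma_r_true) else rep(r_bar, n)
  while (any(r <= 0)) {
    bad <- r <= 0
    r[bad] <- stats::rnorm(sum(bad), r_bar, cfg$sigma_r_true)
  }
  traj <- rbind(c(0, 0), cbind(cumsum(r * cos(phi)), cumsum(r * sin(phi))))
  colnames(traj) <- c("x", "y")
  list(trajectory = traj, steps = cbind(r = r, phi = phi))
}

# Polar -> Cartesian covariance propagation at a measured step (r, phi).
polar_step_cov_to_cartesian <- function(S, r, phi) {
  J <- matrix(c(cos(phi), sin(phi), -r * sin(phi), r * cos(phi)), 2L, 2L)
  J %*% S %*% t(J)
}

#' Simulate the IMU measurement stream
#'
#' Each true polar step is corrupted by the IMU bias and Gaussian noise with
#' covariance `imu_step_cov * scale`, then dead-reckoned from the known
#' origin into a global track. The per-step observation belief has the
#' dead-reckoned position as mean and covariance
#' `c * k * (J Sigma_s J')`, growing linearly with the step count k (J is the
#' polar-to-Cartesian Jacobian at the measured step). Uses the ambient RNG
#' stream.
#'
#' @param truth output of [generate_truth()].
#' @param spec a [sensor_spec()].
#' @param scale multiplier on the IMU step covariance.
#' @return list with `steps` (n x 2 measured polar steps), `track`
#'   ((n + 1) x 2 dead-reckoned positions), and `beliefs` (list of n
#'   Cartesian [gaussian_belief()]s).
#' @export
simulate_imu <- function(truth, spec, scale = 1) {
  stopifnot(inherits(spec, "sensor_spec"))
  n <- nrow(truth$steps)
  S <- spec$imu_step_cov * scale
  noise <- if (all(S == 0)) matrix(0, n, 2L) else MASS::mvrnorm(n, c(0, 0), S)
  meas <- truth$steps + matrix(spec$imu_bias, n, 2L, byrow = TRUE) + noise
  # clamp at a hair above zero: a negative measured length is physically a
  # missed step, and r = 0 would make the polar->Cartesian Jacobian singular
  meas[, 1] <- pmax(meas[, 1], 1e-6)
  meas[, 2] <- wrap_angle(meas[, 2])
  dx <- meas[, 1] * cos(meas[, 2])
  dy <- meas[, 1] * sin(meas[, 2])
  origin <- truth$trajectory[1, ]
  track <- rbind(origin,
                 cbind(origin[1] + cumsum(dx), origin[2] + cumsum(dy)))
  rownames(track) <- NULL
  colnames(track) <- c("x", "y")
  # degenerate noiseless case: keep a tiny SPD floor so beliefs stay valid
  S_belief <- if (all(S == 0)) diag(1e-12, 2L) else S
  beliefs <- lapply(seq_len(n), function(k) {
    Ck <- spec$imu_growth_coeff * k *
      polar_step_cov_to_cartesian(S_belief, meas[k, 1], meas[k, 2])
    # ridge against round-off indefiniteness when a step is near-degenerate
    Ck <- (Ck + t(Ck)) / 2 + diag(1e-9, 2L)
    gaussian_belief(track[k + 1, ], Ck, frame = "cartesian")
  })
  list(steps = meas, track = track, beliefs = beliefs)
}

#' Simulate the GPS measurement stream
#'
#' One fix per step: the true position plus the GPS bias and Gaussian noise
#' with covariance `gps_cov * scale`. The per-fix belief carries the same
#' stationary covariance. With `dropout > 0`, fixes are independently missing
#' with that probability (their belief entry is `NULL`). Uses the ambient RNG
#' stream.
#'
#' @param truth output of [generate_truth()].
#' @param spec a [sensor_spec()].
#' @param scale multiplier on the GPS covariance.
#' @param dropout per-fix missingness probability in `[0, 1)`.
#' @return list with `fixes` (n x 2 matrix, NA rows where dropped) and
#'   `beliefs` (list of n Cartesian [gaussian_belief()]s or `NULL`s).
#' @export
simulate_gps <- function(truth, spec, scale = 1, dropout = 0) {
  stopifnot(inherits(spec, "sensor_spec"))
  pos <- truth$trajectory[-1, , drop = FALSE]
  n <- nrow(pos)
  S <- spec$gps_cov * scale
  noise <- if (all(S == 0)) matrix(0, n, 2L) else MASS::mvrnorm(n, c(0, 0), S)
  fixes <- pos + matrix(spec$gps_bias, n, 2L, byrow = TRUE) + noise
  colnames(fixes) <- c("x", "y")
  keep <- if (dropout > 0) stats::runif(n) >= dropout else rep(TRUE, n)
  S_belief <- if (all(S == 0)) diag(1e-12, 2L) else S
  beliefs <- lapply(seq_len(n), function(k) {
    if (!keep[k]) return(NULL)
    gaussian_belief(fixes[k, ], S_belief, frame = "cartesian")
  })
  fixes[!keep, ] <- NA_real_
  list(fixes = fixes, beliefs = beliefs)
}

#' Simulate a full scenario
#'
#' Draws a subject, generates the ground-truth walk, and synthesizes both
#' measurement streams, seeding each stochastic stream independently from the
#' scenario's master seed so reruns are bit-identical.
#'
#' @param cfg a [scenario_config()].
#' @return list with `kin`, `truth`, `imu`, `gps`, `step_template` (the
#'   [step_model_params()] the filters assume: kinematic mean step length,
#'   base heading, model sds) and `cfg`.
#' @export
simulate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(derive_seed(cfg$seed, "kinematics"))
  kin <- sample_kinematics(cfg$population)
  set.seed(derive_seed(cfg$seed, "truth"))
  truth <- generate_truth(cfg, kin)
  set.seed(derive_seed(cfg$seed, "imu"))
  imu <- simulate_imu(truth, cfg$sensors, cfg$s_scale)
  set.seed(derive_seed(cfg$seed, "gps"))
  gps <- simulate_gps(truth, cfg$sensors, cfg$g_scale, cfg$gps_dropout)
  step_template <- step_model_params(mean_step_size(kin, cfg$coeff),
                                     cfg$heading$base,
                                     cfg$sigma_r_model, cfg$sigma_phi_model)
  list(kin = kin, truth = truth, imu = imu, gps = gps,
       step_template = step_template, cfg = cfg)
}
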