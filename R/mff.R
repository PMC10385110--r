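#' Mode-finding filter configuration
#'
#' @param delta nominal gradient-ascent step size (default 2^-4). The ascent
#'   uses this as the starting step size and halves it whenever a step would
#'   decrease the objective, which guarantees monotone ascent without a line
#'   search.
#' @param tol convergence threshold on the Euclidean norm of an accepted
#'   update, meters.
#' @param max_iter iteration cap, >= 1.
#' @param ascent_space `"log-density"` (default) ascends the log posterior;
#'   `"density"` ascends the unnormalized posterior density itself, whose
#'   gradient is the log-gradient scaled by the (positive) density value, so
#'   both share the same stationary point.
#' @return object of class `"mff_config"`.
#' @export
mff_config <- function(delta = 2^-4, tol = 1e-6, max_iter = 200L,
                       ascent_space = c("log-density", "density")) {
  ascent_space <- match.arg(ascent_space)
  if (!is.finite(delta) || delta <= 0) stop("mff_config: 'delta' must be > 0")
  if (!is.finite(tol) || tol <= 0) stop("mff_config: 'tol' must be > 0")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) {
    stop("mff_config: 'max_iter' must be >= 1")
  }
  structure(list(delta = delta, tol = tol, max_iter = max_iter,
                 ascent_space = ascent_space),
            class = "mff_config")
}

#' Unnormalized log posterior of one filter step
#'
#' The corrected belief for step k is the product of the polar-Gaussian
#' transition density (centered on the previous mode) and the fused Gaussian
#' observation likelihood. With all scalar normalization factors dropped its
#' logarithm is
#' `-1/2 [ (rho' - rho_bar)' Sigma_rho^-1 (rho' - rho_bar)
#'        + (x - x_obs)' Sigma_obs^-1 (x - x_obs) ]`,
#' where `rho'` is the polar decomposition of `x - x_prev_hat` and the
#' angular residual is wrapped into (-pi, pi].
#'
#' @param x candidate position: numeric 2-vector or n x 2 matrix.
#' @param x_prev_hat previous mode, numeric 2-vector.
#' @param step a [step_model_params()] object.
#' @param obs fused observation likelihood, a Cartesian [gaussian_belief()].
#' @return numeric vector of unnormalized log-posterior values (<= 0, with 0
#'   attained only if both residuals vanish simultaneously).
#' @export
posterior_log_unnorm <- function(x, x_prev_hat, step, obs) {
  stopifnot(inherits(step, "step_model_params"),
            inherits(obs, "gaussian_belief"))
  rho <- polar_of_displacement(x, x_prev_hat)
  dr <- rho$r - step$r_bar
  dphi <- wrap_angle(rho$phi - step$phi_bar)
  qs <- dr^2 / step$sigma_r^2 + dphi^2 / step$sigma_phi^2
  Sinv <- inv2(obs$cov, "observation covariance")
  if (is.matrix(x)) {
    d1 <- x[, 1] - obs$mean[1]; d2 <- x[, 2] - obs$mean[2]
  } else {
    d1 <- x[1] - obs$mean[1]; d2 <- x[2] - obs$mean[2]
  }
  qo <- Sinv[1, 1] * d1^2 + 2 * Sinv[1, 2] * d1 * d2 + Sinv[2, 2] * d2^2
  -0.5 * (qs + qo)
}

#' Analytic gradient of the log posterior
#'
#' Gradient of [posterior_log_unnorm()] with respect to `x`, assembled from
#' the analytic Jacobian of the polar displacement map:
#' `-J' Sigma_rho^-1 (rho' - rho_bar) - Sigma_obs^-1 (x - x_obs)`.
#' The density-space gradient is this multiplied by the positive density
#' value, so both share the same zero set.
#'
#' @inheritParams posterior_log_unnorm
#' @param x candidate position, numeric 2-vector, at distance > 1e-9 m from
#'   `x_prev_hat`.
#' @return numeric gradient 2-vector.
#' @export
posterior_gradient <- function(x, x_prev_hat, step, obs) {
  stopifnot(inherits(step, "step_model_params"),
            inherits(obs, "gaussian_belief"))
  x <- as.numeric(x); x_prev_hat <- as.numeric(x_prev_hat)
  J <- displacement_jacobian(x, x_prev_hat)
  rho <- polar_of_displacement(x, x_prev_hat)
  resid <- c(rho$r - step$r_bar, wrap_angle(rho$phi - step$phi_bar))
  g_step <- -as.numeric(t(J) %*% (resid / c(step$sigma_r^2,
                                            step$sigma_phi^2)))
  Sinv <- inv2(obs$cov, "observation covariance")
  g_obs <- -as.numeric(Sinv %*% (x - obs$mean))
  g_step + g_obs
}

#' Initial estimate for the per-step mode search
#'
#' Fuses the Gaussian linearized prediction with the fused observation
#' likelihood in information form and returns the resulting mean. This lands
#' close enough to the true mode that only a few ascent iterations are
#' typically needed.
#'
#' @inheritParams posterior_log_unnorm
#' @return numeric position 2-vector.
#' @export
initial_guess <- function(x_prev_hat, step, obs) {
  fuse_gaussians(linearized_prediction(x_prev_hat, step), obs)$mean
}

#' Fixed-step gradient ascent with monotone safeguard
#'
#' Iterates `x <- x + delta * gradient(x)` from `x0`. A step that would
#' decrease the objective is rejected and `delta` halved (the nominal `delta`
#' is kept deliberately constant otherwise -- no line search). Iteration stops
#' when the norm of an accepted update falls below `tol`, when `delta`
#' underflows (no ascent direction at this scale), or at `max_iter`.
#'
#' @param objective function of a position 2-vector returning a scalar.
#' @param gradient function of a position 2-vector returning its gradient.
#' @param x0 starting position, numeric 2-vector.
#' @param cfg an [mff_config()].
#' @return list with `mode`, `value` (objective at mode), `iterations`,
#'   `converged`.
#' @export
gradient_ascent <- function(objective, gradient, x0, cfg = mff_config()) {
  stopifnot(inherits(cfg, "mff_config"))
  x <- as.numeric(x0)
  f <- objective(x)
  if (!is.finite(f)) stop("gradient_ascent: objective not finite at x0")
  delta <- cfg$delta
  it <- 0L
  converged <- FALSE
  while (it < cfg$max_iter) {
    it <- it + 1L
    g <- gradient(x)
    if (any(!is.finite(g))) {
      stop("gradient_ascent: non-finite gradient at iteration ", it,
           " (x = ", paste(signif(x, 6), collapse = ", "), ")")
    }
    # stationary: even a nominal-size step could not move more than tol
    if (sqrt(sum(g^2)) * cfg$delta < cfg$tol) { converged <- TRUE; break }
    stp <- delta * g
    x_new <- x + stp
    f_new <- objective(x_new)
    if (!is.finite(f_new) || f_new < f) {
      delta <- delta / 2
      if (delta < 1e-12) { converged <- TRUE; break }
      next
    }
    x <- x_new
    f <- f_new
    if (sqrt(sum(stp^2)) < cfg$tol) { converged <- TRUE; break }
  }
  list(mode = x, value = f, iterations = it, converged = converged)
}

# Fuse a list of Gaussian beliefs pairwise (associative, order-independent).
fuse_observations <- function(observations) {
  Reduce(fuse_gaussians, observations)
}

# Exponentially weighted innovation-variance update of the step-model
# variances. The innovation is the polar mismatch between the step implied by
# the fused observation (from the previous estimate) and the model step
# (r_bar, phi_bar). Variances never drop below their configured baselines.
adapt_step_variances <- function(state, obs_mean, x_prev, r_bar, phi_bar,
                                 rate) {
  rho <- polar_of_displacement(as.numeric(obs_mean), as.numeric(x_prev))
  if (rho$degenerate) return(state)
  nu_r <- rho$r - r_bar
  nu_phi <- wrap_angle(rho$phi - phi_bar)
  state$r2 <- max(state$floor_r2, (1 - rate) * state$r2 + rate * nu_r^2)
  state$phi2 <- max(state$floor_phi2,
                    (1 - rate) * state$phi2 + rate * nu_phi^2)
  state
}

#' One recursion of the mode-finding filter
#'
#' Updates the expected heading from the two previous modes, fuses the
#' available observation likelihoods pairwise, seeds gradient ascent with the
#' linearized-fusion estimate, and ascends to the posterior mode. With no
#' observations (sensor dropout) the step falls back to the prediction-only
#' mode one nominal step ahead.
#'
#' @param x_prev_hat mode at step k-1, numeric 2-vector.
#' @param x_prev2_hat mode at step k-2 or `NULL` (first step).
#' @param step a [step_model_params()] template; its `phi_bar` is used as the
#'   heading fallback and replaced by the adapted heading otherwise.
#' @param observations list of Cartesian [gaussian_belief()] objects (possibly
#'   empty).
#' @param cfg an [mff_config()].
#' @return object of class `"mff_step_result"`: list with `mode`,
#'   `init_guess`, `iterations`, `converged`, `log_posterior_at_mode`,
#'   `phi_bar`, and `timing` (seconds per stage: fuse, init, ascend).
#' @export
mff_step <- function(x_prev_hat, x_prev2_hat, step, observations,
                     cfg = mff_config()) {
  stopifnot(inherits(step, "step_model_params"))
  x_prev_hat <- as.numeric(x_prev_hat)
  phi_bar <- update_heading(x_prev_hat, x_prev2_hat, fallback = step$phi_bar)
  stepk <- step_model_params(step$r_bar, phi_bar, step$sigma_r,
                             step$sigma_phi)
  timing <- c(fuse = 0, init = 0, ascend = 0)

  if (length(observations) == 0L) {
    mode <- x_prev_hat + stepk$r_bar * c(cos(phi_bar), sin(phi_bar))
    return(structure(list(mode = mode, init_guess = mode, iterations = 0L,
                          converged = TRUE, log_posterior_at_mode = 0,
                          phi_bar = phi_bar, timing = timing),
                     class = "mff_step_result"))
  }

  t0 <- proc.time()[["elapsed"]]
  obs <- fuse_observations(observations)
  t1 <- proc.time()[["elapsed"]]
  x0 <- initial_guess(x_prev_hat, stepk, obs)
  if (sqrt(sum((x0 - x_prev_hat)^2)) <= 1e-9) {
    # initializer collapsed onto the singular point of the polar map; nudge
    # one tolerance along the expected heading
    x0 <- x_prev_hat + max(cfg$tol, 1e-9) * c(cos(phi_bar), sin(phi_bar))
  }
  t2 <- proc.time()[["elapsed"]]

  logpost <- function(x) posterior_log_unnorm(x, x_prev_hat, stepk, obs)
  loggrad <- function(x) posterior_gradient(x, x_prev_hat, stepk, obs)
  if (cfg$ascent_space == "log-density") {
    res <- gradient_ascent(logpost, loggrad, x0, cfg)
    lp <- res$value
  } else {
    res <- gradient_ascent(function(x) exp(logpost(x)),
                           function(x) exp(logpost(x)) * loggrad(x),
                           x0, cfg)
    lp <- logpost(res$mode)
  }
  t3 <- proc.time()[["elapsed"]]
  timing <- c(fuse = t1 - t0, init = t2 - t1, ascend = t3 - t2)

  structure(list(mode = res$mode, init_guess = x0,
                 iterations = res$iterations, converged = res$converged,
                 log_posterior_at_mode = lp, phi_bar = phi_bar,
                 timing = timing),
            class = "mff_step_result")
}

# Validate a named list of per-step observation streams: every stream must
# have the same length; entries may be NULL (dropout) or gaussian_belief.
check_obs_sequences <- function(obs_sequences) {
  if (length(obs_sequences) == 0L) {
    stop("at least one observation stream is required")
  }
  lens <- vapply(obs_sequences, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("misaligned observation sequences: lengths ",
         paste(lens, collapse = ", "))
  }
  lens[1]
}

#' Run the mode-finding filter over a walk
#'
#' Applies [mff_step()] recursively from a known initial position (a delta
#' prior), retaining the mode at every step so the full walking trajectory is
#' reconstructed.
#'
#' @param obs_sequences named list of observation streams (e.g. `imu`, `gps`),
#'   each a list with one Cartesian [gaussian_belief()] (or `NULL` for
#'   dropout) per step; all streams must have equal length.
#' @param step_template a [step_model_params()] object; `phi_bar` serves as
#'   the initial heading, and `sigma_r`/`sigma_phi` as the baseline (and
#'   floor) step-model standard deviations.
#' @param cfg an [mff_config()].
#' @param x0 known initial position, numeric 2-vector.
#' @param adapt adapt the step-model variances online (default `TRUE`): after
#'   each step with observations, the squared polar innovation between the
#'   fused observation and the model step feeds an exponentially weighted
#'   variance estimate, floored at the template's baseline values. With
#'   `FALSE` the template standard deviations are held fixed.
#' @param adapt_rate exponential weight of the newest squared innovation.
#' @return a `"filter_result"`: list with `estimates` (n x 2 matrix of modes,
#'   one row per step), `x0`, `diagnostics` (data frame: step, iterations,
#'   converged, log_posterior, sigma_r, sigma_phi), `timing` (named seconds
#'   per stage) and `method = "mff"`.
#' @export
run_mff <- function(obs_sequences, step_template, cfg = mff_config(),
                    x0 = c(0, 0), adapt = TRUE, adapt_rate = 0.05) {
  stopifnot(inherits(step_template, "step_model_params"))
  n <- check_obs_sequences(obs_sequences)
  x0 <- as.numeric(x0)
  est <- matrix(NA_real_, n, 2L)
  iters <- integer(n); conv <- logical(n); lp <- numeric(n)
  sig_r <- numeric(n); sig_phi <- numeric(n)
  timing <- c(fuse = 0, init = 0, ascend = 0)
  sig <- list(r2 = step_template$sigma_r^2, phi2 = step_template$sigma_phi^2,
              floor_r2 = step_template$sigma_r^2,
              floor_phi2 = step_template$sigma_phi^2)
  prev <- x0; prev2 <- NULL
  for (k in seq_len(n)) {
    obs_k <- Filter(Negate(is.null),
                    lapply(obs_sequences, function(s) s[[k]]))
    stepk <- step_model_params(step_template$r_bar, step_template$phi_bar,
                               sqrt(sig$r2), sqrt(sig$phi2))
    res <- mff_step(prev, prev2, stepk, obs_k, cfg)
    est[k, ] <- res$mode
    iters[k] <- res$iterations
    conv[k] <- res$converged
    lp[k] <- res$log_posterior_at_mode
    sig_r[k] <- sqrt(sig$r2); sig_phi[k] <- sqrt(sig$phi2)
    timing <- timing + res$timing
    if (adapt && length(obs_k) > 0L) {
      sig <- adapt_step_variances(sig, fuse_observations(obs_k)$mean, prev,
                                  step_template$r_bar, res$phi_bar,
                                  adapt_rate)
    }
    prev2 <- prev
    prev <- res$mode
  }
  structure(list(estimates = est, x0 = x0,
                 diagnostics = data.frame(step = seq_len(n),
                                          iterations = iters,
                                          converged = conv,
                                          log_posterior = lp,
                                          sigma_r = sig_r,
                                          sigma_phi = sig_phi),
                 timing = timing, method = "mff"),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Filter result (", x$method, "): ", nrow(x$estimates), " steps\n",
    sep = "")
  if (!is.null(x$rmse)) cat("  RMSE vs truth:", signif(x$rmse, 5), "m\n")
  cat("  stage seconds:",
      paste(names(x$timing), signif(unname(x$timing), 3), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}
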