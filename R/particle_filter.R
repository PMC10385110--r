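#' Particle set
#'
#' State belief of the baseline sequential importance resampling particle
#' filter: particle positions with normalized nonnegative weights.
#'
#' @param positions n x 2 numeric matrix of particle positions, meters.
#' @param weights numeric vector of n nonnegative weights summing to 1
#'   (within 1e-9).
#' @return object of class `"particle_set"`.
#' @export
particle_set <- function(positions, weights) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || nrow(positions) < 1L ||
      any(!is.finite(positions))) {
    stop("particle_set: 'positions' must be a finite n x 2 matrix, n >= 1")
  }
  weights <- as.numeric(weights)
  if (length(weights) != nrow(positions) || any(!is.finite(weights)) ||
      any(weights < 0)) {
    stop("particle_set: 'weights' must be nonnegative, one per particle")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("particle_set: weights must sum to 1 (got ", sum(weights), ")")
  }
  structure(list(positions = positions, weights = weights),
            class = "particle_set")
}

#' Initialize particles at a known position
#'
#' The initial belief is a delta prior: all particles start at `x0` with
#' equal weights 1/n.
#'
#' @param x0 initial position, numeric 2-vector.
#' @param n number of particles, >= 1.
#' @return a [particle_set()].
#' @export
pf_init <- function(x0, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("pf_init: 'n' must be >= 1")
  x0 <- as.numeric(x0)
  particle_set(matrix(rep(x0, each = n), n, 2L), rep(1 / n, n))
}

#' Propagate particles through the step model
#'
#' Each particle is displaced by an independently sampled polar step
#' `(r, phi) ~ N((r_bar, phi_bar), diag(sigma_r^2, sigma_phi^2))`; the
#' weights are left untouched. Uses the ambient RNG stream.
#'
#' @param ps a [particle_set()].
#' @param step a [step_model_params()] object.
#' @return the propagated [particle_set()].
#' @export
pf_predict <- function(ps, step) {
  stopifnot(inherits(ps, "particle_set"), inherits(step, "step_model_params"))
  n <- nrow(ps$positions)
  r <- stats::rnorm(n, step$r_bar, step$sigma_r)
  phi <- stats::rnorm(n, step$phi_bar, step$sigma_phi)
  ps$positions <- ps$positions + cbind(r * cos(phi), r * sin(phi))
  ps
}

#' Reweight particles by an observation likelihood
#'
#' Multiplies each weight by the Gaussian observation likelihood evaluated at
#' the particle's position and renormalizes. Computed in log space so that
#' only a total collapse of all particles triggers an error.
#'
#' @param ps a [particle_set()].
#' @param obs a Cartesian [gaussian_belief()].
#' @return the reweighted [particle_set()].
#' @export
pf_weight <- function(ps, obs) {
  stopifnot(inherits(ps, "particle_set"))
  lw <- log(ps$weights) + gaussian_logpdf(ps$positions, obs)
  m <- max(lw)
  if (!is.finite(m)) {
    stop("pf_weight: all particle likelihoods underflowed; ",
         "resample more often or rescale the observation covariance")
  }
  w <- exp(lw - m)
  ps$weights <- w / sum(w)
  ps
}

#' Systematic resampling
#'
#' Low-variance resampling: a single uniform offset `u ~ U(0, 1/n)` places n
#' evenly spaced points on the cumulative weight axis; particle i is copied
#' once per point falling in its weight segment, so its copy count is always
#' within 1 of `n * w_i`. Weights are reset to 1/n.
#'
#' @param ps a [particle_set()].
#' @param u optional fixed offset in `[0, 1/n)` (for deterministic use);
#'   drawn from the ambient RNG when `NULL`.
#' @return the resampled [particle_set()] with equal weights.
#' @export
systematic_resample <- function(ps, u = NULL) {
  stopifnot(inherits(ps, "particle_set"))
  n <- nrow(ps$positions)
  if (is.null(u)) u <- stats::runif(1) / n
  if (!is.finite(u) || u < 0 || u >= 1 / n) {
    stop("systematic_resample: 'u' must lie in [0, 1/n)")
  }
  pts <- u + (seq_len(n) - 1) / n
  cw <- cumsum(ps$weights)
  cw <- cw / cw[n]  # pin the last segment to 1 without breaking monotonicity
  idx <- findInterval(pts, cw, left.open = TRUE) + 1L
  particle_set(ps$positions[idx, , drop = FALSE], rep(1 / n, n))
}

#' Effective sample size of a particle set
#'
#' `1 / sum(w_i^2)`, in `[1, n]`: n for uniform weights, 1 when a single
#' particle carries all weight. Standard degeneracy diagnostic.
#'
#' @param ps a [particle_set()].
#' @return scalar effective sample size.
#' @export
effective_sample_size <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  1 / sum(ps$weights^2)
}

#' Point estimate from a particle set
#'
#' Weighted mean of the particle positions.
#'
#' @param ps a [particle_set()].
#' @return numeric position 2-vector.
#' @export
pf_estimate <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  as.numeric(colSums(ps$positions * ps$weights))
}

#' Run the baseline particle filter over a walk
#'
#' Sequential importance resampling with the same step model and fused
#' Gaussian observation likelihoods as the mode-finding filter. Each step:
#' predict, fuse the available observations, weight, resample (every
#' `resample_every` steps, or when the effective sample size drops below
#' `ess_threshold` if given), then record the weighted-mean estimate. The
#' expected heading is adapted from the filter's own two previous estimates.
#' Uses the ambient RNG stream; seed it for reproducibility.
#'
#' @inheritParams run_mff
#' @param n_particles number of particles (default 1000).
#' @param resample_every resample cadence in steps (default 1, i.e. every
#'   step); ignored when `ess_threshold` is given.
#' @param ess_threshold optional effective-sample-size trigger: resample only
#'   when ESS falls below this value.
#' @return a `"filter_result"` (see [run_mff()]) with per-step ESS
#'   diagnostics and `method = "pf"`.
#' @export
run_pf <- function(obs_sequences, step_template, n_particles = 1000,
                   resample_every = 1L, ess_threshold = NULL, x0 = c(0, 0),
                   adapt = TRUE, adapt_rate = 0.05) {
  stopifnot(inherits(step_template, "step_model_params"))
  n <- check_obs_sequences(obs_sequences)
  x0 <- as.numeric(x0)
  t0 <- proc.time()[["elapsed"]]
  ps <- pf_init(x0, n_particles)
  timing <- c(init = proc.time()[["elapsed"]] - t0,
              predict = 0, weight = 0, resample = 0, estimate = 0)
  est <- matrix(NA_real_, n, 2L)
  ess <- numeric(n)
  sig <- list(r2 = step_template$sigma_r^2, phi2 = step_template$sigma_phi^2,
              floor_r2 = step_template$sigma_r^2,
              floor_phi2 = step_template$sigma_phi^2)
  prev <- x0; prev2 <- NULL
  for (k in seq_len(n)) {
    phi_bar <- update_heading(prev, prev2, fallback = step_template$phi_bar)
    stepk <- step_model_params(step_template$r_bar, phi_bar,
                               sqrt(sig$r2), sqrt(sig$phi2))
    t1 <- proc.time()[["elapsed"]]
    ps <- pf_predict(ps, stepk)
    t2 <- proc.time()[["elapsed"]]
    obs_k <- Filter(Negate(is.null),
                    lapply(obs_sequences, function(s) s[[k]]))
    if (length(obs_k) > 0L) {
      obs_fused <- fuse_observations(obs_k)
      ps <- pf_weight(ps, obs_fused)
      if (adapt) {
        sig <- adapt_step_variances(sig, obs_fused$mean, prev,
                                    step_template$r_bar, phi_bar,
                                    adapt_rate)
      }
    }
    t3 <- proc.time()[["elapsed"]]
    ess[k] <- effective_sample_size(ps)
    do_resample <- if (!is.null(ess_threshold)) {
      ess[k] < ess_threshold
    } else {
      k %% resample_every == 0L
    }
    if (do_resample && length(obs_k) > 0L) {
      ps <- systematic_resample(ps)
    }
    t4 <- proc.time()[["elapsed"]]
    est[k, ] <- pf_estimate(ps)
    t5 <- proc.time()[["elapsed"]]
    timing <- timing + c(init = 0, predict = t2 - t1, weight = t3 - t2,
                         resample = t4 - t3, estimate = t5 - t4)
    prev2 <- prev
    prev <- est[k, ]
  }
  structure(list(estimates = est, x0 = x0,
                 diagnostics = data.frame(step = seq_len(n), ess = ess),
                 timing = timing, method = "pf"),
            class = "filter_result")
}
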