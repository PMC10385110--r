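# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; seeds are fixed by the calling tests.

# random SPD 2x2 with moderate conditioning
random_spd <- function(scale = 1) {
  a <- matrix(stats::rnorm(4), 2, 2)
  S <- a %*% t(a) + diag(stats::runif(1, 0.3, 1), 2)
  S * scale
}

# random single-step estimation scenario: previous mode, polar step model and
# a Cartesian observation belief placed near the predicted position
random_scenario <- function(obs_scale = 1, sigma_max = 0.3) {
  x_prev <- stats::runif(2, -5, 5)
  step <- step_model_params(r_bar = stats::runif(1, 0.4, 0.9),
                            phi_bar = stats::runif(1, -pi, pi),
                            sigma_r = stats::runif(1, 0.05, sigma_max),
                            sigma_phi = stats::runif(1, 0.05, sigma_max))
  pred <- x_prev + step$r_bar * c(cos(step$phi_bar), sin(step$phi_bar))
  obs <- gaussian_belief(pred + stats::runif(2, -1, 1),
                         random_spd(obs_scale))
  list(x_prev = x_prev, step = step, obs = obs)
}

# central finite differences of a scalar field on R^2
fd_gradient <- function(f, x, h = 1e-6) {
  c((f(x + c(h, 0)) - f(x - c(h, 0))) / (2 * h),
    (f(x + c(0, h)) - f(x - c(0, h))) / (2 * h))
}

# dense grid argmax of the unnormalized log posterior over a window centered
# on the linearized-fusion mean, half-width 4 fused sds; returns the argmax
# and the grid cell width
grid_argmax <- function(x_prev, step, obs, n_grid = 400L) {
  fused <- fuse_gaussians(linearized_prediction(x_prev, step), obs)
  half <- 4 * sqrt(max(diag(fused$cov)))
  gx <- seq(fused$mean[1] - half, fused$mean[1] + half, length.out = n_grid)
  gy <- seq(fused$mean[2] - half, fused$mean[2] + half, length.out = n_grid)
  pts <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  lp <- posterior_log_unnorm(pts, x_prev, step, obs)
  list(argmax = pts[which.max(lp), ], cell = gx[2] - gx[1],
       values = lp, pts = pts)
}

# tiny scenario configuration for fast end-to-end runs
small_config <- function(n_steps = 100, seed = 1, ...) {
  scenario_config(n_steps = n_steps, seed = seed, n_particles = 200L, ...)
}
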