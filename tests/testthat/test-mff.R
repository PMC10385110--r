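test_that("log posterior decomposes into transition plus observation terms", {
  set.seed(21)
  sc <- random_scenario()
  xs <- matrix(stats::runif(20, -1, 1), 10, 2) +
    matrix(sc$obs$mean, 10, 2, byrow = TRUE)
  lp <- posterior_log_unnorm(xs, sc$x_prev, sc$step, sc$obs)
  ref <- transition_log_unnorm(xs, sc$x_prev, sc$step) +
    gaussian_logpdf(xs, sc$obs)
  # equal up to the dropped normalization constants
  expect_equal(diff(lp - ref), rep(0, 9), tolerance = 1e-10)
})

test_that("posterior argmax collapses to the dominant information source", {
  set.seed(22)
  sc <- random_scenario()
  pred_mode <- sc$x_prev +
    sc$step$r_bar * c(cos(sc$step$phi_bar), sin(sc$step$phi_bar))
  # observation made non-informative: mode is the transition mode
  wide <- gaussian_belief(sc$obs$mean, sc$obs$cov * 1e12)
  g <- grid_argmax(sc$x_prev, sc$step, wide)
  expect_lt(max(abs(g$argmax - pred_mode)), 2 * g$cell)
  # step model made non-informative: mode is the observation mean
  vague_step <- step_model_params(sc$step$r_bar, sc$step$phi_bar,
                                  sc$step$sigma_r * 1e6,
                                  sc$step$sigma_phi * 1e6)
  g2 <- grid_argmax(sc$x_prev, vague_step, sc$obs)
  expect_lt(max(abs(g2$argmax - sc$obs$mean)), 2 * g2$cell)
})

test_that("analytic posterior gradient matches central finite differences", {
  set.seed(23)
  for (i in 1:100) {
    sc <- random_scenario()
    x <- sc$obs$mean + stats::runif(2, -0.5, 0.5)
    g <- posterior_gradient(x, sc$x_prev, sc$step, sc$obs)
    fd <- fd_gradient(function(z) posterior_log_unnorm(z, sc$x_prev,
                                                       sc$step, sc$obs), x)
    expect_equal(g, fd, tolerance = 1e-4)
  }
})

test_that("gradient vanishes at the mode and in the observation-dominated limit", {
  set.seed(24)
  sc <- random_scenario()
  g <- grid_argmax(sc$x_prev, sc$step, sc$obs)
  grad <- posterior_gradient(g$argmax, sc$x_prev, sc$step, sc$obs)
  # argmax is quantized to the grid; gradient norm is bounded by the local
  # curvature times one cell
  expect_lt(sqrt(sum(grad^2)), 1)
  # tight observation pins the mode at its mean
  tight <- gaussian_belief(sc$obs$mean, diag(1e-8, 2))
  grad2 <- posterior_gradient(sc$obs$mean, sc$x_prev, sc$step, tight)
  expect_lt(sqrt(sum(grad2^2)) * 1e-8, 1e-6)
})

test_that("the ascent initializer is the information-form fusion mean", {
  set.seed(25)
  sc <- random_scenario()
  pred <- linearized_prediction(sc$x_prev, sc$step)
  # independent solve of the normal equations
  P1 <- solve(pred$cov); P2 <- solve(sc$obs$cov)
  ref <- solve(P1 + P2, P1 %*% pred$mean + P2 %*% sc$obs$mean)
  expect_equal(initial_guess(sc$x_prev, sc$step, sc$obs), as.numeric(ref),
               tolerance = 1e-10)
  # identical belief and observation share the fused mean
  same <- gaussian_belief(pred$mean, pred$cov)
  expect_equal(initial_guess(sc$x_prev, sc$step, same), pred$mean,
               tolerance = 1e-10)
  # non-informative observation returns the linearized prediction mean
  wide <- gaussian_belief(c(100, 100), diag(1e12, 2))
  expect_equal(initial_guess(sc$x_prev, sc$step, wide), pred$mean,
               tolerance = 1e-4)
})

test_that("gradient ascent solves a quadratic and stops immediately at a mode", {
  b <- gaussian_belief(c(2, -1), matrix(c(1.5, 0.4, 0.4, 0.8), 2, 2))
  # a flat quadratic converges geometrically at rate (1 - delta/lambda_max);
  # give the fixed small step enough iterations
  res <- gradient_ascent(function(x) gaussian_logpdf(x, b),
                         function(x) -solve(b$cov, x - b$mean),
                         x0 = c(-3, 4), cfg = mff_config(max_iter = 5000L))
  expect_true(res$converged)
  expect_equal(res$mode, b$mean, tolerance = 1e-4)
  at_mode <- gradient_ascent(function(x) gaussian_logpdf(x, b),
                             function(x) -solve(b$cov, x - b$mean),
                             x0 = b$mean, cfg = mff_config())
  expect_true(at_mode$converged)
  expect_identical(at_mode$iterations, 1L)
})

test_that("ascent from the initializer reaches the grid-search mode and never loses ground", {
  set.seed(26)
  cfg <- mff_config(max_iter = 1000L)
  for (i in 1:15) {
    sc <- random_scenario()
    x0 <- initial_guess(sc$x_prev, sc$step, sc$obs)
    res <- gradient_ascent(
      function(x) posterior_log_unnorm(x, sc$x_prev, sc$step, sc$obs),
      function(x) posterior_gradient(x, sc$x_prev, sc$step, sc$obs),
      x0, cfg)
    g <- grid_argmax(sc$x_prev, sc$step, sc$obs)
    expect_lt(max(abs(res$mode - g$argmax)), 1.5 * g$cell)
    expect_gte(res$value,
               posterior_log_unnorm(x0, sc$x_prev, sc$step, sc$obs))
  }
})

test_that("log-space and density-space ascent agree on the mode", {
  set.seed(27)
  for (i in 1:10) {
    sc <- random_scenario(obs_scale = 0.5)
    obs_k <- list(sc$obs)
    r_log <- mff_step(sc$x_prev, NULL, sc$step, obs_k,
                      mff_config(ascent_space = "log-density"))
    r_den <- mff_step(sc$x_prev, NULL, sc$step, obs_k,
                      mff_config(ascent_space = "density", max_iter = 5000L))
    expect_lt(sqrt(sum((r_log$mode - r_den$mode)^2)), 2e-3)
  }
})

test_that("the fused posterior is unimodal for moderate direction spread", {
  set.seed(28)
  for (i in 1:20) {
    sc <- random_scenario(sigma_max = 0.3)
    g <- grid_argmax(sc$x_prev, sc$step, sc$obs, n_grid = 200L)
    mx <- max(g$values)
    near <- g$pts[g$values > mx - 1e-6, , drop = FALSE]
    # all near-maximal cells cluster around a single location
    expect_lt(max(dist(rbind(near, g$argmax))), 3 * g$cell)
  }
})

test_that("a filter step handles both sensors, one sensor, and dropout", {
  set.seed(29)
  sc <- random_scenario()
  pred_mode <- sc$x_prev +
    sc$step$r_bar * c(cos(sc$step$phi_bar), sin(sc$step$phi_bar))
  # no observations: prediction-only fallback
  r0 <- mff_step(sc$x_prev, NULL, sc$step, list())
  expect_equal(r0$mode, pred_mode)
  expect_identical(r0$iterations, 0L)
  # a second identical belief must not move the mode (fusion of b with b
  # halves the covariance but keeps the mean)
  r1 <- mff_step(sc$x_prev, NULL, sc$step, list(sc$obs))
  half <- gaussian_belief(sc$obs$mean, sc$obs$cov / 2)
  r1b <- mff_step(sc$x_prev, NULL, sc$step, list(half))
  r2 <- mff_step(sc$x_prev, NULL, sc$step, list(sc$obs, sc$obs))
  expect_equal(r2$mode, r1b$mode, tolerance = 1e-6)
  # fusion order does not matter
  b2 <- gaussian_belief(sc$obs$mean + c(0.3, -0.2), random_spd())
  ra <- mff_step(sc$x_prev, NULL, sc$step, list(sc$obs, b2))
  rb <- mff_step(sc$x_prev, NULL, sc$step, list(b2, sc$obs))
  expect_equal(ra$mode, rb$mode, tolerance = 1e-8)
  expect_true(r1$converged)
})

test_that("the filter reproduces a noiseless walk and matches its own single step", {
  cfg <- scenario_config(n_steps = 40, seed = 2,
                         sigma_r_true = 0, sigma_phi_true = 0)
  sim <- simulate_scenario(cfg)
  truth_pts <- sim$truth$trajectory[-1, ]
  obs <- lapply(seq_len(40), function(k) {
    gaussian_belief(truth_pts[k, ], diag(1e-6, 2))
  })
  res <- run_mff(list(gps = obs), sim$step_template)
  expect_lt(rmse(res$estimates, truth_pts), 1e-4)
  # one-step sequence equals a direct mff_step call
  one <- run_mff(list(gps = obs[1]), sim$step_template)
  direct <- mff_step(c(0, 0), NULL, sim$step_template, list(obs[[1]]))
  expect_equal(one$estimates[1, ], direct$mode)
  # misaligned streams are rejected
  expect_error(run_mff(list(gps = obs, imu = obs[1:10]), sim$step_template),
               "misaligned")
})

test_that("a baseline walk stays bounded under the filter", {
  cfg <- small_config(n_steps = 400, seed = 4)
  sim <- simulate_scenario(cfg)
  res <- run_mff(list(gps = sim$gps$beliefs, imu = sim$imu$beliefs),
                 sim$step_template, cfg$mff)
  err <- rmse(res$estimates, sim$truth$trajectory[-1, ])
  expect_true(is.finite(err))
  # bounded below the unaided dead-reckoning drift of the walk
  imu_err <- rmse(sim$imu$track[-1, ], sim$truth$trajectory[-1, ])
  expect_lt(err, imu_err)
  # iteration budget is respected; when the posterior ridge is a flat arc
  # (large adapted direction spread) the budget may run out, but the
  # returned mode must still be a proper ascent from its initializer
  expect_true(all(res$diagnostics$iterations <= cfg$mff$max_iter))
  expect_true(all(is.finite(res$diagnostics$log_posterior)))
})
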