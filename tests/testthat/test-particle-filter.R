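test_that("particle initialization places a delta prior with equal weights", {
  ps <- pf_init(c(1, 2), 4)
  expect_equal(ps$weights, rep(0.25, 4))
  expect_true(all(ps$positions[, 1] == 1) && all(ps$positions[, 2] == 2))
  expect_equal(sum(ps$weights), 1)
  single <- pf_init(c(0, 0), 1)
  expect_equal(single$weights, 1)
  expect_error(pf_init(c(0, 0), 0), ">= 1")
})

test_that("prediction propagates particles by sampled polar steps", {
  step0 <- step_model_params(0.7, pi / 3, 1e-12, 1e-12)
  ps <- pf_init(c(1, 1), 50)
  moved <- pf_predict(ps, step0)
  shift <- 0.7 * c(cos(pi / 3), sin(pi / 3))
  expect_equal(moved$positions,
               ps$positions + matrix(shift, 50, 2, byrow = TRUE),
               tolerance = 1e-9)
  expect_identical(moved$weights, ps$weights)
  # moment oracle against the linearized mean (small spreads, where the
  # linearization bias ~ r_bar * sigma_phi^2 / 2 is below the Monte Carlo
  # resolution)
  set.seed(31)
  step <- step_model_params(0.7, 0.9, 0.01, 0.01)
  big <- pf_predict(pf_init(c(0, 0), 1e5), step)
  lp <- linearized_prediction(c(0, 0), step)
  mc_se <- sqrt(diag(lp$cov) / 1e5)
  expect_true(all(abs(colMeans(big$positions) - lp$mean) < 3 * mc_se + 1e-4))
})

test_that("weighting follows the Gaussian likelihood and renormalizes", {
  obs <- gaussian_belief(c(0, 0), diag(2))
  sym <- particle_set(rbind(c(1, 0), c(-1, 0)), c(0.5, 0.5))
  w <- pf_weight(sym, obs)
  expect_equal(w$weights, c(0.5, 0.5))
  pair <- particle_set(rbind(c(0, 0), c(1, 0)), c(0.5, 0.5))
  w2 <- pf_weight(pair, obs)
  expect_equal(w2$weights[1] / w2$weights[2], exp(0.5), tolerance = 1e-12)
  expect_equal(sum(w2$weights), 1)
  # moderately distant particles survive through the log-space max shift
  mid <- particle_set(rbind(c(1e3, 0), c(1e3 + 1, 0)), c(0.5, 0.5))
  expect_equal(sum(pf_weight(mid, obs)$weights), 1)
  # a total collapse of every likelihood is reported as underflow
  far <- particle_set(rbind(c(1e200, 0), c(2e200, 0)), c(0.5, 0.5))
  expect_error(pf_weight(far, obs), "underflow")
})

test_that("systematic resampling has copy counts within one of expectation", {
  # all mass on one particle: n copies of it
  ps <- particle_set(rbind(c(1, 1), c(2, 2), c(3, 3)), c(0, 1, 0))
  rs <- systematic_resample(ps, u = 0.1)
  expect_true(all(rs$positions[, 1] == 2))
  expect_equal(rs$weights, rep(1 / 3, 3))
  # uniform weights: each particle appears exactly once
  psu <- particle_set(cbind(1:4, 1:4), rep(0.25, 4))
  rsu <- systematic_resample(psu, u = 0.13)
  expect_equal(sort(rsu$positions[, 1]), as.numeric(1:4))
  # toy weight vector: exhaustively over offsets the counts are (2, 1, 1)
  w <- c(0.5, 0.25, 0.25)
  psw <- particle_set(cbind(1:3, 0), c(w, 0)[1:3])
  for (u in seq(1e-6, 1 / 3 - 1e-6, length.out = 25)) {
    # n = 4 points over 3 particles requires a 4-particle set
    ps4 <- particle_set(cbind(c(1, 2, 3, 4), 0), c(0.5, 0.25, 0.25, 0))
    rs4 <- systematic_resample(ps4, u = u / 4 * 3)  # keep u in [0, 1/4)
    counts <- tabulate(rs4$positions[, 1], nbins = 4)
    expect_equal(counts, c(2, 1, 1, 0))
  }
  # random weights: counts always within 1 of n * w
  set.seed(33)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    w <- stats::runif(n); w <- w / sum(w)
    ps <- particle_set(cbind(seq_len(n), 0), w)
    rs <- systematic_resample(ps, u = stats::runif(1) / n)
    counts <- tabulate(rs$positions[, 1], nbins = n)
    expect_true(all(abs(counts - n * w) < 1 + 1e-9))
  }
})

test_that("effective sample size spans [1, n] as weights degenerate", {
  n <- 6
  uni <- particle_set(cbind(1:n, 0), rep(1 / n, n))
  expect_equal(effective_sample_size(uni), n)
  deg <- particle_set(cbind(1:n, 0), c(1, rep(0, n - 1)))
  expect_equal(effective_sample_size(deg), 1)
  half <- particle_set(cbind(1:4, 0), c(0.5, 0.5, 0, 0))
  expect_equal(effective_sample_size(half), 2)
  # ESS after resampling is restored to n
  set.seed(34)
  w <- stats::runif(20); w <- w / sum(w)
  rs <- systematic_resample(particle_set(cbind(1:20, 0), w), u = 0.01)
  expect_equal(effective_sample_size(rs), 20)
})

test_that("the point estimate is the weighted particle mean", {
  expect_equal(pf_estimate(particle_set(rbind(c(3, -2)), 1)), c(3, -2))
  expect_equal(pf_estimate(particle_set(rbind(c(1, 0), c(-1, 4)),
                                        c(0.5, 0.5))), c(0, 2))
  expect_equal(pf_estimate(particle_set(rbind(c(1, 1), c(5, -3)),
                                        c(0.75, 0.25))), c(2, 0))
})

test_that("resampling preserves the weighted mean in expectation", {
  set.seed(35)
  n <- 30
  pos <- cbind(stats::rnorm(n), stats::rnorm(n))
  w <- stats::runif(n); w <- w / sum(w)
  ps <- particle_set(pos, w)
  target <- pf_estimate(ps)
  reps <- t(vapply(1:1000, function(i) pf_estimate(systematic_resample(ps)),
                   numeric(2)))
  se <- apply(reps, 2, stats::sd) / sqrt(1000)
  expect_true(all(abs(colMeans(reps) - target) < 3 * se + 1e-8))
})

test_that("on a near-linear-Gaussian step the particle posterior matches the closed-form fusion", {
  set.seed(36)
  step <- step_model_params(0.7, 0.4, 0.05, 0.005)
  obs <- gaussian_belief(c(0.7 * cos(0.4) + 0.05, 0.7 * sin(0.4) - 0.03),
                         diag(c(0.04, 0.04)))
  ps <- pf_weight(pf_predict(pf_init(c(0, 0), 1e4), step), obs)
  closed <- fuse_gaussians(linearized_prediction(c(0, 0), step), obs)
  mc_se <- sqrt(diag(closed$cov)) / sqrt(effective_sample_size(ps))
  expect_true(all(abs(pf_estimate(ps) - closed$mean) < 3 * mc_se + 0.01))
})

test_that("the particle filter reproduces a noiseless walk and stays near the truth", {
  cfg <- scenario_config(n_steps = 40, seed = 2,
                         sigma_r_true = 0, sigma_phi_true = 0)
  sim <- simulate_scenario(cfg)
  truth_pts <- sim$truth$trajectory[-1, ]
  obs <- lapply(seq_len(40), function(k) {
    gaussian_belief(truth_pts[k, ], diag(1e-6, 2))
  })
  set.seed(1)
  res <- run_pf(list(gps = obs), sim$step_template, n_particles = 300)
  expect_lt(rmse(res$estimates, truth_pts), 0.05)
  # baseline run is bounded and carries ESS diagnostics
  cfg2 <- small_config(n_steps = 300, seed = 6)
  sim2 <- simulate_scenario(cfg2)
  set.seed(2)
  res2 <- run_pf(list(gps = sim2$gps$beliefs, imu = sim2$imu$beliefs),
                 sim2$step_template, n_particles = 200)
  expect_true(is.finite(rmse(res2$estimates, sim2$truth$trajectory[-1, ])))
  expect_true(all(res2$diagnostics$ess >= 1 &
                  res2$diagnostics$ess <= 200 + 1e-9))
})
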