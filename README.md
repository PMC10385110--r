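# gaitmff

Walking trajectory estimation by fusing wearable-sensor streams with a
probabilistic gait step model.

## The problem

A person walking outdoors can be localized from a wearable GPS (noisy,
drift-free fixes) and a foot-mounted IMU whose zero-velocity-update step
estimates are precise per step but drift when dead-reckoned. gaitmff fuses
both with a motion model built from gait kinematics: the length and
direction of a step are bivariate normal in polar coordinates,

    (r_k, phi_k) ~ N((r_bar, phi_bar), diag(sigma_r^2, sigma_phi^2)),

with the mean step length derived from leg segment lengths and stance-phase
hip/knee angles,

    r_bar = c1*l_l*[sin(th_he + th_ke) + sin(th_hf - th_kf)]
          + c2*l_u*[sin(th_he) + sin(th_hf)].

Because the polar-to-Cartesian map is nonlinear, the per-step posterior over
position is non-Gaussian. The package's estimator — a **mode-finding filter
(MFF)** — condenses that posterior to its mode each step by gradient ascent
on the unnormalized log posterior, seeded by a closed-form Gaussian fusion
of the linearized prediction with the observations. A systematic-resampling
**particle filter** with the identical step model and observation
likelihoods serves as the reference non-Gaussian estimator, and a scenario
simulator plus Monte Carlo evaluation harness compares sensor/filter
combinations by RMSE. It is aimed at researchers in pedestrian navigation
and gait biomechanics who want a cheap MAP-type alternative to particle
filtering.

## Worked example

Simulate a 1000-step walk (sinusoidal heading, kinematic step lengths,
characterized GPS/IMU noise) and compare the raw GPS track with the
filtered estimates:

```r
library(gaitmff)

cfg <- scenario_config(n_steps = 1000, seed = 7)
sim <- simulate_scenario(cfg)

gps <- run_combination(cfg, "gps", "none", sim = sim)
mff <- run_combination(cfg, "gps", "mff",  sim = sim)
pf  <- run_combination(cfg, "gps", "pf",   sim = sim)

cat(sprintf("raw GPS : %.3f m\nGPS+MFF : %.3f m\nGPS+PF  : %.3f m\n",
            gps$rmse, mff$rmse, pf$rmse))
#> raw GPS : 6.742 m
#> GPS+MFF : 4.927 m
#> GPS+PF  : 4.463 m
```

The raw GPS error is set by its ~22 m² fix covariance; the step model
smooths it down by roughly a third, and the particle filter — which carries
the full non-Gaussian belief instead of a single mode — is slightly more
accurate still. `run_combination` accepts any subset of
`c("imu", "gps")` with `filter` one of `"none"`, `"mff"`, `"pf"`;
`sweep_noise_grid()` runs the full sensor/filter grid over IMU/GPS noise
scales and `sweep_resolution()` trades particle count and ascent step size
against runtime.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/gaitmff.R run --sensors gps,imu --filter mff \
    --steps 1000 --seed 7 --out out/
Rscript inst/cli/gaitmff.R sweep-grid --config scenario.yaml --seed 1 --out out/
```

writing estimates/diagnostics CSV, a JSON summary, optional GPX tracks, and
sweep tables. Scenario YAML keys mirror `scenario_config()`.

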