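---
title: "Walking trajectory estimation with a mode-finding filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking trajectory estimation with a mode-finding filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmff)
```

## The estimation problem

gaitmff estimates the 2D trajectory of a walking person, step by step, from
two imperfect sensor streams: a wearable GPS that delivers noisy but
drift-free position fixes, and a foot-mounted IMU whose zero-velocity-update
(ZUPT) step estimates are locally precise but accumulate error when
dead-reckoned. The state is the walker's position $x_k = (x_k, y_k)^\top$ in
a local east–north frame anchored at the start of the path, indexed by the
physical step count $k$.

What makes the problem non-Gaussian is the motion model. A step is most
naturally described in polar coordinates — length $r$ and direction
$\phi$ — and the package models the pair as bivariate normal with
independent components,

$$\rho_k = (r_k, \phi_k)^\top \sim
  \mathcal N\!\big(\bar\rho_k,\ \mathrm{diag}(\sigma_r^2, \sigma_\phi^2)\big).$$

Mapped into the Cartesian belief space the transition density
$p(x_k \mid x_{k-1}) = \mathcal N(\rho'(x_k, x_{k-1}); \bar\rho_k, \Sigma_\rho)$
(with $\rho'$ the polar decomposition of the displacement) is a curved,
banana-shaped distribution: Gaussian filters cannot represent it, and a
particle filter is the usual — but expensive — resort.

## The mode-finding filter

The mode-finding filter (MFF) is a maximum-a-posteriori recursion that keeps
only the posterior mode at each step:

1. **Prediction.** Because the previous belief has been condensed to a point
   $\hat x_{k-1}$ (a delta prior), the predicted density is just the step
   model centered there.
2. **Observation fusion.** Each available sensor contributes a Gaussian
   likelihood (`gaussian_belief`); several are fused in closed information
   form, $\Sigma^{-1} = \sum_i \Sigma_i^{-1}$ — commutative and associative,
   so sensor order is irrelevant (`fuse_gaussians`).
3. **Correction and mode finding.** The unnormalized log posterior is
   $-\tfrac12[(\rho'-\bar\rho)^\top \Sigma_\rho^{-1}(\rho'-\bar\rho)
   + (x-\bar x)^\top \Sigma_x^{-1} (x-\bar x)]$, with the angular residual
   wrapped into $(-\pi, \pi]$. Its analytic gradient
   (`posterior_gradient`) uses the exact Jacobian of the polar map; the mode
   is found by fixed-step gradient ascent seeded by the
   linearized-prediction/observation fusion mean (`initial_guess`).
4. **Model update.** The expected step direction $\bar\phi_k$ is set to the
   direction of the previously estimated step; the step-model spreads are
   adapted online (below).

The expected step length is not a free parameter: it comes from a planar
double-stance kinematic model of gait,
$\bar r = c_1 l_l[\sin(\theta_{he}+\theta_{ke}) + \sin(\theta_{hf}-\theta_{kf})]
        + c_2 l_u[\sin\theta_{he} + \sin\theta_{hf}]$,
with the leg segment lengths and stance angles as inputs
(`mean_step_size`). The default per-term multipliers are $c_1 = c_2 = 1$,
which yields ~0.5–0.8 m steps for adult anthropometry; the geometry admits a
$(2, 2)$ reading, selectable through the `coeff` argument, and we chose not
to hard-code either. The default hip-angle range of 39.2°, split evenly
between extension and flexion, follows published motion-capture statistics
of healthy gait; the knee stance angles (8° extension side, 15° flexion
side) and the leg-length population (upper 0.44 m, lower 0.43 m, sd 0.02 m,
truncated positive) are population stand-ins chosen once from standard
anthropometry tables — no authoritative per-subject statistics were
available to us.

## Numerical choices in the ascent

Equation-level gradient ascent on a *density* whose values vary over many
orders of magnitude makes the step size scale-dependent, so by default the
package ascends the **log** posterior, which has the same mode
(`mff_config(ascent_space = "density")` restores density-space ascent; a
property test confirms both land on the same mode). The nominal step size
$\delta = 2^{-4}$ is kept constant — no line search — but a step that would
*decrease* the objective is rejected and $\delta$ halved, which guarantees
the returned mode is never worse than the initializer. Convergence is
declared when the accepted update norm falls below `tol` (default $10^{-6}$
m) or when the gradient is so small that even a nominal step could not move
that far. With the fused-Gaussian initializer, typical steps converge in
5–30 iterations. One known regime is slow: when the adapted direction spread
approaches ~2 rad the transition density degenerates toward a ring and the
posterior ridge becomes a nearly flat arc; the 200-iteration default budget
can then expire with residual motion of a few millimeters — irrelevant
against meter-scale observation noise, but visible as `converged = FALSE` in
the diagnostics.

Degenerate geometry is handled explicitly: a zero displacement has no
defined direction, so the polar map flags it and the Jacobian refuses
distances below $10^{-9}$ m; the ascent initializer is nudged off the
singular point if fusion ever lands exactly on the previous mode.

## Online adaptation of the step-model spreads

The step-direction mean is adapted every step, and the spreads
$\sigma_r, \sigma_\phi$ are *learned online* rather than fixed: after each
step the polar innovation between the fused observation (seen from the
previous estimate) and the model step feeds exponentially weighted variance
estimates (rate 0.05), floored at the configured baselines (0.1 m, 0.1
rad). This matters structurally: because the MFF condenses belief to a
point, its per-step prediction variance never accumulates, and with fixed
baseline spreads the correction gain against a ~22 m² GPS covariance would
be ~10⁻⁴ per step — the filter would free-run in a straight line and ignore
the sensors. The innovation adaptation lets the model's confidence find the
level the data supports; with it, the filter tracks the path and the
single-sensor estimates improve over the raw streams. Both filters share the
rule (the model is updated identically for the particle filter), and
`adapt = FALSE` restores fixed spreads. The adaptation rate and floors were
chosen once from standard exponential-weighting practice and are exposed in
the configuration.

A deliberate fidelity choice: the linearized prediction covariance used to
seed the ascent keeps zero off-diagonals even though the full first-order
propagation has cross terms; the published diagonal form is used exactly,
and only the initializer (never the posterior itself) depends on it.

## The particle-filter baseline

The comparison baseline (`run_pf`) is a sequential importance resampling
filter with the same step model and the same fused observation likelihoods:
propagate each particle by an independently sampled polar step, reweight by
the observation likelihood (computed in log space), resample systematically
every step (the lowest-variance standard scheme; an effective-sample-size
trigger is available), and report the weighted mean. The point-estimate rule
and resampling scheme are our choices — the standard ones — since the
baseline description leaves them open.

## What the simulator emulates — and what it does not

`simulate_scenario` generates a ground-truth walk from the gait model: step
lengths $\mathcal N(\bar r(\text{kin}), \sigma_{r,\text{true}})$ truncated
positive, and a heading that follows a low-frequency sinusoid
$\phi_k = \text{base} + A\sin(2\pi k/P + \text{phase}) +
\mathcal N(0, \sigma_{\phi,\text{true}})$. Defaults: 5000 steps, $A = 0.5$
rad, $P = 1000$ steps, truth noise 0.05 m / 0.05 rad — the sinusoid
parameters and truth-noise magnitudes are our one-time choices for a
"quasi-straight but non-trivial" outdoor walk; they are configuration, not
estimates of any published value.

The sensor model injects errors at the step level:

* **IMU**: each true polar step is corrupted by a constant bias
  (−0.0531 m, 0.000193 rad) and noise with the characterized polar
  covariance (diag-dominant 0.0618 m², 0.0532 rad², 0.0018 cross), then
  dead-reckoned from the known origin; the reported belief covariance grows
  linearly in the step count, $c\,k\,(J\Sigma_s J^\top)$, with $c = 1$ by
  default and $J$ the polar→Cartesian Jacobian at the measured step.
* **GPS**: one fix per step, zero bias, stationary covariance
  diag(21.846, 24.445) m²; optional dropout.

Raw (100–1000 Hz) inertial signal synthesis and strap-down integration are
*not* simulated — error is injected directly at the step level, which is the
granularity the filter consumes. Likewise there is no terrain, elevation, or
correlated GPS multipath. Passing tests therefore demonstrate the
estimator's behavior under step-level Gaussian sensor errors, not under real
sensor pathologies.

Every stochastic stream (subject kinematics, truth, IMU, GPS, particle
filter, sweep cells) draws its own seed from the scenario's master seed
through a fixed arithmetic counter scheme (`derive_seed`), so any run —
including every cell of a noise-grid sweep — is bit-identical under the same
master seed while cells remain mutually independent.

## Known limitations and observed behavior

* **Scales used in the shipped checks.** The test suite exercises the full
  nine-way sensor/filter grid at 2000 steps (and the GPS-only error
  magnitudes at the study scale of 5000 steps); unit and property tests use
  40–400 step walks. These sizes were chosen to characterize the estimators
  well while keeping the default runs quick.
* **The dead-reckoned IMU level drifts linearly** (bias × k) while its
  stated covariance grows only as √k, so at long horizons the IMU
  observation becomes inconsistent with its own covariance. Filters
  consuming it either follow the drift or ignore the sensor; the step model
  cannot repair an unbounded level bias. Consequently the IMU-only filtered
  estimate tracks the raw dead-reckoned error rather than beating it by an
  order of magnitude, and the fused GPS+IMU estimate inherits part of the
  bias at long horizons.
* **The model does not help the GPS+IMU fusion** — adding the step model to
  the already-fused pair slightly increases RMSE, a negative result the
  evaluation suite asserts rather than hides.
* **MFF vs PF**: across the grid the two estimators agree within ~10%
  RMSE, with the PF slightly ahead — it retains a full non-Gaussian belief
  where the MFF keeps one point.
* The heading update uses only the single previous estimated step, which
  produces mild oscillation of the filtered trajectory about the truth; a
  multi-step heading update would likely reduce it but is out of scope.
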