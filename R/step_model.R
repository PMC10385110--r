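#' Planar gait kinematic parameters
#'
#' Describes the sagittal-plane double-stance geometry that sets the mean step
#' length: upper- and lower-leg segment lengths plus the hip and knee angles
#' of the leading (flexion side) and trailing (extension side) legs at the
#' instant both feet are planted.
#'
#' @param l_u upper-leg (thigh) length, meters, > 0.
#' @param l_l lower-leg (shank) length, meters, > 0.
#' @param theta_he hip extension angle of the trailing leg, radians in
#'   \[0, pi/2).
#' @param theta_hf hip flexion angle of the leading leg, radians in
#'   \[0, pi/2).
#' @param theta_ke knee angle on the extension side at stance, radians in
#'   \[0, pi/2).
#' @param theta_kf knee angle on the flexion side at stance, radians in
#'   \[0, pi/2).
#' @return object of class `"kinematic_params"`.
#' @export
kinematic_params <- function(l_u, l_l, theta_he, theta_hf,
                             theta_ke = 0, theta_kf = 0) {
  vals <- c(l_u = l_u, l_l = l_l, theta_he = theta_he, theta_hf = theta_hf,
            theta_ke = theta_ke, theta_kf = theta_kf)
  if (any(!is.finite(vals))) stop("kinematic_params: non-finite input")
  if (l_u <= 0 || l_l <= 0) stop("kinematic_params: leg lengths must be > 0")
  ang <- vals[3:6]
  if (any(ang < 0) || any(ang >= pi / 2)) {
    stop("kinematic_params: stance angles must lie in [0, pi/2)")
  }
  structure(as.list(vals), class = "kinematic_params")
}

#' Mean step length from gait kinematics
#'
#' Computes the expected step length (distance between consecutive ground
#' contacts of alternating feet) from the planar double-stance geometry:
#'
#' `r_bar = c1 * l_l * (sin(theta_he + theta_ke) + sin(theta_hf - theta_kf))
#'        + c2 * l_u * (sin(theta_he) + sin(theta_hf))`
#'
#' The per-term multipliers `coeff = (c1, c2)` default to (1, 1), which gives
#' an endpoint-to-endpoint step of roughly 0.5--0.8 m for typical adult
#' anthropometry; a (2, 2) reading of the geometry can be selected through
#' `coeff` if desired.
#'
#' @param kin a [kinematic_params()] object.
#' @param coeff numeric length-2 per-term multipliers (lower-leg term,
#'   upper-leg term).
#' @return mean step length in meters (>= 0).
#' @examples
#' kin <- kinematic_params(0.45, 0.45, theta_he = 0.342, theta_hf = 0.342)
#' mean_step_size(kin)  # ~0.604 m
#' @export
mean_step_size <- function(kin, coeff = c(1, 1)) {
  stopifnot(inherits(kin, "kinematic_params"))
  coeff <- as.numeric(coeff)
  if (length(coeff) != 2L || any(!is.finite(coeff)) || any(coeff <= 0)) {
    stop("mean_step_size: 'coeff' must be two positive multipliers")
  }
  r <- coeff[1] * kin$l_l * (sin(kin$theta_he + kin$theta_ke) +
                             sin(kin$theta_hf - kin$theta_kf)) +
       coeff[2] * kin$l_u * (sin(kin$theta_he) + sin(kin$theta_hf))
  if (r < 0) {
    stop("mean_step_size: negative step length (inconsistent stance angles)")
  }
  r
}

#' Polar step-model parameters
#'
#' The step model assumes the length r and direction phi of a step are
#' jointly Gaussian in polar coordinates with independent components, so the
#' model is fully described by (r_bar, phi_bar) and (sigma_r, sigma_phi). The
#' covariance is strictly diagonal: correlation between step length and
#' direction is taken as negligible.
#'
#' @param r_bar mean step length, meters, > 0.
#' @param phi_bar mean step direction, radians (wrapped into (-pi, pi]).
#' @param sigma_r step-length standard deviation, meters, > 0.
#' @param sigma_phi step-direction standard deviation, radians, > 0.
#' @return object of class `"step_model_params"`.
#' @export
step_model_params <- function(r_bar, phi_bar, sigma_r, sigma_phi) {
  vals <- c(r_bar, phi_bar, sigma_r, sigma_phi)
  if (any(!is.finite(vals))) stop("step_model_params: non-finite input")
  if (r_bar <= 0) stop("step_model_params: 'r_bar' must be > 0")
  if (sigma_r <= 0 || sigma_phi <= 0) {
    stop("step_model_params: standard deviations must be > 0")
  }
  structure(list(r_bar = r_bar, phi_bar = wrap_angle(phi_bar),
                 sigma_r = sigma_r, sigma_phi = sigma_phi),
            class = "step_model_params")
}

#' Log transition density of the step model (Cartesian argument)
#'
#' Evaluates the polar-Gaussian step density at the polar decomposition of
#' `x - x_prev`: Gaussian in (r, phi) but non-Gaussian as a function of the
#' Cartesian position `x`. The angular residual is wrapped into (-pi, pi]
#' before the quadratic form. The polar normalization constant is included,
#' but no polar-to-Cartesian Jacobian factor, so in the Cartesian frame this
#' is an unnormalized log-density whose maximum over `x` sits exactly at
#' `x_prev + r_bar * (cos(phi_bar), sin(phi_bar))` with value
#' `-1/2 log|2 pi diag(sigma_r^2, sigma_phi^2)|`.
#'
#' @param x candidate position: numeric 2-vector or n x 2 matrix.
#' @param x_prev previous position, numeric 2-vector.
#' @param params a [step_model_params()] object.
#' @return numeric vector of log-density values.
#' @export
transition_log_unnorm <- function(x, x_prev, params) {
  stopifnot(inherits(params, "step_model_params"))
  rho <- polar_of_displacement(x, x_prev)
  dr <- rho$r - params$r_bar
  dphi <- wrap_angle(rho$phi - params$phi_bar)
  ldet <- 2 * log(params$sigma_r) + 2 * log(params$sigma_phi)
  -log(2 * pi) - 0.5 * ldet -
    0.5 * (dr^2 / params$sigma_r^2 + dphi^2 / params$sigma_phi^2)
}

#' Gaussian (linearized) approximation of the predicted position
#'
#' First-order globalization of the polar step model around its mean: the
#' predicted position is Gaussian with mean one nominal step ahead of
#' `x_prev_hat` and a diagonal covariance mixing the step-length and
#' step-direction variances,
#' `diag((r_bar sin(phi_bar) sigma_phi)^2 + (sigma_r cos(phi_bar))^2,
#'       (r_bar cos(phi_bar) sigma_phi)^2 + (sigma_r sin(phi_bar))^2)`.
#' The off-diagonal cross terms of the full first-order propagation are
#' deliberately dropped, keeping the published diagonal form; the approximation
#' is exact in the limit sigma_r, sigma_phi -> 0. Used to seed gradient
#' ascent, not as the filter's transition density.
#'
#' @param x_prev_hat previous position estimate, numeric 2-vector.
#' @param params a [step_model_params()] object.
#' @return a Cartesian [gaussian_belief()].
#' @export
linearized_prediction <- function(x_prev_hat, params) {
  stopifnot(inherits(params, "step_model_params"))
  x_prev_hat <- as.numeric(x_prev_hat)
  cphi <- cos(params$phi_bar); sphi <- sin(params$phi_bar)
  m <- x_prev_hat + params$r_bar * c(cphi, sphi)
  v1 <- (params$r_bar * sphi * params$sigma_phi)^2 +
        (params$sigma_r * cphi)^2
  v2 <- (params$r_bar * cphi * params$sigma_phi)^2 +
        (params$sigma_r * sphi)^2
  gaussian_belief(m, diag(c(v1, v2)), frame = "cartesian")
}

#' Update the expected step direction from the last estimated step
#'
#' The mean step direction is continuously adapted during filtering: for step
#' k it is set to the direction of the previously estimated step,
#' `x_hat_prev - x_hat_prev2`. For the first step, or when the two previous
#' estimates coincide, the `fallback` heading is used.
#'
#' @param x_hat_prev position estimate at step k-1, numeric 2-vector.
#' @param x_hat_prev2 position estimate at step k-2, numeric 2-vector or
#'   `NULL` when unavailable.
#' @param fallback heading to use when no previous step exists or it is
#'   degenerate, radians.
#' @return heading in radians, in (-pi, pi].
#' @export
update_heading <- function(x_hat_prev, x_hat_prev2, fallback) {
  if (is.null(x_hat_prev2)) return(wrap_angle(fallback))
  rho <- polar_of_displacement(as.numeric(x_hat_prev),
                               as.numeric(x_hat_prev2))
  if (rho$degenerate) wrap_angle(fallback) else rho$phi
}
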