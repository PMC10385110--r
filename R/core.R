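#' Wrap an angle into (-pi, pi]
#'
#' Reduces an angle modulo 2*pi into the half-open interval (-pi, pi].
#' All angular residuals in the package pass through this before entering a
#' quadratic form, so that a heading difference of e.g. 350 degrees is scored
#' as -10 degrees.
#'
#' @param a numeric vector of angles in radians; must be finite.
#' @return numeric vector of the same length, each element in (-pi, pi] and
#'   congruent to the input modulo 2*pi.
#' @examples
#' wrap_angle(3 * pi / 2)   # -pi/2
#' wrap_angle(-pi)          # pi (boundary convention)
#' @export
wrap_angle <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a))) {
    stop("wrap_angle: 'a' must be finite numeric")
  }
  w <- a - 2 * pi * floor(a / (2 * pi))   # [0, 2*pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Construct a 2D Gaussian belief
#'
#' A Gaussian belief is the currency of the package: GPS and IMU observation
#' likelihoods, fused likelihoods and linearized step predictions are all
#' mean-2-vector + 2x2 symmetric positive definite covariance pairs, tagged by
#' the frame their coordinates live in (Cartesian meters or polar
#' meters/radians).
#'
#' @param mean numeric length-2 mean vector.
#' @param cov 2x2 covariance matrix; must be symmetric positive definite.
#' @param frame coordinate frame, `"cartesian"` (x east, y north, meters) or
#'   `"polar"` (step length meters, direction radians).
#' @return an object of class `"gaussian_belief"`: a list with elements
#'   `mean`, `cov`, `frame`.
#' @export
gaussian_belief <- function(mean, cov, frame = c("cartesian", "polar")) {
  frame <- match.arg(frame)
  mean <- as.numeric(mean)
  if (length(mean) != 2L || any(!is.finite(mean))) {
    stop("gaussian_belief: 'mean' must be a finite numeric 2-vector")
  }
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(2L, 2L)) || any(!is.finite(cov))) {
    stop("gaussian_belief: 'cov' must be a finite 2x2 matrix")
  }
  if (abs(cov[1, 2] - cov[2, 1]) > 1e-8 * (1 + max(abs(cov)))) {
    stop("gaussian_belief: 'cov' must be symmetric")
  }
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("gaussian_belief: 'cov' must be positive definite (eigenvalues ",
         paste(signif(ev, 4), collapse = ", "), ")")
  }
  structure(list(mean = mean, cov = cov, frame = frame),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat("Gaussian belief (", x$frame, " frame)\n", sep = "")
  cat("  mean:", format(x$mean, digits = 6), "\n")
  cat("  cov :", format(x$cov[1, ], digits = 6), "\n")
  cat("       ", format(x$cov[2, ], digits = 6), "\n")
  invisible(x)
}

# 2x2 inverse with an explicit conditioning guard; `what` names the caller in
# the diagnostic.
inv2 <- function(S, what = "covariance") {
  dt <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (!is.finite(dt) || dt <= 0 || rcond(S) < 1e-12) {
    stop("singular or near-singular ", what,
         " (det = ", signif(dt, 4), ", rcond = ", signif(rcond(S), 4), ")")
  }
  matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2L, 2L) / dt
}

#' Polar decomposition of a displacement between two positions
#'
#' Converts the Cartesian displacement `to - from` into step-polar
#' coordinates: length `r` (meters) and direction `phi` (radians, four-quadrant
#' arctangent, east = 0, counter-clockwise positive). This is the map whose
#' nonlinearity makes the Cartesian transition density non-Gaussian.
#'
#' @param to target position: numeric 2-vector, or an n x 2 matrix of
#'   positions for vectorized evaluation.
#' @param from source position, numeric 2-vector (recycled across rows of a
#'   matrix `to`).
#' @return list with numeric vectors `r` (>= 0) and `phi` (in (-pi, pi]) and a
#'   logical vector `degenerate`, TRUE where the displacement is exactly zero
#'   (there `r = 0`, `phi = 0` by convention).
#' @export
polar_of_displacement <- function(to, from) {
  from <- as.numeric(from)
  if (length(from) != 2L || any(!is.finite(from))) {
    stop("polar_of_displacement: 'from' must be a finite 2-vector")
  }
  if (is.matrix(to)) {
    dx <- to[, 1] - from[1]
    dy <- to[, 2] - from[2]
  } else {
    to <- as.numeric(to)
    if (length(to) != 2L) stop("polar_of_displacement: 'to' must be a 2-vector")
    dx <- to[1] - from[1]
    dy <- to[2] - from[2]
  }
  if (any(!is.finite(dx)) || any(!is.finite(dy))) {
    stop("polar_of_displacement: non-finite positions")
  }
  r <- sqrt(dx^2 + dy^2)
  degenerate <- r == 0
  phi <- atan2(dy, dx)
  phi[degenerate] <- 0
  list(r = r, phi = phi, degenerate = degenerate)
}

#' Jacobian of the polar displacement map
#'
#' Analytic derivative of [polar_of_displacement()] with respect to the target
#' position, evaluated at `at`: row 1 is the gradient of the step length r,
#' row 2 the gradient of the step direction phi. Used by the mode-finding
#' filter's analytic posterior gradient and by the polar-to-Cartesian
#' covariance propagation.
#'
#' @param at target position, numeric 2-vector.
#' @param from source position, numeric 2-vector.
#' @param eps singularity clamp on the displacement length, meters; below this
#'   the Jacobian is undefined and an error is raised.
#' @return 2x2 matrix `[[dx/d, dy/d], [-dy/d^2, dx/d^2]]` with
#'   `d = ||at - from||`.
#' @export
displacement_jacobian <- function(at, from, eps = 1e-9) {
  at <- as.numeric(at); from <- as.numeric(from)
  dx <- at[1] - from[1]
  dy <- at[2] - from[2]
  d2 <- dx^2 + dy^2
  d <- sqrt(d2)
  if (!is.finite(d) || d <= eps) {
    stop("displacement_jacobian: displacement length ", signif(d, 3),
         " m is at or below the singularity clamp (", eps, " m)")
  }
  matrix(c(dx / d, -dy / d2, dy / d, dx / d2), 2L, 2L)
}

#' Log-density of a 2D Gaussian belief
#'
#' Evaluates the normalized bivariate normal log-density
#' `-1/2 log|2 pi Sigma| - 1/2 (v - m)' Sigma^-1 (v - m)`.
#'
#' @param v numeric 2-vector, or an n x 2 matrix for vectorized evaluation.
#' @param belief a [gaussian_belief()].
#' @return numeric vector of log-densities.
#' @export
gaussian_logpdf <- function(v, belief) {
  stopifnot(inherits(belief, "gaussian_belief"))
  S <- belief$cov
  Sinv <- inv2(S)
  dt <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  m <- belief$mean
  if (is.matrix(v)) {
    d1 <- v[, 1] - m[1]; d2 <- v[, 2] - m[2]
  } else {
    v <- as.numeric(v)
    d1 <- v[1] - m[1]; d2 <- v[2] - m[2]
  }
  q <- Sinv[1, 1] * d1^2 + 2 * Sinv[1, 2] * d1 * d2 + Sinv[2, 2] * d2^2
  -log(2 * pi) - 0.5 * log(dt) - 0.5 * q
}

#' Fuse two Gaussian beliefs (information form)
#'
#' Closed-form product of two Gaussian densities, renormalized: the fused
#' covariance is the inverse of the summed precisions and the fused mean is
#' the precision-weighted mean. This is the online GPS/IMU fusion rule; it is
#' commutative and associative, so multi-sensor fusion reduces to sequential
#' pairwise calls.
#'
#' @param a,b [gaussian_belief()] objects in the same frame.
#' @return the fused [gaussian_belief()].
#' @export
fuse_gaussians <- function(a, b) {
  stopifnot(inherits(a, "gaussian_belief"), inherits(b, "gaussian_belief"))
  if (!identical(a$frame, b$frame)) {
    stop("fuse_gaussians: beliefs are in different frames (",
         a$frame, " vs ", b$frame, ")")
  }
  Ia <- inv2(a$cov, "input covariance (first belief)")
  Ib <- inv2(b$cov, "input covariance (second belief)")
  S <- inv2(Ia + Ib, "summed precision")
  S <- (S + t(S)) / 2
  m <- as.numeric(S %*% (Ia %*% a$mean + Ib %*% b$mean))
  gaussian_belief(m, S, frame = a$frame)
}
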