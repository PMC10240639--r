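#' Load a patellar mechanism
#'
#' The mechanism couples knee flexion angle \eqn{\theta} to (i) the
#' patellar-tendon/quadriceps force ratio \eqn{k(\theta)} and (ii) the
#' patellar mechanism angle \eqn{\beta(\theta)} between the
#' quadriceps-tendon and patellar-tendon force vectors acting on the
#' patella. Both are polynomials read from a versioned mechanism file;
#' evaluation outside the valid flexion range clamps \eqn{\theta} and sets
#' a flag. The shipped default is a synthetic fit to published in vitro
#' trends (see the file's provenance note).
#'
#' @param path mechanism JSON file.
#' @return object of class \code{patellar_mechanism}.
#' @export
patellar_mechanism <- function(path = default_file("mechanism")) {
  d <- read_defaults_json(path)
  mech <- structure(list(version = d$version,
                         k_coeffs = as.numeric(d$k_coeffs),
                         beta_coeffs = as.numeric(d$beta_coeffs),
                         valid_range = as.numeric(d$theta_valid_range_deg),
                         source = path),
                    class = "patellar_mechanism")
  th <- seq(mech$valid_range[1], mech$valid_range[2], length.out = 241)
  if (any(polyval(mech$k_coeffs, th) <= 0))
    stop("model error: k(theta) must be positive over the valid range")
  b <- polyval(mech$beta_coeffs, th)
  if (any(b <= 0 | b >= 180))
    stop("model error: beta(theta) must lie in (0, 180) deg over the valid range")
  mech
}

polyval <- function(coeffs, x) {
  out <- 0
  for (p in seq_along(coeffs)) out <- out + coeffs[p] * x^(p - 1)
  out
}

clamp_theta <- function(theta, mech) {
  lo <- mech$valid_range[1]; hi <- mech$valid_range[2]
  list(theta = pmin(hi, pmax(lo, theta)), clamped = theta < lo | theta > hi)
}

#' Patellar-tendon / quadriceps force ratio k(theta)
#' @param theta knee flexion angle (deg); clamped to the valid range.
#' @param mech a \code{patellar_mechanism}.
#' @return ratio (dimensionless), attribute \code{clamped}.
#' @export
patellar_ratio <- function(theta, mech = patellar_mechanism()) {
  cl <- clamp_theta(theta, mech)
  out <- polyval(mech$k_coeffs, cl$theta)
  attr(out, "clamped") <- cl$clamped
  out
}

#' Patellar mechanism angle beta(theta)
#' @inheritParams patellar_ratio
#' @return angle between the tendon force vectors (deg), attribute
#'   \code{clamped}.
#' @export
mechanism_angle <- function(theta, mech = patellar_mechanism()) {
  cl <- clamp_theta(theta, mech)
  out <- polyval(mech$beta_coeffs, cl$theta)
  attr(out, "clamped") <- cl$clamped
  out
}

#' Patellar tendon force from quadriceps force
#'
#' \eqn{F_P = k(\theta) F_Q}: the ratio is dimensionless, so the result is
#' in whatever unit \eqn{F_Q} carries (BW throughout this package).
#'
#' @param f_q quadriceps force (BW), nonnegative.
#' @param theta knee flexion angle (deg).
#' @param mech a \code{patellar_mechanism}.
#' @return patellar tendon force (BW), attribute \code{clamped}.
#' @export
patellar_tendon_force <- function(f_q, theta, mech = patellar_mechanism()) {
  if (any(f_q < 0)) stop("input error: quadriceps force must be nonnegative")
  k <- patellar_ratio(theta, mech)
  out <- as.numeric(k) * f_q
  attr(out, "clamped") <- attr(k, "clamped")
  out
}

#' PFJ contact force: law-of-cosines resultant
#'
#' \deqn{F_{PFJ} = \sqrt{F_Q^2 + F_P^2 + 2 F_Q F_P \cos\beta}}
#' the magnitude of the resultant of the quadriceps-tendon and
#' patellar-tendon force vectors separated by the mechanism angle
#' \eqn{\beta}. Exact formula, no approximation.
#'
#' @param f_q quadriceps force (BW), nonnegative.
#' @param f_p patellar tendon force (BW), nonnegative.
#' @param beta mechanism angle (deg) in [0, 180]; no wrapping.
#' @return contact force (BW).
#' @export
pfj_contact_force <- function(f_q, f_p, beta) {
  if (any(f_q < 0) || any(f_p < 0))
    stop("input error: tendon forces must be nonnegative")
  if (any(beta < 0 | beta > 180))
    stop("input error: beta must lie in [0, 180] degrees")
  sq <- f_q^2 + f_p^2 + 2 * f_q * f_p * cos(beta * DEG)
  sqrt(pmax(sq, 0))
}

#' PFJ contact force series from quadriceps force and knee kinematics
#'
#' @param f_q_series quadriceps force (BW) per sample.
#' @param kin a \code{joint_kinematics} on the same clock (knee flexion
#'   angle is read from it), or a numeric vector of knee angles (deg).
#' @param mech a \code{patellar_mechanism}.
#' @param time optional sample times.
#' @return object of class \code{pfj_force_series}: data.frame fields
#'   \code{time, f_q, f_p, beta, f_pfj, clamped}, plus the mechanism
#'   version used.
#' @export
pfj_series <- function(f_q_series, kin, mech = patellar_mechanism(),
                       time = NULL) {
  if (inherits(kin, "joint_kinematics")) {
    theta <- kin$angles[, "knee"]
    time <- time %||% kin$time
  } else theta <- as.numeric(kin)
  if (length(theta) == 0 || length(f_q_series) == 0)
    stop("alignment error: zero-length overlap between series")
  if (length(theta) != length(f_q_series))
    stop("alignment error: quadriceps force and knee angle series differ in length")
  f_p <- patellar_tendon_force(f_q_series, theta, mech)
  beta <- mechanism_angle(theta, mech)
  out <- data.frame(
    time = if (is.null(time)) seq_along(theta) else time,
    f_q = f_q_series, f_p = as.numeric(f_p), beta = as.numeric(beta),
    f_pfj = pfj_contact_force(f_q_series, as.numeric(f_p), as.numeric(beta)),
    clamped = attr(f_p, "clamped"))
  structure(list(series = out, mechanism_version = mech$version),
            class = "pfj_force_series")
}
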