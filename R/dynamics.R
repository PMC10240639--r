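#' Net joint moments by bottom-up Newton--Euler inverse dynamics
#'
#' Recurses foot -> shank -> thigh on the planar chain, including segment
#' inertial terms (m a, I alpha) and gravity, with the ground-reaction
#' force applied at the centre of pressure. Segment COM and angular
#' accelerations are obtained by central differences of the pose
#' trajectory (one-sided at the endpoints).
#'
#' Reported sign conventions: hip flexion positive, knee extension
#' positive, ankle dorsiflexion positive. The conjugate-coordinate moments
#' (knee flexion positive) used by the static optimizer are carried in the
#' \code{conjugate} field.
#'
#' @param kin a \code{joint_kinematics} from \code{\link{inverse_kinematics}}.
#' @param grf data.frame on the same clock as \code{kin}: columns
#'   \code{time}, \code{fx}, \code{fy} (N) and \code{cop_x} (m).
#' @param model a \code{\link{planar_model}} scaled to the participant.
#' @param grf_cutoff low-pass cutoff (Hz) applied to fx/fy before the
#'   recursion (\code{NULL} = raw). Event detection must always use the
#'   raw native-rate signal, not this filtered copy.
#' @return object of class \code{net_joint_moments}: \code{time},
#'   \code{moments} (N m, reported convention), \code{conjugate} (N m),
#'   and the applied force/COP series.
#' @export
inverse_dynamics <- function(kin, grf, model, grf_cutoff = 50) {
  stopifnot(inherits(kin, "joint_kinematics"))
  if (nrow(grf) != length(kin$time) ||
      max(abs(grf$time - kin$time)) > stats::median(diff(kin$time)) / 2)
    stop("alignment error: kinematics and GRF are not on the same clock")
  n <- length(kin$time)
  dt <- stats::median(diff(kin$time))
  g <- model$g

  fx <- grf$fx
  fy <- grf$fy
  if (!is.null(grf_cutoff)) {
    fx <- low_pass(fx, 1 / dt, grf_cutoff)
    fy <- low_pass(fy, 1 / dt, grf_cutoff)
  }
  cop <- grf$cop_x
  loaded <- sqrt(fx^2 + fy^2) > 1e-6
  if (any(loaded & !is.finite(cop)))
    stop("input error: missing center of pressure while force is applied")
  cop[!is.finite(cop)] <- 0

  dof <- c("px", "py", "phi", "hip", "knee", "ankle")
  segnames <- c("pelvis_hat", "thigh", "shank", "foot")
  coms <- array(NA_real_, c(n, 4, 2), dimnames = list(NULL, segnames, NULL))
  rots <- matrix(NA_real_, n, 4, dimnames = list(NULL, segnames))
  joints <- array(NA_real_, c(n, 3, 2),
                  dimnames = list(NULL, c("hip", "knee", "ankle"), NULL))
  for (i in seq_len(n)) {
    pose <- kin$pose[i, dof]
    chain <- fk_chain(model, pose)
    coms[i, , ] <- fk_segment_coms(model, pose, chain)
    rots[i, ] <- segment_rotations(pose)[segnames]
    joints[i, , ] <- rbind(chain$joints$hip, chain$joints$knee,
                           chain$joints$ankle)
  }
  acc <- apply(coms, c(2, 3), function(v) central_diff(central_diff(v, dt), dt))
  aalpha <- apply(rots * DEG, 2, function(v) central_diff(central_diff(v, dt), dt))
  gvec <- c(0, -g)
  cross2 <- function(r, f) r[, 1] * f[, 2] - r[, 2] * f[, 1]

  Mz <- matrix(0, n, 3, dimnames = list(NULL, c("hip", "knee", "ankle")))
  Fgrf <- cbind(fx, fy)
  copxy <- cbind(cop, 0)
  recurse <- function(seg, prox_joint, dist_joint, F_dist, M_dist,
                      F_ext = NULL, P_ext = NULL) {
    s <- model$segments[[seg]]
    C <- coms[, seg, ]
    Fe <- if (is.null(F_ext)) matrix(0, n, 2) else F_ext
    F_prox <- s$mass * acc[, seg, ] -
      matrix(gvec * s$mass, n, 2, byrow = TRUE) - F_dist - Fe
    M_prox <- s$inertia * aalpha[, seg] - M_dist -
      cross2(joints[, prox_joint, ] - C, F_prox) -
      (if (is.null(dist_joint)) 0 else cross2(joints[, dist_joint, ] - C, F_dist)) -
      (if (is.null(F_ext)) 0 else cross2(P_ext - C, Fe))
    list(F = F_prox, M = M_prox)
  }
  ft <- recurse("foot", "ankle", NULL, matrix(0, n, 2), 0,
                F_ext = Fgrf, P_ext = copxy)
  Mz[, "ankle"] <- ft$M
  sh <- recurse("shank", "knee", "ankle", -ft$F, -ft$M)
  Mz[, "knee"] <- sh$M
  th <- recurse("thigh", "hip", "knee", -sh$F, -sh$M)
  Mz[, "hip"] <- th$M

  conj <- cbind(hip = Mz[, "hip"], knee = -Mz[, "knee"], ankle = Mz[, "ankle"])
  rep_m <- cbind(hip = Mz[, "hip"], knee = Mz[, "knee"], ankle = Mz[, "ankle"])
  structure(list(time = kin$time, moments = rep_m, conjugate = conj,
                 grf_applied = data.frame(time = kin$time, fx = fx, fy = fy,
                                          cop_x = cop)),
            class = "net_joint_moments")
}
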