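#' Static optimization: decompose net moments into muscle forces
#'
#' Per-sample convex quadratic program: minimise the sum of squared
#' activations subject to moment equilibrium at hip, knee and ankle and
#' activation bounds \eqn{0 \le a_i \le 1}, with muscle force
#' \eqn{F_i = a_i f_{max,i}} (affine force generation; no
#' force--length--velocity scaling). Biarticular muscles couple the three
#' joint equality constraints within each frame. Samples whose demanded
#' moments exceed capacity are infeasible for the equality-constrained
#' program; they are reported with the bound-constrained least-residual
#' solution and flagged, so one bad frame does not reject a trial.
#'
#' @param moments a \code{net_joint_moments} object, or a matrix of
#'   conjugate-convention moments (N m) with columns hip, knee, ankle.
#' @param kin a \code{joint_kinematics} supplying joint angles (deg) for
#'   the angle-dependent moment arms.
#' @param model a \code{\link{planar_model}} with a non-empty muscle set.
#' @return object of class \code{muscle_solution}: activation and force
#'   matrices (samples x muscles), per-sample objective, maximum moment
#'   residual (N m), feasibility flags, and the summed quadriceps force
#'   (N).
#' @export
static_optimization <- function(moments, kin, model) {
  if (length(model$muscles) == 0) stop("model error: empty muscle set")
  M <- if (inherits(moments, "net_joint_moments")) moments$conjugate
       else as.matrix(moments)
  tm <- if (inherits(moments, "net_joint_moments")) moments$time else kin$time
  theta <- kin$angles
  if (nrow(theta) != nrow(M))
    stop("alignment error: moments and kinematics differ in length")
  nmus <- length(model$muscles)
  fmax <- vapply(model$muscles, `[[`, 0, "f_max")
  quad <- vapply(model$muscles, `[[`, TRUE, "is_quadriceps")
  for (j in model$joint_names) {
    spans <- vapply(model$muscles, function(m) j %in% names(m$arms), TRUE)
    if (!any(spans) && any(abs(M[, j]) > 1e-9))
      stop("model error: no muscle spans constrained joint ", j)
  }

  n <- nrow(M)
  act <- matrix(0, n, nmus, dimnames = list(NULL, names(model$muscles)))
  objective <- numeric(n)
  residual <- numeric(n)
  feasible <- rep(TRUE, n)
  for (i in seq_len(n)) {
    Rarm <- moment_arm_matrix(model, theta[i, ])
    Reff <- Rarm * rep(fmax, each = 3)
    # drop unconstrained joints (no spanning muscle, zero demand)
    keep <- apply(Reff != 0, 1, any) | abs(M[i, ]) > 1e-9
    sol <- solve_activation_qp(Reff[keep, , drop = FALSE], M[i, keep])
    act[i, ] <- sol$a
    objective[i] <- sum(sol$a^2)
    residual[i] <- max(abs(Reff %*% sol$a - M[i, ]))
    feasible[i] <- sol$feasible && residual[i] < 1e-6
  }
  forces <- act * rep(fmax, each = n)
  structure(list(time = tm, activations = act, forces = forces,
                 objective = objective, residual = residual,
                 feasible = feasible, f_max = fmax, is_quadriceps = quad,
                 quadriceps_force_n = rowSums(forces[, quad, drop = FALSE])),
            class = "muscle_solution")
}

# min ||a||^2 s.t. Reff a = M, 0 <= a <= 1; bounded least-residual fallback
solve_activation_qp <- function(Reff, M) {
  nmus <- ncol(Reff)
  Amat <- cbind(t(Reff), diag(nmus), -diag(nmus))
  bvec <- c(M, rep(0, nmus), rep(-1, nmus))
  fit <- tryCatch(
    quadprog::solve.QP(Dmat = diag(2, nmus), dvec = rep(0, nmus),
                       Amat = Amat, bvec = bvec, meq = nrow(Reff)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    a <- pmin(1, pmax(0, fit$solution))
    return(list(a = a, feasible = TRUE))
  }
  # infeasible demand: minimise the moment residual within the bounds,
  # with a tiny ridge to select a unique (near-minimum-norm) solution
  D <- 2 * crossprod(Reff) + diag(1e-8, nmus)
  d <- 2 * as.numeric(crossprod(Reff, M))
  fit <- quadprog::solve.QP(Dmat = D, dvec = d,
                            Amat = cbind(diag(nmus), -diag(nmus)),
                            bvec = c(rep(0, nmus), rep(-1, nmus)), meq = 0)
  list(a = pmin(1, pmax(0, fit$solution)), feasible = FALSE)
}

#' Quadriceps force in body weights
#'
#' Sums the forces of the quadriceps-flagged muscles and normalises by
#' body weight (mass x g).
#'
#' @param solution a \code{muscle_solution}.
#' @param body_mass participant mass (kg).
#' @param g gravitational acceleration (m/s^2).
#' @return numeric vector of quadriceps force (BW) per sample.
#' @export
quadriceps_force <- function(solution, body_mass, g = 9.81) {
  stopifnot(inherits(solution, "muscle_solution"))
  if (!is.numeric(body_mass) || body_mass <= 0)
    stop("input error: body mass must be positive")
  solution$quadriceps_force_n / (body_mass * g)
}
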