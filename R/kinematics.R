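#' Construct a marker time series
#'
#' @param time numeric vector of sample times (s), strictly increasing.
#' @param xy numeric array \code{[frame, marker, 2]} of x/y positions (m).
#' @param names marker names (length = second dim of \code{xy}).
#' @return object of class \code{marker_series}.
#' @export
marker_series <- function(time, xy, names) {
  stopifnot(length(dim(xy)) == 3, dim(xy)[3] == 2,
            dim(xy)[1] == length(time), dim(xy)[2] == length(names))
  if (any(diff(time) <= 0)) stop("input error: time must be strictly increasing")
  dimnames(xy) <- list(NULL, names, c("x", "y"))
  rate <- if (length(time) > 1) 1 / stats::median(diff(time)) else NA_real_
  structure(list(time = as.numeric(time), names = names, xy = xy,
                 rate = rate), class = "marker_series")
}

#' Planar forward kinematics: marker positions from joint angles
#'
#' The exact inverse of noiseless \code{\link{inverse_kinematics}}; used as
#' the generator back end and as the IK test oracle.
#'
#' @param poses data.frame or matrix with columns
#'   \code{px, py, phi, hip, knee, ankle} (m / deg) and optionally
#'   \code{time}.
#' @param model a \code{\link{planar_model}}.
#' @param time sample times; defaults to \code{poses$time}.
#' @return a \code{\link{marker_series}}.
#' @export
forward_markers <- function(poses, model, time = NULL) {
  poses <- as.data.frame(poses)
  time <- time %||% poses$time
  if (is.null(time)) stop("input error: sample times required")
  need <- c("px", "py", "phi", "hip", "knee", "ankle")
  if (!all(need %in% names(poses)))
    stop("input error: poses must have columns ", paste(need, collapse = ", "))
  lim <- model$joint_limits
  if (!is.null(lim)) {
    for (j in c("hip", "knee", "ankle")) {
      if (any(poses[[j]] < lim[[j]][1] - 1e-9 | poses[[j]] > lim[[j]][2] + 1e-9))
        stop("model error: ", j, " angle outside model joint limits")
    }
  }
  n <- nrow(poses)
  nm <- model$markers$name
  xy <- array(NA_real_, c(n, length(nm), 2))
  for (i in seq_len(n)) {
    pose <- as.numeric(poses[i, need])
    names(pose) <- need
    xy[i, , ] <- fk_markers_pose(model, pose)
  }
  marker_series(time, xy, nm)
}

# weighted IK objective for one frame: sum_m w_m ||xhat_m(pose) - x_m||^2
ik_objective <- function(model, pose, obs, weights) {
  xhat <- fk_markers_pose(model, pose)
  ok <- is.finite(obs[, 1]) & is.finite(obs[, 2]) & weights > 0
  sum(weights[ok] * rowSums((xhat[ok, , drop = FALSE] -
                             obs[ok, , drop = FALSE])^2))
}

# analytic Jacobian of marker positions wrt (px,py,phi,hip,knee,ankle)
ik_jacobian <- function(model, pose, idx) {
  chain <- fk_chain(model, pose)
  xhat <- fk_markers_pose(model, pose, chain)
  seg <- model$markers$segment
  P <- chain$joints$hip; K <- chain$joints$knee; A <- chain$joints$ankle
  nm <- length(idx)
  J <- matrix(0, 2 * nm, 6)
  for (r in seq_len(nm)) {
    m <- idx[r]
    p <- xhat[m, ]
    rows <- c(2 * r - 1, 2 * r)
    J[rows, 1] <- c(1, 0)
    J[rows, 2] <- c(0, 1)
    perp <- function(v) c(-v[2], v[1]) * DEG
    J[rows, 3] <- perp(p - P)
    if (seg[m] != "pelvis_hat") J[rows, 4] <- perp(p - P)
    if (seg[m] %in% c("shank", "foot")) J[rows, 5] <- -perp(p - K)
    if (seg[m] == "foot") J[rows, 6] <- perp(p - A)
  }
  list(J = J, xhat = xhat)
}

# damped Gauss-Newton solve of one frame; returns pose, objective, iters
ik_solve_frame <- function(model, obs, weights, init,
                           fixed = NULL, tol = 1e-10, max_iter = 100L) {
  dof <- c("px", "py", "phi", "hip", "knee", "ankle")
  pose <- init[dof]
  free <- if (is.null(fixed)) rep(TRUE, 6) else !(dof %in% names(fixed))
  if (!is.null(fixed)) pose[names(fixed)] <- unlist(fixed)
  idx <- which(is.finite(obs[, 1]) & is.finite(obs[, 2]) & weights > 0)
  w <- rep(weights[idx], each = 2)
  lambda <- 1e-8
  for (it in seq_len(max_iter)) {
    jb <- ik_jacobian(model, pose, idx)
    res <- as.numeric(t(jb$xhat[idx, , drop = FALSE] -
                        obs[idx, , drop = FALSE]))
    J <- jb$J[, free, drop = FALSE]
    H <- crossprod(J, w * J) + lambda * diag(sum(free))
    g <- crossprod(J, w * res)
    step <- tryCatch(solve(H, g), error = function(e) rep(0, sum(free)))
    pose[free] <- pose[free] - step
    if (max(abs(step)) < tol) break
  }
  list(pose = pose, objective = ik_objective(model, pose, obs, weights),
       iterations = it)
}

# closed-form optimal translation given the rotational DOFs
ik_init_translation <- function(model, pose, obs, weights) {
  pose[c("px", "py")] <- c(0, 0)
  xhat <- fk_markers_pose(model, pose)
  ok <- is.finite(obs[, 1]) & is.finite(obs[, 2]) & weights > 0
  w <- weights[ok]
  d <- colSums(w * (obs[ok, , drop = FALSE] - xhat[ok, , drop = FALSE])) / sum(w)
  pose[c("px", "py")] <- d
  pose
}

#' Inverse kinematics by weighted least squares
#'
#' Estimates the 6-DOF planar pose (pelvis translation + tilt, hip, knee,
#' ankle angles) per frame by minimising the weighted sum of squared
#' distances between model and measured marker positions, with a damped
#' Gauss--Newton solver warm-started from the previous frame. Frames with
#' fewer than 3 usable markers are flagged and linearly interpolated when
#' the gap is at most \code{max_gap} frames; longer gaps reject the trial.
#'
#' @param markers a \code{\link{marker_series}}.
#' @param model a \code{\link{planar_model}}.
#' @param weights optional named replacement marker weights.
#' @param filter_cutoff low-pass cutoff (Hz) applied to marker trajectories
#'   before solving (zero-lag Butterworth); \code{NULL} disables filtering.
#' @param fixed named list of DOFs to hold fixed (e.g.
#'   \code{list(px = 0, py = 0, phi = 0)}), mainly for oracle tests.
#' @param init optional initial pose for the first frame.
#' @param max_gap longest marker gap (frames) bridged by interpolation.
#' @return object of class \code{joint_kinematics}: sample times, pose
#'   matrix, joint angles (deg), angular velocities and accelerations
#'   (deg/s, deg/s^2, central differences), per-frame objective values and
#'   interpolation flags.
#' @export
inverse_kinematics <- function(markers, model, weights = NULL,
                               filter_cutoff = 12, fixed = NULL,
                               init = NULL, max_gap = 10L) {
  stopifnot(inherits(markers, "marker_series"))
  mk <- model$markers
  w <- mk$weight
  names(w) <- mk$name
  if (!is.null(weights)) w[names(weights)] <- unlist(weights)
  ord <- match(mk$name, markers$names)
  if (anyNA(ord))
    stop("model error: marker(s) missing from data: ",
         paste(mk$name[is.na(ord)], collapse = ", "))
  xy <- markers$xy[, ord, , drop = FALSE]
  n <- dim(xy)[1]

  if (!is.null(filter_cutoff)) {
    for (m in seq_len(dim(xy)[2])) for (k in 1:2) {
      v <- xy[, m, k]
      if (!anyNA(v)) xy[, m, k] <- low_pass(v, markers$rate, filter_cutoff)
    }
  }

  usable <- vapply(seq_len(n), function(i) {
    sum(is.finite(xy[i, , 1]) & is.finite(xy[i, , 2]) & w > 0) >= 3
  }, TRUE)
  if (!any(usable)) stop("gap error: no frame has 3 usable markers")
  gaps <- rle(!usable)
  if (any(gaps$lengths[gaps$values] > max_gap))
    stop("gap error: marker gap exceeds ", max_gap, " frames")

  dof <- c("px", "py", "phi", "hip", "knee", "ankle")
  pose_mat <- matrix(NA_real_, n, 6, dimnames = list(NULL, dof))
  objective <- rep(NA_real_, n)
  prev <- NULL
  for (i in seq_len(n)) {
    if (!usable[i]) next
    obs <- xy[i, , , drop = TRUE]
    if (is.null(prev)) {
      best <- NULL
      grid <- expand.grid(phi = c(0, 10), hip = c(0, 30, 60),
                          knee = c(5, 30, 60), ankle = c(-10, 10))
      for (gidx in seq_len(nrow(grid))) {
        cand <- c(px = 0, py = 0, phi = grid$phi[gidx], hip = grid$hip[gidx],
                  knee = grid$knee[gidx], ankle = grid$ankle[gidx])
        cand <- ik_init_translation(model, cand, obs, w)
        f <- ik_objective(model, cand, obs, w)
        if (is.null(best) || f < best$f) best <- list(pose = cand, f = f)
      }
      start <- if (is.null(init)) best$pose else {
        ini <- c(px = 0, py = 0, phi = 0, hip = 0, knee = 0, ankle = 0)
        ini[names(init)] <- unlist(init)
        ini
      }
    } else start <- prev
    sol <- ik_solve_frame(model, obs, w, start, fixed = fixed)
    pose_mat[i, ] <- sol$pose
    objective[i] <- sol$objective
    prev <- sol$pose
  }
  if (any(!usable)) {
    good <- which(usable)
    for (k in seq_len(6)) {
      pose_mat[, k] <- stats::approx(markers$time[good], pose_mat[good, k],
                                     xout = markers$time, rule = 2)$y
    }
  }

  dt <- if (n > 1) stats::median(diff(markers$time)) else 1
  ang <- pose_mat[, c("hip", "knee", "ankle"), drop = FALSE]
  if (n > 1) {
    vel <- central_diff(ang, dt)
    acc <- central_diff(vel, dt)
  } else {
    vel <- acc <- ang * 0
  }
  structure(list(time = markers$time, pose = pose_mat,
                 angles = ang, velocity = vel, acceleration = acc,
                 objective = objective, interpolated = !usable,
                 rate = markers$rate),
            class = "joint_kinematics")
}

#' Detect stance from the raw vertical ground-reaction force
#'
#' Stance is the interval bounded by the first and last samples whose raw
#' (unfiltered) vertical force exceeds the threshold (20 N by default).
#'
#' @param grf numeric vector of raw vertical force (N), or a data.frame
#'   with a \code{fy} column (and optionally \code{time}).
#' @param threshold force threshold (N), must be positive.
#' @return list with \code{contact_index}, \code{toe_off_index} (1-based)
#'   and, when time is available, \code{contact_time}/\code{toe_off_time}.
#' @export
detect_stance <- function(grf, threshold = 20) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("configuration error: threshold must be > 0")
  tm <- NULL
  if (is.data.frame(grf)) {
    if (!"fy" %in% names(grf)) stop("input error: grf needs an fy column")
    tm <- grf$time
    f <- grf$fy
  } else f <- as.numeric(grf)
  above <- which(f > threshold)
  if (length(above) == 0)
    stop("no-stance error: no sample exceeds ", threshold, " N")
  out <- list(contact_index = above[1], toe_off_index = above[length(above)])
  if (!is.null(tm)) {
    out$contact_time <- tm[out$contact_index]
    out$toe_off_time <- tm[out$toe_off_index]
  }
  out
}

#' Approach velocity: mean forward COM velocity before foot contact
#'
#' Computes the mean forward (approach-direction) centre-of-mass velocity
#' over the \code{window} seconds preceding \code{contact_time}, by
#' trapezoidal averaging of the centrally-differentiated COM trajectory.
#'
#' @param com data.frame with columns \code{time} and \code{x} (m); use
#'   mass-weighted segment COMs when full kinematics are available, or a
#'   sacral-marker proxy otherwise (set \code{proxy = TRUE} to flag it).
#' @param contact_time foot-contact time (s).
#' @param window averaging window (s), default 0.050.
#' @param proxy flag carried through to the result attribute.
#' @return mean forward velocity (m/s) with attribute \code{proxy}.
#' @export
approach_velocity <- function(com, contact_time, window = 0.050,
                              proxy = FALSE) {
  if (!is.numeric(window) || window <= 0)
    stop("configuration error: window must be > 0")
  t0 <- contact_time - window
  if (min(com$time) > t0 + 1e-12 || max(com$time) < contact_time - 1e-12)
    stop("insufficient-history error: COM trajectory does not cover the ",
         window * 1000, " ms before contact")
  dt <- stats::median(diff(com$time))
  vx <- central_diff(com$x, dt)
  knots <- sort(unique(c(t0, com$time[com$time > t0 & com$time < contact_time],
                         contact_time)))
  vk <- stats::approx(com$time, vx, xout = knots, rule = 2)$y
  v <- sum(diff(knots) * (utils::head(vk, -1) + utils::tail(vk, -1)) / 2) / window
  attr(v, "proxy") <- proxy
  v
}

#' Time-normalize a series onto 0--100% of stance
#'
#' Linear interpolation onto 101 evenly spaced samples spanning the given
#' interval (e.g. foot contact to toe-off).
#'
#' @param x numeric vector of values.
#' @param time numeric vector of sample times.
#' @param interval length-2 numeric \code{c(start, end)} within the record.
#' @return numeric vector of length 101 with attribute \code{pct}.
#' @export
time_normalize <- function(x, time, interval) {
  if (interval[2] <= interval[1])
    stop("bounds error: interval end must exceed start")
  if (interval[1] < min(time) - 1e-9 || interval[2] > max(time) + 1e-9)
    stop("bounds error: interval outside record")
  tq <- seq(interval[1], interval[2], length.out = 101)
  out <- stats::approx(time, x, xout = tq, rule = 2)$y
  attr(out, "pct") <- seq(0, 100, length.out = 101)
  out
}

#' Downsample a force series to the marker clock by windowed averaging
#'
#' Each marker-rate sample is the mean of the native-rate samples falling
#' within half a marker period on either side of the marker time stamp.
#' Event detection must use the native-rate signal; this fusion is only for
#' joint-level computations.
#'
#' @param grf data.frame with \code{time} plus numeric columns.
#' @param marker_time target sample times (s).
#' @return data.frame on the marker clock with the same value columns.
#' @export
align_grf_to_markers <- function(grf, marker_time) {
  h <- stats::median(diff(marker_time))
  cols <- setdiff(names(grf), "time")
  out <- data.frame(time = marker_time)
  bins <- findInterval(grf$time, c(marker_time - h / 2, marker_time[length(marker_time)] + h / 2))
  for (cl in cols) {
    agg <- tapply(grf[[cl]], bins, mean)
    v <- rep(NA_real_, length(marker_time))
    ok <- as.integer(names(agg))
    keep <- ok >= 1 & ok <= length(marker_time)
    v[ok[keep]] <- agg[keep]
    if (anyNA(v)) {
      na <- is.na(v)
      v[na] <- stats::approx(grf$time, grf[[cl]], xout = marker_time[na],
                             rule = 2)$y
    }
    out[[cl]] <- v
  }
  out
}
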