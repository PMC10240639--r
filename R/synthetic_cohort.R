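#' Define a synthetic cohort design
#'
#' The stated world of the recovery simulation: two cohorts (ACLR
#' participants tested on both limbs, controls on one), a fixed number of
#' cutting trials per limb, per-limb calibration of the three outcome
#' metrics, per-limb approach-velocity distributions, velocity slopes, and
#' the within-trial correlation structure among metrics. Defaults are
#' loaded from the versioned \code{cohort_defaults.json} shipped with the
#' package (group marginal means, velocity distributions, and SDs
#' back-calculated from the published CIs), not hard-coded in logic.
#'
#' @param ... named overrides of any defaults-file field
#'   (\code{n_aclr}, \code{n_control}, \code{trials_per_limb},
#'   \code{limb_calibration}, \code{sd_between}, \code{sd_within},
#'   \code{velocity_calibration}, \code{velocity_slope},
#'   \code{metric_correlation}, \code{anthropometry}).
#' @param defaults path to a cohort defaults JSON file.
#' @return object of class \code{cohort_design}.
#' @export
cohort_design <- function(..., defaults = default_file("cohort")) {
  d <- read_defaults_json(defaults)
  over <- list(...)
  bad <- setdiff(names(over), c("n_aclr", "n_control", "trials_per_limb",
                                "limb_calibration", "sd_between", "sd_within",
                                "velocity_calibration", "velocity_slope",
                                "metric_correlation", "anthropometry"))
  if (length(bad))
    stop("configuration error: unknown design field(s): ",
         paste(bad, collapse = ", "))
  for (nm in names(over)) {
    # nested lists merge into the defaults; scalars and matrices replace
    if (is.list(d[[nm]]) && is.list(over[[nm]]) && !is.data.frame(over[[nm]]))
      d[[nm]] <- utils::modifyList(d[[nm]], over[[nm]])
    else d[[nm]] <- over[[nm]]
  }
  design <- structure(list(
    n_aclr = d$n_aclr, n_control = d$n_control,
    trials_per_limb = d$trials_per_limb,
    limb_calibration = d$limb_calibration,
    sd_between = d$sd_between, sd_within = d$sd_within,
    velocity_calibration = d$velocity_calibration,
    velocity_slope = d$velocity_slope,
    metric_correlation = as.matrix(d$metric_correlation),
    anthropometry = d$anthropometry,
    version = d$version), class = "cohort_design")
  validate_cohort_design(design)
  design
}

validate_cohort_design <- function(design) {
  if (!is.numeric(design$n_aclr) || design$n_aclr < 2)
    stop("configuration error: n_aclr must be at least 2")
  if (!is.numeric(design$n_control) || design$n_control < 2)
    stop("configuration error: n_control must be at least 2")
  if (!is.numeric(design$trials_per_limb) || design$trials_per_limb < 1)
    stop("configuration error: trials_per_limb must be at least 1")
  for (fld in c("sd_between", "sd_within")) {
    v <- unlist(design[[fld]])
    if (any(v < 0)) stop("configuration error: ", fld, " must be nonnegative")
  }
  for (l in names(design$velocity_calibration)) {
    if (design$velocity_calibration[[l]]$sd < 0)
      stop("configuration error: velocity_calibration sd for ", l,
           " must be nonnegative")
  }
  C <- design$metric_correlation
  if (any(abs(C) > 1 + 1e-12))
    stop("configuration error: metric_correlation entries must lie in [-1, 1]")
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("configuration error: metric_correlation must be positive semidefinite")
  limbs <- c("ACLR", "contralateral", "control")
  if (!all(limbs %in% names(design$limb_calibration)))
    stop("configuration error: limb_calibration must cover ",
         paste(limbs, collapse = ", "))
  invisible(design)
}

#' Pooled mean approach velocity implied by a design
#'
#' Row-weighted mean of the per-limb velocity means (ACLR and contralateral
#' rows weighted by the ACLR cohort size, control rows by the control
#' cohort size). The metric-level generator centres its velocity slopes
#' here, so the calibrated group means are exactly the velocity-adjusted
#' marginal means at the pooled mean velocity.
#'
#' @param design a \code{cohort_design}.
#' @return pooled mean velocity (m/s).
#' @export
design_pooled_velocity <- function(design) {
  vc <- design$velocity_calibration
  na <- design$n_aclr; nc <- design$n_control
  (na * (vc$ACLR$mean + vc$contralateral$mean) + nc * vc$control$mean) /
    (2 * na + nc)
}

#' Generate a metric-level synthetic cohort
#'
#' Simulates per-trial scalar outcomes with the structure the mixed model
#' assumes: for metric \eqn{m} on limb \eqn{l},
#' \deqn{y = \mu_m(l) + b_{participant,m} + s_m (v - \bar v) + \epsilon}
#' with participant intercepts \eqn{b \sim N(0, sd_{between})} shared by
#' the two limbs of an ACLR participant, correlated within-trial residuals
#' \eqn{\epsilon \sim N(0, sd_{within})}, and per-limb approach velocities
#' \eqn{v}. Deterministic for a fixed seed.
#'
#' @param design a \code{\link{cohort_design}}.
#' @param seed integer seed.
#' @return data.frame with columns \code{participant_id},
#'   \code{limb} (\code{ACLR}, \code{contralateral}, \code{control}),
#'   \code{trial}, \code{peak_pfj_bw}, \code{knee_angle_deg},
#'   \code{quad_force_bw}, \code{approach_velocity_ms}.
#' @export
generate_metric_cohort <- function(design, seed) {
  validate_cohort_design(design)
  metrics <- c("pfj", "angle", "quad")
  sdb <- unlist(design$sd_between[metrics])
  sdw <- unlist(design$sd_within[metrics])
  slope <- unlist(design$velocity_slope[metrics])
  vbar <- design_pooled_velocity(design)
  L <- chol(nearest_psd(design$metric_correlation))
  with_seed(seed, {
    rows <- list()
    emit <- function(pid, limb, b) {
      vc <- design$velocity_calibration[[limb]]
      mu <- design$limb_calibration[[limb]]
      mu <- c(mu$mu_pfj, mu$mu_angle, mu$mu_quad)
      for (tr in seq_len(design$trials_per_limb)) {
        v <- stats::rnorm(1, vc$mean, vc$sd)
        eps <- as.numeric(crossprod(L, stats::rnorm(3))) * sdw
        y <- mu + b + slope * (v - vbar) + eps
        rows[[length(rows) + 1L]] <<- data.frame(
          participant_id = pid, limb = limb, trial = tr,
          peak_pfj_bw = y[1], knee_angle_deg = y[2], quad_force_bw = y[3],
          approach_velocity_ms = v, stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(design$n_aclr)) {
      pid <- sprintf("A%03d", i)
      b <- stats::rnorm(3) * sdb       # shared by both limbs
      emit(pid, "ACLR", b)
      emit(pid, "contralateral", b)
    }
    for (i in seq_len(design$n_control)) {
      pid <- sprintf("C%03d", i)
      b <- stats::rnorm(3) * sdb
      emit(pid, "control", b)
    }
    do.call(rbind, rows)
  })
}

nearest_psd <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 1e-12)
  e$vectors %*% diag(v) %*% t(e$vectors)
}

#' Per-limb specification for the signal-level generator
#'
#' @param design a \code{\link{cohort_design}}.
#' @param limb one of \code{"ACLR"}, \code{"contralateral"},
#'   \code{"control"}.
#' @return list with the limb's waveform calibration (peak knee flexion,
#'   peak quadriceps force), velocity distribution and anthropometry.
#' @export
limb_spec_from_design <- function(design, limb = "ACLR") {
  limb <- match.arg(limb, c("ACLR", "contralateral", "control"))
  cal <- design$limb_calibration[[limb]]
  vc <- design$velocity_calibration[[limb]]
  list(limb = limb, angle_peak_deg = cal$mu_angle,
       quad_peak_bw = cal$mu_quad,
       velocity_mean = vc$mean, velocity_sd = vc$sd,
       mass_kg = design$anthropometry$mass_kg,
       height_m = design$anthropometry$height_m)
}

#' Stance waveform parameters for the signal-level generator
#'
#' Raised-cosine (Hann) joint-angle curves and a two-bump vertical GRF
#' template over a 0.25 s stance, sampled at 250 Hz (markers) and 1000 Hz
#' (GRF); bump centres/widths are fractions of stance duration. All values
#' are configurable; these defaults were frozen once so that mid-stance is
#' quadriceps-dominant (GRF line posterior to the knee).
#'
#' @return named list of waveform parameters.
#' @export
signal_waveform_defaults <- function() {
  list(stance_s = 0.25, pre_contact_s = 0.12,
       marker_rate = 250, grf_rate = 1000,
       knee_td_deg = 20, hip_td_deg = 25, hip_range_deg = 10,
       ankle_td_deg = -5, ankle_range_deg = 20, pelvis_tilt_deg = 5,
       pelvis_drop_m = 0.04, decel_fraction = 0.6,
       ankle_height_m = 0.09,
       fz_bumps = list(c(amp = 0.35, center = 0.12, width = 0.10),
                       c(amp = 1.00, center = 0.50, width = 0.32)),
       # anteroposterior shear as a smooth fraction of the vertical force
       # (braking early, mild propulsion late) so the GRF vector stays
       # physically coherent across stance
       fx_ratio_bumps = list(c(amp = -0.28, center = 0.35, width = 0.35),
                             c(amp = 0.12, center = 0.80, width = 0.25)),
       cop_offset_m = 0.02, cop_travel_m = 0.04)
}

hann01 <- function(u) 0.5 * (1 - cos(2 * pi * pmin(pmax(u, 0), 1)))
cos_bump <- function(u, center, width) {
  ifelse(abs(u - center) < width, 0.5 * (1 + cos(pi * (u - center) / width)), 0)
}

# pose trajectory (marker clock) for one synthetic trial; angles in deg
signal_pose_trajectory <- function(time, v, wf) {
  tc <- wf$pre_contact_s
  Tst <- wf$stance_s
  u <- pmin(pmax((time - tc) / Tst, 0), 1)
  h <- hann01(u)
  knee <- wf$knee_td_deg + (wf$angle_peak_deg - wf$knee_td_deg) * h
  hip <- wf$hip_td_deg + wf$hip_range_deg * h
  ankle <- wf$ankle_td_deg + wf$ankle_range_deg * h
  phi <- rep(wf$pelvis_tilt_deg, length(time))
  # pelvis advance: rigid translation at v before contact, smooth
  # deceleration to (1 - decel_fraction) v across stance
  tau <- pmin(pmax(time - tc, 0), Tst)
  px <- v * pmin(time, tc) + v * tau - wf$decel_fraction * v * tau^2 / (2 * Tst)
  py <- -wf$pelvis_drop_m * h
  data.frame(time = time, px = px, py = py, phi = phi,
             hip = hip, knee = knee, ankle = ankle)
}

# GRF template on the native clock; force in N for body weight bw_n
signal_grf_template <- function(time, wf, bw_n, scale, ankle_x_fun) {
  tc <- wf$pre_contact_s
  Tst <- wf$stance_s
  u <- (time - tc) / Tst
  inside <- u >= 0 & u <= 1
  fz <- rep(0, length(time))
  ratio <- rep(0, length(time))
  for (b in wf$fz_bumps) fz <- fz + b[["amp"]] * cos_bump(u, b[["center"]], b[["width"]])
  for (b in wf$fx_ratio_bumps) ratio <- ratio + b[["amp"]] * cos_bump(u, b[["center"]], b[["width"]])
  fz <- scale * bw_n * fz * inside
  fx <- ratio * fz
  cop <- ankle_x_fun(time) + wf$cop_offset_m + wf$cop_travel_m * pmin(pmax(u, 0), 1)
  cop[!inside] <- NA_real_
  data.frame(time = time, fx = fx, fy = fz, cop_x = cop)
}

#' Generate one signal-level synthetic cutting trial
#'
#' Emits a stance-phase trial with a pre-contact approach at a drawn
#' velocity: marker trajectories from planar forward kinematics (plus
#' Gaussian observation noise), a two-bump ground-reaction-force template
#' (zero before contact), and a fully populated ground truth. The ground
#' truth is self-consistent by construction: true net moments come from
#' inverse dynamics of the true kinematics, true muscle forces from static
#' optimization of those moments (so moments equal the moment-arm-weighted
#' force sum), and the true PFJ series from the patellar mechanism applied
#' to the true quadriceps force and knee angle. The GRF scale is
#' calibrated by a deterministic secant iteration so the true peak
#' quadriceps force equals the limb calibration value. Noise applies to
#' observations only; ground truth is noise-free.
#'
#' @param limb_spec from \code{\link{limb_spec_from_design}} (or a list
#'   with the same fields).
#' @param noise list with \code{marker_sd} (m) and \code{grf_sd} (N);
#'   nonnegative.
#' @param seed integer seed.
#' @param model optional pre-scaled \code{\link{planar_model}}.
#' @param mech a \code{patellar_mechanism}.
#' @param waveform waveform parameters, see
#'   \code{\link{signal_waveform_defaults}}.
#' @return list with \code{trial} (markers, native-rate GRF, metadata) and
#'   \code{truth} (poses, moments, muscle solution, quadriceps force (BW),
#'   PFJ series, COM trajectory, metrics, contact time, GRF scale).
#' @export
generate_signal_trial <- function(limb_spec, noise = list(marker_sd = 0.001,
                                                          grf_sd = 2),
                                  seed = 1, model = NULL,
                                  mech = patellar_mechanism(),
                                  waveform = signal_waveform_defaults()) {
  if ((noise$marker_sd %||% 0) < 0 || (noise$grf_sd %||% 0) < 0)
    stop("configuration error: noise SDs must be nonnegative")
  wf <- waveform
  wf$angle_peak_deg <- limb_spec$angle_peak_deg
  if (wf$stance_s <= 0) stop("configuration error: stance duration must be > 0")
  if (is.null(model))
    model <- planar_model(limb_spec$mass_kg, limb_spec$height_m)
  bw_n <- model$mass * model$g

  with_seed(seed, {
    v <- stats::rnorm(1, limb_spec$velocity_mean, limb_spec$velocity_sd)
    t_mark <- seq(0, wf$pre_contact_s + wf$stance_s, by = 1 / wf$marker_rate)
    t_grf <- seq(0, wf$pre_contact_s + wf$stance_s, by = 1 / wf$grf_rate)
    poses <- signal_pose_trajectory(t_mark, v, wf)
    # anchor pelvis height so the ankle sits near the ground at contact
    pose_c <- poses[which.min(abs(t_mark - wf$pre_contact_s)), ]
    chain_c <- fk_chain(model, unlist(pose_c[c("px", "py", "phi", "hip",
                                               "knee", "ankle")]))
    poses$py <- poses$py + (wf$ankle_height_m - chain_c$joints$ankle[2])

    ankle_x <- vapply(seq_len(nrow(poses)), function(i) {
      fk_chain(model, unlist(poses[i, c("px", "py", "phi", "hip", "knee",
                                        "ankle")]))$joints$ankle[1]
    }, 0)
    ankle_x_fun <- stats::approxfun(t_mark, ankle_x, rule = 2)

    true_kin <- kinematics_from_poses(poses)
    eval_peak_fq <- function(scale) {
      grf <- signal_grf_template(t_grf, wf, bw_n, scale, ankle_x_fun)
      truth_chain(grf, poses, true_kin, model, mech, wf)
    }
    target <- limb_spec$quad_peak_bw
    s0 <- 1; r0 <- eval_peak_fq(s0)
    s1 <- s0 * target / max(r0$peak_fq, 0.1)
    for (it in 1:10) {
      r1 <- eval_peak_fq(s1)
      if (abs(r1$peak_fq - target) < 0.02) break
      slope <- (r1$peak_fq - r0$peak_fq) / (s1 - s0)
      s0 <- s1; r0 <- r1
      s1 <- s1 + (target - r1$peak_fq) / slope
    }
    truth <- r1
    truth$scale <- s1
    truth$velocity <- v
    truth$contact_time <- detect_stance(truth$grf)$contact_time

    mk <- forward_markers(poses, model)
    if ((noise$marker_sd %||% 0) > 0)
      mk$xy <- mk$xy + stats::rnorm(length(mk$xy), 0, noise$marker_sd)
    grf_obs <- truth$grf
    if ((noise$grf_sd %||% 0) > 0) {
      stance_mask <- grf_obs$fy > 0
      grf_obs$fx <- grf_obs$fx + stats::rnorm(nrow(grf_obs), 0, noise$grf_sd) * stance_mask
      grf_obs$fy <- pmax(0, grf_obs$fy + stats::rnorm(nrow(grf_obs), 0, noise$grf_sd) * stance_mask)
    }
    list(trial = list(markers = mk, grf = grf_obs,
                      mass_kg = model$mass, height_m = model$height,
                      limb = limb_spec$limb, seed = seed),
         truth = truth)
  })
}

# build a joint_kinematics object directly from a pose table (generator use)
kinematics_from_poses <- function(poses) {
  dof <- c("px", "py", "phi", "hip", "knee", "ankle")
  pm <- as.matrix(poses[, dof])
  dt <- stats::median(diff(poses$time))
  ang <- pm[, c("hip", "knee", "ankle")]
  vel <- central_diff(ang, dt)
  structure(list(time = poses$time, pose = pm, angles = ang,
                 velocity = vel, acceleration = central_diff(vel, dt),
                 objective = rep(0, nrow(pm)),
                 interpolated = rep(FALSE, nrow(pm)), rate = 1 / dt),
            class = "joint_kinematics")
}

# shared truth computation: ID -> SO -> PFJ -> metrics on noiseless signals
truth_chain <- function(grf, poses, true_kin, model, mech, wf) {
  grf_mark <- align_grf_to_markers(grf, poses$time)
  moments <- inverse_dynamics(true_kin, grf_mark, model, grf_cutoff = NULL)
  st_native <- detect_stance(grf)
  stance_idx <- which(poses$time >= st_native$contact_time - 1e-9 &
                      poses$time <= st_native$toe_off_time + 1e-9)
  sol <- static_optimization(moments, true_kin, model)
  fq_bw <- quadriceps_force(sol, model$mass, model$g)
  pfj <- pfj_series(fq_bw, true_kin, mech)
  com <- t(vapply(seq_len(nrow(poses)), function(i) {
    fk_model_com(model, unlist(poses[i, c("px", "py", "phi", "hip", "knee",
                                          "ankle")]))
  }, c(0, 0)))
  com <- data.frame(time = poses$time, x = com[, 1], y = com[, 2])
  vel <- approach_velocity(com, st_native$contact_time)
  met <- extract_metrics(pfj, true_kin, stance_idx, vel,
                         feasible = sol$feasible)
  list(poses = poses, grf = grf, moments = moments, muscles = sol,
       f_q_bw = fq_bw, pfj = pfj, com = com, metrics = met,
       stance_idx = stance_idx, peak_fq = met$quad_at_peak)
}
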