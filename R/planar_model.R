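#' Build a planar four-segment limb model
#'
#' Constructs the sagittal-plane chain pelvis+HAT -> thigh -> shank -> foot
#' used throughout the pipeline, scaled to a participant's anthropometry.
#' Segment lengths scale with stature, segment masses and muscle strengths
#' with body mass; COM fractions and mass fractions are preserved under
#' scaling. Pose coordinates are \code{(px, py, phi, hip, knee, ankle)}:
#' pelvis (= hip joint) position in metres, pelvis tilt and joint angles in
#' degrees. Conventions: approach direction +x, up +y; hip flexion and
#' ankle dorsiflexion positive; knee flexion positive with 0 at full
#' extension. In the reference pose (all angles zero) the thigh and shank
#' hang vertically and the foot points forward horizontally.
#'
#' @param mass_kg participant body mass (kg).
#' @param height_m participant stature (m).
#' @param defaults path to a planar-model defaults JSON file.
#' @return an object of class \code{planar_model}.
#' @export
planar_model <- function(mass_kg = NULL, height_m = NULL,
                         defaults = default_file("model")) {
  d <- read_defaults_json(defaults)
  ref <- d$reference_anthropometry
  mass_kg <- mass_kg %||% ref$mass_kg
  height_m <- height_m %||% ref$height_m
  if (!is.numeric(mass_kg) || mass_kg <= 0)
    stop("configuration error: mass_kg must be > 0")
  if (!is.numeric(height_m) || height_m <= 0)
    stop("configuration error: height_m must be > 0")
  hscale <- height_m / ref$height_m

  segs <- list()
  s <- d$segments
  for (nm in c("thigh", "shank", "foot")) {
    p <- s[[nm]]
    len <- p$length_fraction * height_m
    m <- p$mass_fraction * mass_kg
    rog <- p$rog_fraction * len
    segs[[nm]] <- list(length = len, mass = m, com_fraction = p$com_fraction,
                       inertia = m * rog^2)
  }
  ph <- s$pelvis_hat
  segs$pelvis_hat <- list(
    mass = ph$mass_fraction * mass_kg,
    com_local = unlist(ph$com_local) * hscale,
    inertia = ph$mass_fraction * mass_kg * (ph$rog_m * hscale)^2)

  mk <- d$markers
  markers <- data.frame(
    name = names(mk),
    segment = vapply(mk, function(x) x$segment, ""),
    ox = vapply(mk, function(x) x$offset[1], 0) * hscale,
    oy = vapply(mk, function(x) x$offset[2], 0) * hscale,
    weight = vapply(mk, function(x) x$weight %||% 1, 0),
    stringsAsFactors = FALSE)
  rownames(markers) <- NULL

  muscles <- lapply(seq_len(nrow(d$muscles)), function(i) {
    row <- d$muscles[i, ]
    arms <- row$arms
    arms <- lapply(as.list(arms), function(cc) {
      cc <- unlist(cc)
      if (is.null(cc) || all(is.na(cc))) NULL else cc[!is.na(cc)]
    })
    arms <- arms[!vapply(arms, is.null, TRUE)]
    list(name = row$name, f_max = row$f_max * mass_kg / ref$mass_kg,
         group = row$group, is_quadriceps = isTRUE(row$is_quadriceps),
         arms = arms)
  })
  names(muscles) <- vapply(muscles, `[[`, "", "name")

  model <- structure(list(
    version = d$version, mass = mass_kg, height = height_m,
    g = d$gravity %||% 9.81,
    segments = segs, markers = markers, muscles = muscles,
    joint_limits = d$joint_limits_deg,
    joint_names = c("hip", "knee", "ankle")), class = "planar_model")
  validate_planar_model(model)
  model
}

validate_planar_model <- function(model) {
  for (nm in c("thigh", "shank", "foot")) {
    s <- model$segments[[nm]]
    if (s$length <= 0 || s$mass <= 0)
      stop("model error: segment ", nm, " must have positive length and mass")
    if (s$com_fraction < 0 || s$com_fraction > 1)
      stop("model error: segment ", nm, " COM fraction outside [0,1]")
  }
  if (any(model$markers$weight < 0))
    stop("model error: marker weights must be nonnegative")
  if (sum(model$markers$weight > 0) < 6)
    stop("model error: need at least 6 positively weighted markers for 6 DOF")
  if (length(model$muscles) > 0) {
    for (m in model$muscles) {
      if (m$f_max <= 0) stop("model error: f_max must be > 0 for ", m$name)
    }
  }
  invisible(model)
}

#' @export
print.planar_model <- function(x, ...) {
  cat("planar_model (v", x$version, "): mass ", x$mass, " kg, height ",
      x$height, " m\n", sep = "")
  cat("  segments: pelvis_hat + thigh/shank/foot;",
      nrow(x$markers), "markers;", length(x$muscles), "muscles\n")
  invisible(x)
}

DEG <- pi / 180

# segment frame rotations (deg) for a pose; names match segments
segment_rotations <- function(pose) {
  c(pelvis_hat = pose[["phi"]],
    thigh = pose[["phi"]] + pose[["hip"]],
    shank = pose[["phi"]] + pose[["hip"]] - pose[["knee"]],
    foot = pose[["phi"]] + pose[["hip"]] - pose[["knee"]] + pose[["ankle"]])
}

rot2 <- function(deg) {
  a <- deg * DEG
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# unit vector along a long-axis direction angle measured CCW from -y (deg)
uvec <- function(deg) {
  a <- deg * DEG
  c(sin(a), -cos(a))
}

# forward kinematics: joint centers and segment frames for one pose
fk_chain <- function(model, pose) {
  rot <- segment_rotations(pose)
  hip <- c(pose[["px"]], pose[["py"]])
  knee <- hip + model$segments$thigh$length * uvec(rot[["thigh"]])
  ankle <- knee + model$segments$shank$length * uvec(rot[["shank"]])
  toe <- ankle + model$segments$foot$length * uvec(rot[["foot"]] + 90)
  origins <- list(pelvis_hat = hip, thigh = hip, shank = knee, foot = ankle)
  list(rot = rot, origins = origins,
       joints = list(hip = hip, knee = knee, ankle = ankle, toe = toe))
}

# marker positions for one pose: named 2-column matrix (x, y)
fk_markers_pose <- function(model, pose, chain = fk_chain(model, pose)) {
  mk <- model$markers
  out <- matrix(NA_real_, nrow(mk), 2, dimnames = list(mk$name, c("x", "y")))
  for (seg in unique(mk$segment)) {
    idx <- which(mk$segment == seg)
    R <- rot2(chain$rot[[seg]])
    o <- chain$origins[[seg]]
    off <- t(R %*% rbind(mk$ox[idx], mk$oy[idx]))
    out[idx, ] <- sweep(off, 2, -o)
  }
  out
}

# per-segment COM positions for one pose
fk_segment_coms <- function(model, pose, chain = fk_chain(model, pose)) {
  s <- model$segments
  com <- matrix(NA_real_, 4, 2,
                dimnames = list(c("pelvis_hat", "thigh", "shank", "foot"),
                                c("x", "y")))
  com["pelvis_hat", ] <- chain$origins$pelvis_hat +
    as.numeric(rot2(chain$rot[["pelvis_hat"]]) %*% s$pelvis_hat$com_local)
  com["thigh", ] <- chain$origins$thigh +
    s$thigh$com_fraction * s$thigh$length * uvec(chain$rot[["thigh"]])
  com["shank", ] <- chain$origins$shank +
    s$shank$com_fraction * s$shank$length * uvec(chain$rot[["shank"]])
  com["foot", ] <- chain$origins$foot +
    s$foot$com_fraction * s$foot$length * uvec(chain$rot[["foot"]] + 90)
  com
}

segment_masses <- function(model) {
  vapply(model$segments[c("pelvis_hat", "thigh", "shank", "foot")],
         `[[`, 0, "mass")[c("pelvis_hat", "thigh", "shank", "foot")]
}

# whole-model COM for one pose
fk_model_com <- function(model, pose) {
  com <- fk_segment_coms(model, pose)
  m <- segment_masses(model)
  colSums(com * m) / sum(m)
}

#' Evaluate muscle moment arms at a joint configuration
#'
#' Returns the 3 x n_muscles matrix of signed moment arms (m) in the
#' conjugate convention (hip flexion +, knee flexion +, ankle
#' dorsiflexion +) at joint angles \code{theta_deg}. A muscle that does
#' not span a joint has a zero entry.
#'
#' @param model a \code{planar_model}.
#' @param theta_deg named numeric: hip, knee, ankle angles in degrees.
#' @return numeric matrix with rows \code{hip}, \code{knee}, \code{ankle}.
#' @export
moment_arm_matrix <- function(model, theta_deg) {
  joints <- model$joint_names
  R <- matrix(0, 3, length(model$muscles),
              dimnames = list(joints, names(model$muscles)))
  for (i in seq_along(model$muscles)) {
    mu <- model$muscles[[i]]
    for (j in names(mu$arms)) {
      th <- theta_deg[[j]]
      cc <- mu$arms[[j]]
      R[j, i] <- sum(cc * th^(seq_along(cc) - 1))
    }
  }
  R
}
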