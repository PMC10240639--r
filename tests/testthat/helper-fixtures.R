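# shared fixtures and independent oracles, built in code at test time

ref_model <- function() planar_model(71.4, 1.73)

# a smooth multi-frame pose trajectory within joint limits
smooth_poses <- function(n = 40, rate = 250) {
  t <- seq(0, (n - 1) / rate, by = 1 / rate)
  data.frame(time = t, px = 0.5 * t, py = 0.9 + 0.01 * sin(12 * t),
             phi = 5 + 2 * sin(7 * t), hip = 30 + 12 * sin(9 * t),
             knee = 25 + 20 * (1 - cos(20 * t)) / 2,
             ankle = -5 + 8 * sin(11 * t))
}

# independent polynomial evaluation (direct powers; no shared code path)
poly_oracle <- function(coeffs, x) {
  sum(coeffs * x^(seq_along(coeffs) - 1))
}

# hierarchical dense grid search over (hip, knee, ankle) for one frame,
# centred on the true angles, final resolution 0.01 deg; root DOFs fixed
ik_grid_oracle <- function(model, obs, weights, truth, fixed_root) {
  center <- truth
  best <- NULL
  for (lv in list(c(3, 0.5), c(0.6, 0.1), c(0.06, 0.01))) {
    gr <- expand.grid(
      hip = seq(center[1] - lv[1], center[1] + lv[1], by = lv[2]),
      knee = seq(center[2] - lv[1], center[2] + lv[1], by = lv[2]),
      ankle = seq(center[3] - lv[1], center[3] + lv[1], by = lv[2]))
    f <- vapply(seq_len(nrow(gr)), function(i) {
      pose <- c(px = fixed_root[["px"]], py = fixed_root[["py"]],
                phi = fixed_root[["phi"]], hip = gr$hip[i], knee = gr$knee[i],
                ankle = gr$ankle[i])
      pfjload:::ik_objective(model, pose, obs, weights)
    }, 0)
    k <- which.min(f)
    center <- c(gr$hip[k], gr$knee[k], gr$ankle[k])
    best <- f[k]
  }
  list(objective = best, angles = center)
}

# brute-force grid search for the 3-muscle single-joint static optimization
so_grid_oracle <- function(fr, M, res = 1e-3) {
  a1 <- seq(0, 1, by = res)
  a2 <- seq(0, 1, by = res)
  g <- expand.grid(a1 = a1, a2 = a2)
  a3 <- (M - g$a1 * fr[1] - g$a2 * fr[2]) / fr[3]
  ok <- a3 >= -1e-12 & a3 <= 1 + 1e-12
  g <- g[ok, ]; a3 <- pmin(1, pmax(0, a3[ok]))
  obj <- g$a1^2 + g$a2^2 + a3^2
  k <- which.min(obj)
  c(g$a1[k], g$a2[k], a3[k])
}

# static planar equilibrium oracle: moments about each joint from distal
# segment weights and the GRF, written independently of the package's
# Newton-Euler recursion (valid for zero velocity/acceleration only)
static_moment_oracle <- function(model, pose, grf_vec, cop_x) {
  chain <- pfjload:::fk_chain(model, pose)
  coms <- pfjload:::fk_segment_coms(model, pose, chain)
  masses <- pfjload:::segment_masses(model)
  g <- model$g
  cross <- function(r, f) r[1] * f[2] - r[2] * f[1]
  mz <- function(joint, segs) {
    jp <- chain$joints[[joint]]
    tot <- cross(c(cop_x, 0) - jp, grf_vec)
    for (s in segs) tot <- tot + cross(coms[s, ] - jp, c(0, -masses[s] * g))
    -tot   # internal moment balances the external sum
  }
  c(hip = mz("hip", c("thigh", "shank", "foot")),
    knee = mz("knee", c("shank", "foot")),
    ankle = mz("ankle", "foot"))
}

aclr_design <- function(...) cohort_design(...)

quiet_fit <- function(...) suppressWarnings(fit_limb_model(...))
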