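test_that("forward markers are rigid within segments over time", {
  m <- ref_model()
  mk <- forward_markers(smooth_poses(60), m)
  pairs <- list(c("THI", "KNEE"), c("TIB", "ANKLE"), c("HEEL", "TOE"),
                c("SACR", "ASIS"))
  for (p in pairs) {
    d <- sqrt(rowSums((mk$xy[, p[1], ] - mk$xy[, p[2], ])^2))
    expect_lt(diff(range(d)), 1e-9)
  }
})

test_that("joint limits are enforced by forward kinematics", {
  m <- ref_model()
  p <- smooth_poses(5)
  p$knee <- -10
  expect_error(forward_markers(p, m), "joint limits")
})

test_that("noiseless IK round trip recovers the generating angles", {
  m <- ref_model()
  poses <- smooth_poses(40)
  mk <- forward_markers(poses, m)
  kin <- inverse_kinematics(mk, m, filter_cutoff = NULL)
  expect_lt(max(abs(kin$angles - as.matrix(poses[, c("hip", "knee", "ankle")]))),
            1e-6)
  # objective at the solution never exceeds the generating-pose objective
  expect_true(all(kin$objective <= 1e-10))
  # velocity/acceleration consistent with central differences of angles
  dt <- 1 / 250
  vel_oracle <- pfjload:::central_diff(kin$angles, dt)
  expect_equal(kin$velocity, vel_oracle, tolerance = 1e-12)
})

test_that("a zero-weight marker has no influence on the solution", {
  m <- ref_model()
  poses <- smooth_poses(8)
  mk <- forward_markers(poses, m)
  mk$xy[, "THI2", ] <- mk$xy[, "THI2", ] + 0.5  # arbitrary displacement
  kin0 <- inverse_kinematics(mk, m, weights = list(THI2 = 0),
                             filter_cutoff = NULL)
  expect_lt(max(abs(kin0$angles - as.matrix(poses[, c("hip", "knee", "ankle")]))),
            1e-6)
})

test_that("single-frame IK matches a dense grid-search oracle", {
  m <- ref_model()
  truth <- c(hip = 32, knee = 48, ankle = 6)
  pose_t <- data.frame(time = 0, px = 0.2, py = 0.9, phi = 4,
                       hip = truth[1], knee = truth[2], ankle = truth[3])
  mk <- forward_markers(pose_t, m)
  set.seed(42)
  mk$xy <- mk$xy + rnorm(length(mk$xy), 0, 0.001)  # 1 mm isotropic noise
  w <- setNames(m$markers$weight, m$markers$name)
  obs <- mk$xy[1, , ]
  root <- c(px = 0.2, py = 0.9, phi = 4)
  kin <- inverse_kinematics(mk, m, filter_cutoff = NULL,
                            fixed = as.list(root),
                            init = as.list(c(root, truth)))
  oracle <- ik_grid_oracle(m, obs, w, truth, root)
  expect_lt(kin$objective[1], oracle$objective + 1e-8)
})

test_that("long marker gaps reject the trial, short gaps interpolate", {
  m <- ref_model()
  poses <- smooth_poses(40)
  mk <- forward_markers(poses, m)
  mk2 <- mk
  mk2$xy[10:12, , ] <- NA  # 3-frame full dropout
  kin <- inverse_kinematics(mk2, m, filter_cutoff = NULL)
  expect_true(all(kin$interpolated[10:12]))
  expect_lt(max(abs(kin$angles[5, ] - as.matrix(poses[5, c("hip", "knee", "ankle")]))), 1e-6)
  mk3 <- mk
  mk3$xy[10:25, , ] <- NA  # 16-frame gap exceeds the 10-frame limit
  expect_error(inverse_kinematics(mk3, m, filter_cutoff = NULL), "gap error")
})

test_that("stance detection implements the 20 N raw-force rule", {
  st <- detect_stance(c(15, 25, 30, 18), threshold = 20)
  expect_equal(st$contact_index, 2L)
  expect_equal(st$toe_off_index, 3L)
  # saturation: all samples above threshold
  st2 <- detect_stance(rep(100, 7))
  expect_equal(c(st2$contact_index, st2$toe_off_index), c(1L, 7L))
  # degenerate inputs
  expect_error(detect_stance(rep(0, 10)), "no-stance")
  expect_error(detect_stance(c(1, 30, 2), threshold = -5), "threshold")
  # invariance to samples outside the stance bout
  f <- c(rep(0, 5), 25, 40, 25, rep(0, 5))
  st3 <- detect_stance(f)
  st4 <- detect_stance(c(rep(0, 3), f))
  expect_equal(st4$contact_index - st3$contact_index, 3L)
  expect_equal(st4$toe_off_index - st3$toe_off_index, 3L)
})

test_that("approach velocity matches analytic and trapezoidal oracles", {
  t <- seq(0, 0.3, by = 1 / 200)  # grid contains the window edges exactly
  # constant 4 m/s
  com <- data.frame(time = t, x = 4 * t)
  expect_equal(as.numeric(approach_velocity(com, 0.3)), 4, tolerance = 1e-9)
  # stationary
  expect_equal(as.numeric(approach_velocity(data.frame(time = t, x = 0 * t), 0.3)),
               0, tolerance = 1e-12)
  # linear deceleration 4 -> 3 m/s over the final 100 ms
  decel <- function(tt) ifelse(tt < 0.2, 4, 4 - 10 * (tt - 0.2))
  x <- cumsum(c(0, (decel(head(t, -1)) + decel(tail(t, -1))) / 2 * diff(t)))
  com2 <- data.frame(time = t, x = x)
  v <- approach_velocity(com2, 0.3, window = 0.05)
  # trapezoidal oracle on the sampled velocity profile over the window
  tw <- t[t >= 0.25]
  vw <- decel(tw)
  oracle <- sum(diff(tw) * (head(vw, -1) + tail(vw, -1)) / 2) / 0.05
  expect_equal(as.numeric(v), oracle, tolerance = 1e-3)
  # invariance to rigid translation of the coordinate origin
  com3 <- transform(com2, x = x + 17.3)
  expect_equal(as.numeric(approach_velocity(com3, 0.3, 0.05)),
               as.numeric(v), tolerance = 1e-12)
  # insufficient history
  expect_error(approach_velocity(com2[t > 0.28, ], 0.3, window = 0.05),
               "insufficient-history")
})

test_that("time normalization is linear interpolation onto 101 samples", {
  t <- seq(0, 1, by = 1 / 250)
  const <- time_normalize(rep(3.3, length(t)), t, c(0.2, 0.8))
  expect_equal(as.numeric(const), rep(3.3, 101))
  ramp <- time_normalize(2 * t, t, c(0.2, 0.8))
  expect_equal(ramp[c(1, 101)], c(0.4, 1.6), tolerance = 1e-9)
  expect_equal(as.numeric(ramp), seq(0.4, 1.6, length.out = 101),
               tolerance = 1e-9)
  sine <- time_normalize(sin(2 * pi * 3 * t), t, c(0.1, 0.9))
  tq <- seq(0.1, 0.9, length.out = 101)
  expect_lt(max(abs(sine - sin(2 * pi * 3 * tq))), 1e-3)
  expect_error(time_normalize(t, t, c(-0.5, 0.5)), "bounds error")
  expect_error(time_normalize(t, t, c(0.5, 0.2)), "bounds error")
})

test_that("GRF downsampling matches hand-computed window averages", {
  tg <- seq(0, 0.02, by = 1e-3)   # 21 samples at 1000 Hz
  grf <- data.frame(time = tg, fy = seq_along(tg))  # values 1..21
  tm <- c(0.004, 0.012)           # marker clock, 8 ms spacing
  out <- align_grf_to_markers(grf, tm)
  # half-window 4 ms: bin 1 covers [0, 8) ms -> samples 1..8,
  # bin 2 covers [8, 16) ms -> samples 9..16 (index-arithmetic oracle)
  expect_equal(out$fy, c(mean(1:8), mean(9:16)))
  expect_equal(nrow(out), 2L)
})

test_that("zero-lag low-pass has the expected gain and no phase lag", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)
  # DC passes untouched
  expect_equal(low_pass(rep(2.5, length(t)), fs, 12), rep(2.5, length(t)),
               tolerance = 1e-9)
  # at the single-pass cutoff the double pass attenuates to ~0.5
  x <- sin(2 * pi * 12 * t)
  y <- low_pass(x, fs, 12)
  mid <- t > 1 & t < 3
  expect_equal(max(abs(y[mid])), 0.5, tolerance = 0.03)
  # zero lag: peak of a slow sine is not shifted
  xs <- sin(2 * pi * 1 * t)
  ys <- low_pass(xs, fs, 12)
  expect_equal(which.max(ys[mid]), which.max(xs[mid]))
  expect_error(low_pass(x, fs, 200), "cutoff")
})
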