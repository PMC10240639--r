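test_that("design validation names the offending field", {
  expect_error(cohort_design(n_aclr = 1), "n_aclr")
  expect_error(cohort_design(trials_per_limb = 0), "trials_per_limb")
  expect_error(cohort_design(sd_between = list(pfj = -1)), "sd_between")
  expect_error(cohort_design(metric_correlation = matrix(c(1, 2, 2, 1), 2)),
               "metric_correlation")
  expect_error(cohort_design(bogus_field = 3), "unknown design field")
})

test_that("zero-variance zero-slope design reproduces the calibration exactly", {
  des <- cohort_design(sd_between = list(pfj = 0, angle = 0, quad = 0),
                       sd_within = list(pfj = 0, angle = 0, quad = 0),
                       velocity_slope = list(pfj = 0, angle = 0, quad = 0))
  tab <- generate_metric_cohort(des, 4)
  aclr <- tab[tab$limb == "ACLR", ]
  expect_true(all(aclr$peak_pfj_bw == 12.7))
  expect_true(all(aclr$knee_angle_deg == 52))
  expect_true(all(aclr$quad_force_bw == 10.9))
  ctrl <- tab[tab$limb == "control", ]
  expect_true(all(ctrl$peak_pfj_bw == 17.1))
  expect_equal(nrow(tab), (26 * 2 + 22) * 3)
})

test_that("metric generation is seed-deterministic", {
  des <- cohort_design()
  expect_identical(generate_metric_cohort(des, 11),
                   generate_metric_cohort(des, 11))
  expect_false(identical(generate_metric_cohort(des, 11),
                         generate_metric_cohort(des, 12)))
})

test_that("large-cohort ACLR mean matches the generator's own calibration", {
  des <- cohort_design(n_aclr = 2000, n_control = 2)
  tab <- generate_metric_cohort(des, 8)
  aclr <- tab[tab$limb == "ACLR", ]
  # law-of-large-numbers oracle: the raw ACLR mean includes the velocity
  # slope times the limb's offset from the design pooled mean velocity
  vbar <- design_pooled_velocity(des)
  expected <- 12.7 + 1.5 * (3.7 - vbar)
  sdb <- 3.4; sdw <- 1.7; slope <- 1.5; vsd <- 0.6
  var_mean <- (sdb^2 + (sdw^2 + slope^2 * vsd^2) / 3) / 2000
  expect_lt(abs(mean(aclr$peak_pfj_bw) - expected), 3 * sqrt(var_mean))
})

test_that("between-participant SD of participant means approaches sd_between", {
  des <- cohort_design(n_aclr = 2000, n_control = 2)
  tab <- generate_metric_cohort(des, 9)
  aclr <- tab[tab$limb == "ACLR", ]
  pm <- tapply(aclr$peak_pfj_bw, aclr$participant_id, mean)
  expect_lt(abs(sd(pm) - 3.4) / 3.4, 0.10)
})

test_that("paired limbs of one participant are positively correlated", {
  des <- cohort_design(n_aclr = 500, n_control = 2)
  tab <- generate_metric_cohort(des, 13)
  pm <- tapply(tab$peak_pfj_bw, list(tab$participant_id, tab$limb), mean)
  aclr_ids <- grep("^A", rownames(pm), value = TRUE)
  r <- cor(pm[aclr_ids, "ACLR"], pm[aclr_ids, "contralateral"])
  expect_gt(r, 0)
})

test_that("signal trial calibrates to the stated operating point", {
  des <- cohort_design()
  spec <- limb_spec_from_design(des, "ACLR")
  sim <- generate_signal_trial(spec, noise = list(marker_sd = 0, grf_sd = 0),
                               seed = 5)
  met <- sim$truth$metrics
  expect_equal(met$quad_at_peak, 10.9, tolerance = 0.02)
  expect_equal(met$angle_at_peak, 52, tolerance = 1.0)
  # sampled maximum of the Hann curve; the analytic peak (52) can fall
  # between marker samples
  expect_equal(max(sim$truth$poses$knee), 52, tolerance = 1e-3)
  # self-consistency: moments equal the moment-arm-weighted force sums
  expect_lt(max(sim$truth$muscles$residual), 1e-6)
  # true PFJ equals the mechanism evaluated on true inputs at every sample
  mech <- patellar_mechanism()
  redo <- pfj_series(sim$truth$f_q_bw,
                     sim$truth$poses$knee, mech)$series$f_pfj
  expect_equal(sim$truth$pfj$series$f_pfj, redo, tolerance = 1e-12)
})

test_that("noise applies to observations only, ground truth is shared", {
  des <- cohort_design()
  spec <- limb_spec_from_design(des, "ACLR")
  spec$velocity_sd <- 0  # freeze the drawn velocity so truth is comparable
  s1 <- generate_signal_trial(spec, seed = 31)
  s2 <- generate_signal_trial(spec, seed = 32)
  expect_equal(s1$truth$poses, s2$truth$poses, tolerance = 1e-12)
  expect_equal(s1$truth$metrics$peak_pfj, s2$truth$metrics$peak_pfj,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s1$trial$markers$xy, s2$trial$markers$xy)))
  # same seed is byte-identical
  expect_identical(generate_signal_trial(spec, seed = 31)$trial$markers$xy,
                   s1$trial$markers$xy)
})

test_that("negative noise SDs are rejected", {
  spec <- limb_spec_from_design(cohort_design(), "ACLR")
  expect_error(generate_signal_trial(spec, noise = list(marker_sd = -1,
                                                        grf_sd = 0)),
               "noise")
})
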