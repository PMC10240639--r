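mk_pfj <- function(f_pfj, f_q = f_pfj / 1.2) {
  n <- length(f_pfj)
  structure(list(series = data.frame(time = seq_len(n) / 250, f_q = f_q,
                                     f_p = 0.8 * f_q, beta = 100,
                                     f_pfj = f_pfj, clamped = FALSE),
                 mechanism_version = "test"), class = "pfj_force_series")
}

mk_kin <- function(n, knee = seq(20, 60, length.out = n)) {
  ang <- cbind(hip = rep(30, n), knee = knee, ankle = rep(0, n))
  structure(list(time = seq_len(n) / 250, angles = ang),
            class = "joint_kinematics")
}

test_that("peak extraction: monotone series, ties, and flag exclusion", {
  n <- 11
  kin <- mk_kin(n)
  inc <- mk_pfj(seq(1, 5, length.out = n))
  m <- extract_metrics(inc, kin, seq_len(n), velocity = 4)
  expect_equal(m$peak_time_pct, 100)
  expect_equal(m$peak_pfj, 5)
  expect_equal(m$angle_at_peak, 60)
  # exact tie: earliest sample reported
  tie <- mk_pfj(c(1, 7, 3, 7, 2, rep(1, 6)))
  mt <- extract_metrics(tie, kin, seq_len(n), velocity = 4)
  expect_equal(mt$peak_time_pct, 10)
  # flagged samples excluded from the peak
  flags <- rep(TRUE, n); flags[2] <- FALSE
  mf <- extract_metrics(tie, kin, seq_len(n), velocity = 4, feasible = flags)
  expect_equal(mf$peak_time_pct, 30)
  expect_equal(mf$n_flagged, 1)
  expect_error(extract_metrics(tie, kin, seq_len(n), 4,
                               feasible = rep(FALSE, n)),
               "metrics-unavailable")
  expect_error(extract_metrics(tie, kin, integer(0), 4), "stance")
  expect_error(extract_metrics(tie, kin, 1:3, 4, limb = "left"), "limb")
})

test_that("degenerate no-noise fit returns the group constants exactly", {
  des <- cohort_design(sd_between = list(pfj = 0, angle = 0, quad = 0),
                       sd_within = list(pfj = 0, angle = 0, quad = 0))
  tab <- generate_metric_cohort(des, 3)
  f <- quiet_fit(tab, "peak_pfj")
  # slope removes all velocity-induced variation, leaving the constants
  expect_equal(f$marginal_means$emmean[1] -
                 f$fixed_effects$estimate[4] * (f$pooled_velocity -
                                                design_pooled_velocity(des)),
               12.7, tolerance = 1e-6)
  expect_equal(f$fixed_effects$estimate[4], 1.5, tolerance = 1e-6)
  expect_true(all(f$contrasts$p_adj < 1e-6))
})

test_that("pairwise contrasts equal differences of marginal means", {
  tab <- generate_metric_cohort(cohort_design(), 17)
  f <- quiet_fit(tab, "quad_at_peak")
  mm <- setNames(f$marginal_means$emmean, f$marginal_means$limb)
  expect_equal(f$contrasts$estimate[f$contrasts$contrast == "ACLR - contralateral"],
               unname(mm["ACLR"] - mm["contralateral"]), tolerance = 1e-10)
  expect_equal(f$contrasts$estimate[f$contrasts$contrast == "contralateral - control"],
               unname(mm["contralateral"] - mm["control"]), tolerance = 1e-10)
})

test_that("with one trial and no participant variance the fit matches OLS", {
  des <- cohort_design(trials_per_limb = 1,
                       sd_between = list(pfj = 0, angle = 0, quad = 0))
  tab <- generate_metric_cohort(des, 23)
  f <- quiet_fit(tab, "peak_pfj")
  ols <- lm(peak_pfj_bw ~ factor(limb, levels = c("ACLR", "contralateral",
                                                  "control")) +
              approach_velocity_ms, data = tab)
  expect_equal(unname(f$fixed_effects$estimate), unname(coef(ols)),
               tolerance = 1e-6)
  expect_true(f$singular)
})

test_that("marginal-mean CIs widen with residual variance at fixed design", {
  des <- cohort_design()
  base <- generate_metric_cohort(des, 29)
  f1 <- quiet_fit(base, "peak_pfj")
  # scale the trial-level residuals around participant-limb means by 3x
  pl <- interaction(base$participant_id, base$limb)
  mu <- ave(base$peak_pfj_bw, pl)
  noisy <- base
  noisy$peak_pfj_bw <- mu + 3 * (base$peak_pfj_bw - mu)
  f2 <- quiet_fit(noisy, "peak_pfj")
  w1 <- f1$marginal_means$upper - f1$marginal_means$lower
  w2 <- f2$marginal_means$upper - f2$marginal_means$lower
  expect_true(all(w2 > w1))
})

test_that("identically generated groups keep Tukey p above 0.05", {
  # type-I behaviour: contralateral calibrated identically to ACLR
  des <- cohort_design(
    n_aclr = 200, n_control = 4,
    limb_calibration = list(contralateral = list(mu_pfj = 12.7, mu_angle = 52,
                                                 mu_quad = 10.9)),
    velocity_calibration = list(contralateral = list(mean = 3.7, sd = 0.6)))
  nrep <- 100
  ps <- vapply(seq_len(nrep), function(s) {
    tab <- generate_metric_cohort(des, 1000 + s)
    f <- quiet_fit(tab, "peak_pfj")
    f$contrasts$p_adj[f$contrasts$contrast == "ACLR - contralateral"]
  }, 0)
  expect_gte(mean(ps > 0.05), 0.90)
})

test_that("velocity adjustment removes the confounded-velocity bias", {
  # constructed instance with strongly group-confounded velocities and a
  # steep slope, so the raw group mean is visibly biased
  des <- cohort_design(
    n_aclr = 200, n_control = 4,
    velocity_calibration = list(ACLR = list(mean = 3.0, sd = 0.5),
                                contralateral = list(mean = 4.0, sd = 0.5),
                                control = list(mean = 4.5, sd = 0.5)),
    velocity_slope = list(pfj = 3.0, angle = 1.0, quad = 1.0))
  nrep <- 100
  est <- vapply(seq_len(nrep), function(s) {
    tab <- generate_metric_cohort(des, 2000 + s)
    f <- quiet_fit(tab, "peak_pfj")
    raw <- mean(tab$peak_pfj_bw[tab$limb == "ACLR"])
    c(adj = f$marginal_means$emmean[1], raw = raw)
  }, c(0, 0))
  bias_adj <- abs(mean(est["adj", ]) - 12.7)
  bias_raw <- abs(mean(est["raw", ]) - 12.7)
  expect_gt(bias_raw, 0.5)            # raw means are visibly confounded
  expect_gt(1 - bias_adj / bias_raw, 0.75)
})

test_that("the estimated velocity slope recovers the generator's slope", {
  des <- cohort_design(n_aclr = 500, n_control = 4)
  tab <- generate_metric_cohort(des, 37)
  f <- quiet_fit(tab, "peak_pfj")
  slope <- f$fixed_effects$estimate[f$fixed_effects$term == "v"]
  se <- f$fixed_effects$se[f$fixed_effects$term == "v"]
  expect_lt(abs(slope - 1.5), 3 * se)
})

test_that("compare_all assembles the 3x3 report and validates input", {
  tab <- generate_metric_cohort(cohort_design(), 41)
  rep <- suppressWarnings(compare_all(tab))
  expect_s3_class(rep, "limb_report")
  expect_equal(dim(rep$summary), c(9L, 5L))
  expect_setequal(unique(rep$summary$limb),
                  c("ACLR", "contralateral", "control"))
  one <- suppressWarnings(compare_all(tab, outcomes = "angle_at_peak"))
  expect_length(one$results, 1L)
  expect_error(compare_all(tab[0, ]), "empty")
  expect_error(fit_limb_model(tab, "bogus"), "unknown outcome")
  few <- tab[tab$participant_id %in% c("A001", "C001", "C002") |
               tab$limb == "control", ]
  expect_error(quiet_fit(few, "peak_pfj"), "rank-deficient")
})
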