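{
  "version": "1.0",
  "notes": [
    "Default calibration for the synthetic side-step-cut cohort.",
    "limb_calibration mu values are the published velocity-adjusted group",
    "marginal means used as recovery targets: peak PFJ force (BW), knee",
    "flexion angle at peak (deg), quadriceps force at peak (BW).",
    "velocity_calibration is the per-limb approach-velocity distribution",
    "(mean +/- SD, m/s) reported for the cutting task.",
    "sd_between back-calculation: the marginal-mean 95% CI half-widths are",
    "~1.4 BW (PFJ), ~2.5 deg (angle), ~0.85 BW (quad) at n=26 participants,",
    "3 trials/limb. With a participant random intercept, SE(marginal mean)",
    "~ sqrt((sd_between^2 + sd_within^2/3)/26) and halfwidth ~ 2.01*SE.",
    "Assuming sd_within = sd_between/2 (trial-level variability is not",
    "reported; flagged assumption) gives sd_between = halfwidth/0.410:",
    "3.4 BW, 6.1 deg, 2.1 BW.",
    "velocity_slope values are invented but configurable; chosen so the",
    "velocity adjustment is exercised without dominating group effects.",
    "metric_correlation applies to the within-trial residuals, order",
    "(pfj, angle, quad); between-participant intercepts are independent",
    "across metrics."
  ],
  "n_aclr": 26,
  "n_control": 22,
  "trials_per_limb": 3,
  "limb_calibration": {
    "ACLR":          {"mu_pfj": 12.7, "mu_angle": 52, "mu_quad": 10.9},
    "contralateral": {"mu_pfj": 18.7, "mu_angle": 56, "mu_quad": 15.1},
    "control":       {"mu_pfj": 17.1, "mu_angle": 57, "mu_quad": 13.7}
  },
  "sd_between": {"pfj": 3.4, "angle": 6.1, "quad": 2.1},
  "sd_within":  {"pfj": 1.7, "angle": 3.05, "quad": 1.05},
  "velocity_calibration": {
    "ACLR":          {"mean": 3.7, "sd": 0.6},
    "contralateral": {"mean": 3.9, "sd": 0.5},
    "control":       {"mean": 4.3, "sd": 0.6}
  },
  "velocity_slope": {"pfj": 1.5, "angle": 1.0, "quad": 1.0},
  "metric_correlation": [
    [1.0, 0.5, 0.5],
    [0.5, 1.0, 0.25],
    [0.5, 0.25, 1.0]
  ],
  "anthropometry": {"mass_kg": 71.4, "height_m": 1.73}
}
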