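{
  "version": "1.0",
  "provenance": [
    "SYNTHETIC default patellar mechanism. The in vitro source curves used",
    "by the original experiments are not printed in any primary table, so",
    "these polynomials are a smooth synthetic fit to the published in",
    "vitro TRENDS: the patellar-tendon/quadriceps force ratio k is ~1.05",
    "near full extension and declines with flexion; the angle beta between",
    "the quadriceps-tendon and patellar-tendon force vectors acting on the",
    "patella is obtuse near extension (resultant small) and decreases with",
    "flexion (resultant grows). Swap this file to use a different",
    "mechanism; every result records the mechanism version used."
  ],
  "theta_valid_range_deg": [0, 120],
  "k_coeffs": [1.05, -0.00275, -1e-05],
  "beta_coeffs": [171.0, -1.3],
  "beta_convention": "angle (deg) between the quadriceps-tendon and patellar-tendon force vectors; obtuse near full extension"
}
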