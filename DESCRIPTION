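Package: pfjload
Title: Patellofemoral Joint Loading Analysis for Side-Step Cutting Trials
Version: 0.1.0
Authors@R: person("pfjload", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A desk-scale musculoskeletal analysis chain for estimating
    patellofemoral joint (PFJ) contact forces during the stance phase of
    side-step cutting, and for comparing limbs after anterior cruciate
    ligament reconstruction (ACLR). Provides a planar four-segment limb
    model with inverse kinematics from marker trajectories, bottom-up
    Newton-Euler inverse dynamics from ground-reaction forces, static
    optimization of muscle forces (minimum summed squared activations),
    an empirical patellar-mechanism model relating quadriceps force and
    knee flexion angle to PFJ contact force, stance-phase event detection
    and approach-velocity computation, velocity-adjusted linear
    mixed-effects limb comparisons with Tukey post hoc tests, and a
    seeded synthetic-cohort generator (metric-level and signal-level)
    for parameter-recovery simulation. Includes TRC/MOT/STO-dialect
    readers and writers and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    quadprog,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
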