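---
title: "Methods: patellofemoral loading from cutting trials"
author: "pfjload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patellofemoral loading from cutting trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pfjload)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the tunable parameters that
matter, and what a green test suite does and does not establish. It states
no empirical result that the tests or `scripts/acceptance.R` do not
themselves compute.

## The mechanical model

The limb is a planar (sagittal) four-segment chain — pelvis+HAT, thigh,
shank, foot — with revolute hip, knee and ankle joints. A full 3D
musculoskeletal model would be the norm for laboratory work, but the PFJ
contact-force model consumes only knee flexion angle and quadriceps force,
both sagittal-plane quantities, and PFJ loading is strongly sagittal-plane
dominant; a planar chain keeps every stage verifiable against closed-form
and brute-force oracles at desk scale. The cost is that frontal/transverse
loading, 3D marker redundancy and out-of-plane compensations are outside
the model; the package makes no claims about them.

Segment lengths scale with stature and masses with body mass using a fixed
published-proportion table shipped in
`inst/extdata/planar_model_defaults.json`; COM fractions and mass fractions
are invariant under scaling (a tested invariant). The pelvis+HAT segment
lumps trunk, head, arms and the swing leg so that total model mass equals
body mass — this makes the model centre of mass, and therefore the
approach velocity, meaningful.

Conventions, fixed throughout: approach direction +x, up +y; knee flexion
positive with 0° at full extension; hip flexion and ankle dorsiflexion
positive; net knee moments are reported extension-positive. The internal
("conjugate") sign convention used by the static optimizer flips only the
knee row; both matrices are carried on the inverse-dynamics result so the
mapping is explicit rather than implied.

## Stage-by-stage notes

**Inverse kinematics.** Per frame, the 6-DOF pose minimises
$\sum_m w_m \lVert \hat x_m(q) - x_m \rVert^2$ by damped Gauss–Newton
(damping $10^{-8}$, convergence when the largest step falls below
$10^{-10}$, at most 100 iterations), warm-started from the previous frame.
The first frame uses a small multi-start over joint-angle combinations
with the optimal translation solved in closed form, which makes the solver
robust to arbitrary initial poses. Frames with fewer than 3 usable markers
are flagged and linearly interpolated when the gap is ≤ 10 frames;
longer gaps reject the trial. A dense-grid oracle (0.01° final
resolution) bounds the single-frame objective in the tests.

**Filtering.** Markers default to a 12 Hz zero-lag low-pass (2nd-order
Butterworth, forward+backward — the conventional "4th-order zero-lag"),
GRF to 50 Hz for inverse dynamics only; event detection always uses the
raw native-rate force, as the 20 N stance rule specifies "raw". Both
cutoffs are configurable and may be disabled (`NA`). For *noiseless*
verification trials the round-trip tests run unfiltered: with zero
observation noise the filters are the only bias source (about 1% peak
attenuation of a 4 Hz Hann component at the 12 Hz default), and the
round-trip criterion is about solver fidelity, not filter design.

**Inverse dynamics.** Bottom-up Newton–Euler with segment inertial terms
and gravity, GRF applied at the centre of pressure, accelerations by
central differences (one-sided at endpoints). The 1000 Hz force series is
fused to the 250 Hz marker clock by windowed averaging; event indices are
always computed on the native signal. Verified against a static
equilibrium oracle written independently in the test suite, plus linearity
and superposition properties.

**Static optimization.** Per sample: minimise $\sum_i a_i^2$ subject to
$\sum_i a_i f_{\max,i}\, r_{ij}(\theta) = M_j$ for hip, knee, ankle and
$0 \le a_i \le 1$; muscle force is $a_i f_{\max,i}$ (affine force
generation — no force–length–velocity scaling, a documented
simplification since the source methodology does not state one). The QP is
solved with `quadprog` (dual active-set, deterministic, residuals ~1e-10);
KKT conditions and a brute-force activation-grid oracle are asserted in
tests. The 8-muscle planar set (iliopsoas, gluteus maximus, hamstrings,
rectus femoris, vasti, gastrocnemius, soleus, tibialis anterior) with
polynomial moment arms is a self-contained default in the model file —
magnitudes are in the range of published lower-limb models but are not a
reproduction of any specific one. Samples whose demand exceeds capacity
are solved as bounded least-residual problems, flagged, and excluded from
peak extraction, so a single bad frame cannot reject a trial.

**PFJ model.** $F_P = k(\theta) F_Q$ and
$F_{PFJ} = \sqrt{F_Q^2 + F_P^2 + 2 F_Q F_P \cos\beta}$, evaluated
per sample in body weights. The in vitro $k(\theta)$ and $\beta(\theta)$
curves behind the published methodology are cited there but never printed,
so they are unknowable from the text alone. The package therefore treats
the mechanism as an explicit, swappable input: a versioned JSON file with
polynomial coefficients, valid range (default 0–120°, clamped and flagged
outside), and a provenance note. The shipped default is a *synthetic*
smooth fit to the published in vitro trends ($k \approx 1.05$ near
extension, declining with flexion; $\beta$ obtuse near extension,
decreasing with flexion, so the resultant grows as the knee bends). Its
β convention (obtuse near extension) is a config-level choice, never
silently assumed. The acceptance suite only requires *soft* consistency:
the ACLR operating point (52°, 10.9 BW) must land within 20% of the
published 12.7 BW peak — the shipped default lands within ~0.5%, but that
closeness is a property of the synthetic fit, not a validated
reproduction.

**Statistics.** Trial-level rows enter
`outcome ~ limb + approach_velocity + (1 | participant)` fitted by REML
(lme4); all trials are repeated measures with the participant intercept
absorbing within-person correlation (the source analysis does not state
whether trials or participant means were modelled; trials-as-rows is the
assumption here, and the shared intercept also links the two limbs of an
ACLR participant). Marginal means are evaluated at the pooled mean
approach velocity across all rows. Pairwise limb differences use the Tukey
(studentized-range) adjustment over the three contrasts, computed from
`ptukey`/`qtukey`. Degrees of freedom use a between-participant
containment approximation (participants − limb levels = 45 at the default
design) rather than Satterthwaite: the Satterthwaite machinery lives in
packages not available in this build environment, and at these sample
sizes the difference in critical values is ~1%. Singular fits (zero
between-participant variance) return a flagged result instead of
aborting; exact ties in peak extraction resolve to the earliest sample.

## The synthetic cohort: what it emulates

No raw data are deposited with the study design this package mirrors, so
its acceptance evidence is parameter recovery on synthetic cohorts plus
property-based suites — a deliberate and explicit substitution.

The **metric-level generator** draws per-trial outcomes
$y = \mu_m(\mathrm{limb}) + b_{p,m} + s_m (v - \bar v) + \epsilon$ with
participant intercepts shared across the two limbs of an ACLR participant
and correlated within-trial residuals. Its defaults
(`inst/extdata/cohort_defaults.json`) are the stated world:

- group means: the published velocity-adjusted marginal means
  (12.7/18.7/17.1 BW; 52/56/57°; 10.9/15.1/13.7 BW);
- approach velocities: 3.7 ± 0.6 (ACLR), 3.9 ± 0.5 (contralateral),
  4.3 ± 0.6 m/s (control);
- cohort sizes 26 ACLR (both limbs) and 22 controls (the abstract of the
  source reports 23 controls; the methods and tables say 22, which is
  used), 3 trials per limb;
- between-participant SDs (3.4 BW, 6.1°, 2.1 BW) back-calculated from the
  published CI half-widths assuming the within-trial SD is half the
  between-participant SD — trial-level variability is not reported
  anywhere, so this ratio is an assumption, recorded in the defaults file;
- velocity slopes (1.5 BW, 1°, 1 BW per m/s) and the metric correlation
  (angle and quadriceps force each 0.5 with peak PFJ) are invented but
  configurable, chosen so the velocity adjustment is exercised without
  dominating group effects.

Because the generator centres its slopes at the design's pooled mean
velocity and the model evaluates marginal means at the sample's pooled
mean velocity, the published means are recovered *unbiasedly*; single
cohorts scatter with SE ≈ 0.65 BW for a group mean.

The **signal-level generator** emits a stylised stance-phase trial: Hann
(raised-cosine) joint-angle curves over a 0.25 s stance (250 Hz markers,
1000 Hz GRF, matching conventional capture rates), a two-bump vertical GRF
template with anteroposterior shear expressed as a smooth fraction of the
vertical force, a COP track progressing under the foot, and a pre-contact
window in which the contact pose translates rigidly at the drawn approach
velocity (so COM velocity is exactly the drawn value and continuous at
contact — the 50 ms rule is unbiased by construction, not by tuning).
Waveform shapes are not published anywhere; raised cosines were chosen for
smoothness, differentiability and controllable peaks, and all parameters
live in `signal_waveform_defaults()`. The template geometry was tuned once
so that mid-stance is quadriceps-dominant (GRF line posterior to the knee,
peak vertical force ≈ 3 BW) and then frozen.

Ground truth is self-consistent by construction: true moments come from
inverse dynamics of the true kinematics, true muscle forces from static
optimization of those moments (so moments equal the moment-arm-weighted
force sums — a tested invariant), and the true PFJ series from the
mechanism applied to the true $F_Q$ and $\theta$. The GRF scale is
calibrated per trial by a deterministic secant iteration (the moments are
affine in the scale) so the true peak quadriceps force equals the limb
calibration value to 0.02 BW. Observation noise (default 1 mm markers,
2 N GRF) applies to the emitted signals only, never to the truth.

**What a green suite establishes** — that the pipeline recovers what the
generator put in, at the published operating points, and that every
stage agrees with independent oracles. **What it does not establish** —
anything about real marker artefact (soft tissue, occlusion patterns),
real GRF waveforms, 3D kinematic coupling, or the true in vitro patellar
mechanism. The synthetic world has exactly the statistical structure the
mixed model assumes; real data need not.

## Numerical choices

- IK: damping $10^{-8}$, step tolerance $10^{-10}$, ≤ 100 iterations,
  multi-start on the first frame only.
- QP: quadprog defaults (machine-precision equality residuals); ridge
  $10^{-8}$ on the bounded least-residual fallback to select a unique
  solution; feasibility flag threshold $10^{-6}$ N·m.
- Differentiation: central differences, one-sided at endpoints; the GRF
  fusion window is one marker period.
- Peak ties: earliest sample (the `which.max` convention, asserted).
- Mechanism clamping: hard clamp to the valid θ range with a per-sample
  flag; $k$, $\beta$ are continuous across the boundary by construction.
- Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state; derived sub-seed streams stay below $2^{31}$.

## Known limitations

- Planar chain; no frontal/transverse mechanics, no 6-DOF joints, no
  soft-tissue artefact model, no gap-filling beyond linear interpolation.
- Affine muscle model; no activation dynamics or EMG-informed estimation.
- The patellar mechanism default is a synthetic stand-in; conclusions
  about absolute PFJ force magnitudes inherit its uncertainty, which is
  why acceptance treats the operating-point check as diagnostic (20%
  band) rather than exact.
- The mixed-model df approximation is containment, not Satterthwaite;
  CIs at small cohort sizes are approximate at the ~1% level.
- During stance the generator drives the pelvis, so the synthetic foot
  drifts rather than staying planted; graded quantities (pre-contact COM
  velocity, θ, $F_Q$, $F_{PFJ}$) are unaffected, but the trials are
  stylised, not gait-realistic.
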