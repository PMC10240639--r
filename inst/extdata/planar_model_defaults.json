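{
  "version": "1.0",
  "notes": [
    "Planar (sagittal) four-segment limb model: pelvis+HAT -> thigh ->",
    "shank -> foot, right leg, approach direction +x, up +y.",
    "Segment lengths are fractions of stature, masses fractions of body",
    "mass, COM location a fraction of segment length from the proximal",
    "joint, moment of inertia m*(rog_fraction*length)^2 about the COM;",
    "proportions follow standard adjusted cadaver-study tables.",
    "The pelvis_hat segment lumps pelvis, trunk, head, arms and the swing",
    "leg so that total model mass equals body mass (COM velocity correct).",
    "Marker offsets (m) are local coordinates in the segment frame at the",
    "reference pose (all joint angles zero: thigh and shank vertical, foot",
    "horizontal, toes forward) for reference stature 1.73 m; they scale",
    "proportionally with stature.",
    "Muscle moment-arm polynomials are in meters vs joint angle in degrees",
    "in the conjugate-coordinate convention (hip flexion +, knee flexion +,",
    "ankle dorsiflexion +); f_max values are for the reference body mass",
    "71.4 kg and scale proportionally with body mass.",
    "All muscle parameters are a self-contained planar default set with",
    "magnitudes in the range of published lower-limb models; they are not",
    "a reproduction of any specific published 3D model."
  ],
  "reference_anthropometry": {"mass_kg": 71.4, "height_m": 1.73},
  "gravity": 9.81,
  "segments": {
    "pelvis_hat": {
      "mass_fraction": 0.8014,
      "com_local": [0.0, 0.25],
      "rog_m": 0.35
    },
    "thigh": {
      "length_fraction": 0.245,
      "mass_fraction": 0.1416,
      "com_fraction": 0.41,
      "rog_fraction": 0.329
    },
    "shank": {
      "length_fraction": 0.246,
      "mass_fraction": 0.0433,
      "com_fraction": 0.44,
      "rog_fraction": 0.302
    },
    "foot": {
      "length_fraction": 0.152,
      "mass_fraction": 0.0137,
      "com_fraction": 0.44,
      "rog_fraction": 0.257
    }
  },
  "markers": {
    "SACR":  {"segment": "pelvis_hat", "offset": [-0.08, 0.05],  "weight": 1.0},
    "ASIS":  {"segment": "pelvis_hat", "offset": [0.10, 0.02],   "weight": 1.0},
    "PELV":  {"segment": "pelvis_hat", "offset": [0.02, 0.15],   "weight": 1.0},
    "THI":   {"segment": "thigh",      "offset": [0.04, -0.18],  "weight": 1.0},
    "THI2":  {"segment": "thigh",      "offset": [0.05, -0.30],  "weight": 1.0},
    "KNEE":  {"segment": "thigh",      "offset": [0.05, -0.42],  "weight": 1.0},
    "TIB":   {"segment": "shank",      "offset": [0.04, -0.15],  "weight": 1.0},
    "TIB2":  {"segment": "shank",      "offset": [0.04, -0.28],  "weight": 1.0},
    "ANKLE": {"segment": "shank",      "offset": [0.05, -0.42],  "weight": 1.0},
    "HEEL":  {"segment": "foot",       "offset": [-0.04, -0.03], "weight": 1.0},
    "TOE":   {"segment": "foot",       "offset": [0.20, -0.02],  "weight": 1.0},
    "MT5":   {"segment": "foot",       "offset": [0.13, 0.02],   "weight": 1.0}
  },
  "joint_limits_deg": {
    "hip":   [-30, 120],
    "knee":  [0, 140],
    "ankle": [-40, 40]
  },
  "muscles": [
    {"name": "iliopsoas", "f_max": 2500, "group": "hip_flexor",
     "is_quadriceps": false,
     "arms": {"hip": [0.033]}},
    {"name": "gluteus_maximus", "f_max": 5500, "group": "hip_extensor",
     "is_quadriceps": false,
     "arms": {"hip": [-0.055]}},
    {"name": "hamstrings", "f_max": 6000, "group": "knee_flexor",
     "is_quadriceps": false,
     "arms": {"hip": [-0.060], "knee": [0.030, -5e-05]}},
    {"name": "rectus_femoris", "f_max": 3600, "group": "knee_extensor",
     "is_quadriceps": true,
     "arms": {"hip": [0.040], "knee": [-0.040, -0.0004, 5e-06]}},
    {"name": "vasti", "f_max": 12000, "group": "knee_extensor",
     "is_quadriceps": true,
     "arms": {"knee": [-0.040, -0.0004, 5e-06]}},
    {"name": "gastrocnemius", "f_max": 4500, "group": "plantarflexor",
     "is_quadriceps": false,
     "arms": {"knee": [0.020], "ankle": [-0.050]}},
    {"name": "soleus", "f_max": 8000, "group": "plantarflexor",
     "is_quadriceps": false,
     "arms": {"ankle": [-0.052]}},
    {"name": "tibialis_anterior", "f_max": 2200, "group": "dorsiflexor",
     "is_quadriceps": false,
     "arms": {"ankle": [0.040]}}
  ]
}
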