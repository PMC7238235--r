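{
  "kind": "compaction_simulator",
  "press": {
    "name": "StylOne",
    "pitch_circle_diameter": 0.24,
    "n_dies": 1,
    "roller_diameter": 0.18,
    "head_flat_length": 0.012,
    "head_radius": 0.016,
    "fill_angle": 360,
    "die_spacing_angle": 360
  },
  "feeder": {
    "paddle_diameter": 0.085,
    "n_spokes": 4,
    "clearance": 0.002,
    "holdup_mass": 0.25,
    "feed_volume": 0.00055,
    "bulk_density": 500
  },
  "provenance": "Placeholder geometry, not from paper or vendor data. Single-station compaction simulator: one die position under the feeder (n_dies = 1). The press block is the nominal replay geometry (euro-D tooling); kinematics of a simulated run come from the simulated press fixture, and the shear-number corrections use the simulated press's fill and die-spacing angles. Feeder hold-up calibrated jointly with the XL100 fixture (see XL100.json)."
}
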