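{
  "kind": "rotary_press",
  "press": {
    "name": "XL100",
    "pitch_circle_diameter": 0.24,
    "n_dies": 4,
    "roller_diameter": 0.18,
    "head_flat_length": 0.012,
    "head_radius": 0.016,
    "fill_angle": 110,
    "die_spacing_angle": 90
  },
  "feeder": {
    "paddle_diameter": 0.1,
    "n_spokes": 3,
    "clearance": 0.0025,
    "holdup_mass": 0.237069,
    "feed_volume": 0.0006,
    "bulk_density": 500
  },
  "provenance": "Placeholder geometry, not from paper or vendor data. Pilot-scale press run with 4 installed punch pairs; die_spacing_angle = 360/4 for the installed set. The feeder hold-up mass is calibrated jointly with the StylOne feeder so that the shear-number paddle-frequency transfer reproduces the documented operating pair 60 -> 128 min^-1; edit freely for a real machine."
}
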