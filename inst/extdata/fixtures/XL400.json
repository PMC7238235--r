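{
  "kind": "rotary_press",
  "press": {
    "name": "XL400",
    "pitch_circle_diameter": 0.3056,
    "n_dies": 29,
    "roller_diameter": 0.25,
    "head_flat_length": 0.012,
    "head_radius": 0.016,
    "fill_angle": 110,
    "die_spacing_angle": 12.413793103448276
  },
  "feeder": {
    "paddle_diameter": 0.14,
    "n_spokes": 3,
    "clearance": 0.0025,
    "holdup_mass": 0.5,
    "feed_volume": 0.0013,
    "bulk_density": 500
  },
  "provenance": "Placeholder geometry, not from paper or vendor data. Production-scale press, 29 dies, die_spacing_angle = 360/29. Pitch circle chosen with the 12 mm euro-D head flat so that the theoretical dwell time at 60 min^-1 turret speed is 12.5 ms; edit freely for a real machine."
}
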