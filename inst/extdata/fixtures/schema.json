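{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "tabscale machine fixture",
  "type": "object",
  "required": ["kind", "press", "feeder"],
  "additionalProperties": false,
  "properties": {
    "kind": {"enum": ["rotary_press", "compaction_simulator"]},
    "provenance": {"type": "string"},
    "press": {
      "type": "object",
      "required": ["name", "pitch_circle_diameter", "n_dies", "roller_diameter",
                   "head_flat_length", "head_radius", "fill_angle",
                   "die_spacing_angle"],
      "additionalProperties": false,
      "properties": {
        "name": {"type": "string"},
        "pitch_circle_diameter": {"type": "number", "exclusiveMinimum": 0,
                                  "description": "m"},
        "n_dies": {"type": "integer", "minimum": 1},
        "roller_diameter": {"type": "number", "exclusiveMinimum": 0,
                            "description": "m"},
        "head_flat_length": {"type": "number", "exclusiveMinimum": 0,
                             "description": "m"},
        "head_radius": {"type": "number", "exclusiveMinimum": 0,
                        "description": "m"},
        "fill_angle": {"type": "number", "exclusiveMinimum": 0, "maximum": 360,
                       "description": "deg"},
        "die_spacing_angle": {"type": "number", "exclusiveMinimum": 0,
                              "maximum": 360, "description": "deg"}
      }
    },
    "feeder": {
      "type": "object",
      "required": ["paddle_diameter", "n_spokes", "clearance", "holdup_mass",
                   "feed_volume", "bulk_density"],
      "additionalProperties": false,
      "properties": {
        "paddle_diameter": {"type": "number", "exclusiveMinimum": 0,
                            "description": "m"},
        "n_spokes": {"type": "integer", "minimum": 1},
        "clearance": {"type": "number", "exclusiveMinimum": 0,
                      "description": "m"},
        "holdup_mass": {"type": "number", "exclusiveMinimum": 0,
                        "description": "kg; must not exceed feed_volume*bulk_density"},
        "feed_volume": {"type": "number", "exclusiveMinimum": 0,
                        "description": "m^3"},
        "bulk_density": {"type": "number", "exclusiveMinimum": 0,
                         "description": "kg/m^3"}
      }
    }
  }
}
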