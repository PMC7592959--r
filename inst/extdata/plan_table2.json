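{
  "name": "patient1_right_orbital_gyrus",
  "note": "Arc couch/gantry angles transcribed from a published SRS case (patient 1, right orbital gyrus). The reference point and isocenter are SYNTHETIC demonstration values (the published case does not include them), chosen anatomically plausible and so that this plan shows both colliding and clearing arcs with machine_demo.yaml.",
  "reference_point": {"lat": 103.1, "ap": 4.0, "si": 23.3},
  "isocenter": {"lat": -18.0, "ap": -28.2, "si": 40.8},
  "sz_shape": "box",
  "arcs": [
    {"id": "1", "couch": 180, "gantry_start": 200, "gantry_stop": 350, "n_points": 19},
    {"id": "2", "couch": 255, "gantry_start": 160, "gantry_stop": 10,  "n_points": 19},
    {"id": "3", "couch": 205, "gantry_start": 10,  "gantry_stop": 160, "n_points": 19},
    {"id": "4", "couch": 130, "gantry_start": 200, "gantry_stop": 350, "n_points": 19},
    {"id": "5", "couch": 255, "gantry_start": 165, "gantry_stop": 45,  "n_points": 19},
    {"id": "6", "couch": 195, "gantry_start": 55,  "gantry_stop": 165, "n_points": 19},
    {"id": "7", "couch": 165, "gantry_start": 195, "gantry_stop": 315, "n_points": 19},
    {"id": "8", "couch": 105, "gantry_start": 315, "gantry_stop": 195, "n_points": 19}
  ]
}
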