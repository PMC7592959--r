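{
  "name": "patient3_right_cerebellar_peduncle",
  "note": "Arc couch/gantry angles transcribed from a published SRS case (patient 3, right cerebellar peduncle lesion). The reference point and isocenter are SYNTHETIC demonstration values (the published case does not include them).",
  "reference_point": {"lat": 103.1, "ap": 4.0, "si": 23.3},
  "isocenter": {"lat": -3.0, "ap": 6.8, "si": 30.8},
  "sz_shape": "box",
  "arcs": [
    {"id": "1", "couch": 125, "gantry_start": 190, "gantry_stop": 350, "n_points": 19},
    {"id": "2", "couch": 230, "gantry_start": 10,  "gantry_stop": 170, "n_points": 19},
    {"id": "3", "couch": 180, "gantry_start": 220, "gantry_stop": 350, "n_points": 19},
    {"id": "4", "couch": 245, "gantry_start": 80,  "gantry_stop": 10,  "n_points": 19},
    {"id": "5", "couch": 205, "gantry_start": 10,  "gantry_stop": 90,  "n_points": 19},
    {"id": "6", "couch": 145, "gantry_start": 220, "gantry_stop": 350, "n_points": 19},
    {"id": "7", "couch": 115, "gantry_start": 350, "gantry_stop": 220, "n_points": 19}
  ]
}
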