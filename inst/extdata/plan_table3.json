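{
  "name": "patient2_left_cerebellar",
  "note": "Arc couch/gantry angles transcribed from a published SRS case (patient 2, left cerebellar lesion). The reference point and isocenter are SYNTHETIC demonstration values (the published case does not include them).",
  "reference_point": {"lat": 103.1, "ap": 4.0, "si": 23.3},
  "isocenter": {"lat": 12.0, "ap": 11.8, "si": 20.8},
  "sz_shape": "box",
  "arcs": [
    {"id": "1", "couch": 180, "gantry_start": 150, "gantry_stop": 10,  "n_points": 19},
    {"id": "2", "couch": 255, "gantry_start": 10,  "gantry_stop": 150, "n_points": 19},
    {"id": "3", "couch": 105, "gantry_start": 220, "gantry_stop": 350, "n_points": 19},
    {"id": "4", "couch": 270, "gantry_start": 10,  "gantry_stop": 140, "n_points": 19},
    {"id": "5", "couch": 225, "gantry_start": 150, "gantry_stop": 10,  "n_points": 19}
  ]
}
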