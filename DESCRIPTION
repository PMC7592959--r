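Package: conearc
Title: Geometric Pre-Screening of Stereotactic Cone Collisions for Linac
    SRS Arcs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the gantry head, stereotactic cone, treatment couch and
    a patient safety zone as scaled, translated and rotated geometric
    primitives (boxes, cylinders, ellipsoids) placed from machine
    commissioning measurements and plan coordinates.  Treatment arcs are
    swept over gantry angle at a fixed couch angle and every machine-side
    versus patient-side pair is scored by its minimum clearance, yielding a
    clear / close / collide classification per arc, batch CSV/JSON reports
    and 3D room views.  Intended as a desk-side pre-screen during
    intracranial stereotactic radiosurgery planning; it never replaces the
    in-room collision check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
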