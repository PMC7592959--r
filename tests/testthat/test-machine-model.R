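cfg_list <- function(...) {
  # minimal valid config as a named list, overridable per test
  base <- list(
    szs = 165, szi = 165, sza = 155, szp = 120, szr = 115, szl = 115,
    cod = 75, cht = 20, chad = 120, cad = 256, chw = 282, chse = 200,
    chie = -113, cbie = -2240, cbw = 530, hod = 670, ht = 670, had = 437,
    gia = 180, gicw = 0, cia = 180, cicw = 1,
    szlatcomm = 2, szapcomm = 1.8, szsicomm = 0.8,
    reflatcomm = 103.1, refapcomm = 4, refsicomm = 23.3,
    apdir = -1, latdir = 1, sidir = -1
  )
  utils::modifyList(base, list(...), keep.null = TRUE)
}

test_that("the shipped commissioning file loads with its surveyed values", {
  cfg <- load_config(system.file("extdata", "machine_table1.yaml",
                                 package = "conearc"))
  expect_s3_class(cfg, "machine_config")
  expect_equal(cfg$gicw, 0)
  expect_equal(cfg$cicw, 1)
  expect_equal(cfg$had, 437)
  expect_equal(cfg$chad, 120)
  expect_equal(cfg$cod, 750)
  expect_equal(cfg$close_threshold_mm, 10)  # default when omitted
  expect_equal(cfg$label_ap, "Y")
})

test_that("config validation names the offending key", {
  expect_error(machine_config(cfg_list(cod = -5)), "cod",
               class = "conearc_config_error")
  expect_error(machine_config(cfg_list(had = NULL)), "had",
               class = "conearc_config_error")
  expect_error(machine_config(cfg_list(gicw = 2)), "gicw",
               class = "conearc_config_error")
  expect_error(machine_config(cfg_list(latdir = 0)), "latdir",
               class = "conearc_config_error")
  expect_error(machine_config(cfg_list(chie = 250)), "chie",
               class = "conearc_config_error")
  expect_error(machine_config(cfg_list(had = 200)), "had",
               class = "conearc_config_error")  # must exceed cad
  expect_warning(machine_config(cfg_list(couch_model = "exact")),
                 "unknown config key")
})

test_that("vertdir is accepted as an alias for sidir", {
  l <- cfg_list(); l$sidir <- NULL; l$vertdir <- -1
  expect_equal(machine_config(l)$sidir, -1)
})

test_that("internal angles apply the initial-angle and sense flags", {
  cfg <- machine_config(cfg_list())
  expect_equal(internal_gantry_angle(180, cfg), 0)     # overhead pose
  expect_equal(internal_gantry_angle(180 + 360, cfg), 0)
  expect_equal(internal_gantry_angle(190, cfg), -10)   # gicw = 0 flips sign
  expect_equal(internal_couch_angle(180, cfg), 0)
  expect_equal(internal_couch_angle(90, cfg), -90)     # cicw = 1 keeps sign
  expect_equal(internal_couch_angle(180, machine_config(cfg_list(cicw = 0))), 0)
  # normalization lands in (-180, 180]
  expect_equal(internal_gantry_angle(0, cfg), 180)
  angles <- internal_gantry_angle(seq(-720, 720, by = 7), cfg)
  expect_true(all(angles > -180 & angles <= 180))
})

test_that("patient placement follows the commissioned reference relation", {
  cfg <- machine_config(cfg_list())
  refcomm <- c(lat = 103.1, ap = 4, si = 23.3)
  szcomm <- c(lat = 2, ap = 1.8, si = 0.8)
  # isocenter on the safety-zone centre: offsets cancel
  expect_equal(unname(patient_offset(plan_context(refcomm, szcomm), cfg)),
               c(0, 0, 0))
  # isocenter on the reference point: the commissioned lever arm remains
  off <- patient_offset(plan_context(refcomm, refcomm), cfg)
  expect_equal(unname(off), c(-101.1, 22.5, 2.2), tolerance = 1e-9)
  # linearity: a large lateral shift moves the zone by -shift * latdir
  iso2 <- refcomm + c(lat = 200, ap = 0, si = 0)
  off2 <- patient_offset(plan_context(refcomm, iso2), cfg)
  expect_equal(off2[["x"]] - off[["x"]], -200 * cfg$latdir)
  expect_equal(off2[c("y", "z")], off[c("y", "z")])
})

test_that("the built scene places each component per the survey", {
  cfg <- demo_cfg()
  plan <- plan_with_offset(c(0, 0, 0))
  sc <- build_scene(cfg, plan, 180, 180)
  expect_named(sc$solids, c("cone", "gantry_head", "couch_head",
                            "couch_body", "safety_zone"))
  expect_equal(sc$gantry_internal, 0)
  expect_equal(sc$couch_internal, 0)
  cone <- sc$solids$cone
  expect_equal(cone$scale, c(75, 75, 181))
  expect_equal(cone$translation, c(0, 0, 346.5))
  sz <- sc$solids$safety_zone
  expect_equal(sz$kind, "box")
  expect_equal(sz$scale, c(230, 330, 275))
  expect_equal(sz$translation, c(0, 0, 17.5))
  head <- sc$solids$gantry_head
  expect_equal(unname(mesh_extents(solid_mesh(head))["z", ]), c(437, 1107))
  # at the initial angles the meshes equal their unrotated construction
  for (s in sc$solids) {
    expect_equal(solid_mesh(s, 8)$xs,
                 scale_translate(unit_mesh(s$kind, 8), s$scale,
                                 s$translation)$xs)
  }
})

test_that("ellipsoid safety zone shares the box placement rule", {
  cfg <- demo_cfg()
  b <- build_scene(cfg, plan_with_offset(c(3, -4, 5), "box"), 205, 130)
  e <- build_scene(cfg, plan_with_offset(c(3, -4, 5), "ellipsoid"), 205, 130)
  expect_equal(e$solids$safety_zone$kind, "ellipsoid")
  expect_equal(e$solids$safety_zone$scale, b$solids$safety_zone$scale)
  expect_equal(e$solids$safety_zone$translation,
               b$solids$safety_zone$translation)
})

test_that("the patient assembly translates rigidly with the offset", {
  cfg <- demo_cfg()
  off <- c(31, -12, 44)
  sc <- build_scene(cfg, plan_with_offset(off), 205, 40)
  sc0 <- build_scene(cfg, plan_with_offset(c(0, 0, 0)), 205, 40)
  for (role in c("safety_zone", "couch_head", "couch_body")) {
    expect_equal(sc$solids[[role]]$translation - off,
                 sc0$solids[[role]]$translation, tolerance = 1e-12)
  }
  # machine side is untouched by the patient offset
  expect_equal(sc$solids$cone, sc0$solids$cone)
})

test_that("couch head and body abut exactly at the inferior head edge", {
  cfg <- demo_cfg()
  off <- c(7, 13, -21)
  sc <- build_scene(cfg, plan_with_offset(off), 180, 180)
  head <- sc$solids$couch_head; body <- sc$solids$couch_body
  head_ymin <- head$translation[2] - head$scale[2] / 2
  body_ymax <- body$translation[2] + body$scale[2] / 2
  expect_equal(head_ymin, body_ymax)              # no gap, no overlap
  expect_equal(head_ymin, off[2] + cfg$chie)
  expect_equal(head$translation[3], body$translation[3])  # same top plane
  expect_equal(head$scale[3], body$scale[3])
})

test_that("scene construction is deterministic", {
  cfg <- demo_cfg()
  a <- build_scene(cfg, plan_with_offset(c(1, 2, 3)), 255, 10)
  b <- build_scene(cfg, plan_with_offset(c(1, 2, 3)), 255, 10)
  expect_identical(a, b)
})
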