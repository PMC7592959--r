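test_that("unit primitives are centred with extents exactly [-0.5, 0.5]", {
  box <- unit_mesh("box", 2)
  corners <- unique(round(mesh_points(box), 12))
  expect_equal(nrow(corners), 8)
  expect_true(all(abs(abs(corners) - 0.5) < 1e-15))

  sph <- unit_mesh("ellipsoid", 64)
  norms <- sqrt(rowSums(mesh_points(sph)^2))
  expect_true(all(abs(norms - 0.5) < 1e-12))

  cyl <- unit_mesh("cylinder", 64)
  P <- mesh_points(cyl)
  expect_equal(max(abs(P[, "z"])), 0.5, tolerance = 1e-12)
  expect_equal(max(sqrt(P[, "x"]^2 + P[, "y"]^2)), 0.5, tolerance = 1e-12)
  for (m in list(box, sph, cyl)) {
    expect_equal(unname(mesh_extents(m)),
                 matrix(c(-0.5, 0.5), 3, 2, byrow = TRUE), tolerance = 1e-12)
  }

  expect_error(unit_mesh("pyramid"), class = "conearc_invalid_argument")
  expect_error(unit_mesh("box", 1), class = "conearc_invalid_argument")
})

test_that("scale_translate is the componentwise affine map", {
  box <- unit_mesh("box", 2)
  m <- scale_translate(box, c(2, 3, 4), c(1, 0, 0))
  expect_equal(unname(mesh_extents(m)),
               rbind(c(0, 2), c(-1.5, 1.5), c(-2, 2)))
  # identity is exact
  expect_identical(scale_translate(box, c(1, 1, 1), c(0, 0, 0))$xs, box$xs)
  # couch-head-sized box from the commissioning sheet: 282 x 313 x 20 mm
  ch <- scale_translate(box, c(282, 200 - (-113), 20))
  expect_equal(unname(mesh_extents(ch)[, 2] - mesh_extents(ch)[, 1]),
               c(282, 313, 20))
  expect_error(scale_translate(box, c(0, 1, 1)),
               class = "conearc_invalid_argument")
})

test_that("rotations implement the printed quarter-turn equations", {
  probe <- surface_mesh(matrix(1, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  ry <- rotate_about_y(probe, 90)
  expect_equal(c(ry$xs[1], ry$ys[1], ry$zs[1]), c(0, 0, 1), tolerance = 1e-15)
  rz <- rotate_about_z(probe, 90)
  expect_equal(c(rz$xs[1], rz$ys[1], rz$zs[1]), c(0, 1, 0), tolerance = 1e-15)
  # zero rotation is bit-exact; a full turn is an identity to 1e-9
  m <- unit_mesh("cylinder", 16)
  expect_identical(rotate_about_y(m, 0)$xs, m$xs)
  expect_equal(rotate_about_z(m, 360)$xs, m$xs, tolerance = 1e-9)
  expect_error(rotate_about_y(m, NaN), class = "conearc_invalid_argument")
})

test_that("rotations are isometries matching a rotation-matrix oracle", {
  set.seed(42)
  for (i in 1:10) {
    m <- surface_mesh(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4),
                      matrix(rnorm(12), 3, 4), blocks = 3)
    ang <- runif(1, -720, 720)
    for (axis in c("y", "z")) {
      rotated <- if (axis == "y") rotate_about_y(m, ang) else rotate_about_z(m, ang)
      R <- rotation_matrix(if (axis == "y") rotation_about_y(ang) else
                             rotation_about_z(ang))
      expect_equal(mesh_points(rotated), mesh_points(m) %*% t(R),
                   tolerance = 1e-12, ignore_attr = TRUE)
      d0 <- dist(mesh_points(m)); d1 <- dist(mesh_points(rotated))
      expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
    }
  }
})

test_that("rotation composition about one axis adds angles", {
  m <- unit_mesh("box", 3)
  a <- rotate_about_z(rotate_about_z(m, 33.5), 71.25)
  b <- rotate_about_z(m, 33.5 + 71.25)
  expect_equal(a$xs, b$xs, tolerance = 1e-9)
  expect_equal(a$ys, b$ys, tolerance = 1e-9)
})

test_that("the transform order is scale -> translate -> rotate", {
  m <- unit_mesh("box", 2)
  C <- c(2, 1, 1); d <- c(5, 0, 0)
  rot_last <- rotate_about_z(scale_translate(m, C, d), 90)
  rot_first <- scale_translate(rotate_about_z(m, 90), C, d)
  expect_gt(max(abs(rot_last$xs - rot_first$xs)), 1)  # demonstrably different
  # solid_mesh composes in the fixed order
  s <- solid("box", C, d, rotation_about_z(90))
  expect_equal(solid_mesh(s, 2)$xs, rot_last$xs)
})

test_that("containment handles boundaries, rotations and anisotropy", {
  ub <- solid("box", c(1, 1, 1))
  expect_true(contains_point(ub, c(0, 0, 0)))
  expect_true(contains_point(ub, c(0.5, 0.5, 0.5)))  # boundary inclusive
  expect_false(contains_point(ub, c(0.6, 0, 0)))
  # a 2 mm cube rotated 45 deg about z reaches sqrt(2) laterally
  rb <- solid("box", c(2, 2, 2), rotation = rotation_about_z(45))
  expect_true(contains_point(rb, c(1.2, 0, 0)))
  expect_false(contains_point(rb, c(1.5, 0, 0)))
  # frame-sized ellipsoid: 165 mm superior semi-axis
  el <- solid("ellipsoid", c(230, 330, 275))
  expect_false(contains_point(el, c(0, 166, 0)))
  expect_true(contains_point(el, c(0, 164, 0)))
})

test_that("solid_mesh vertices lie on the boundary and push off it", {
  set.seed(7)
  shapes <- list(
    solid("cylinder", c(75, 75, 181), c(0, 0, 346.5), role = "cone"),
    solid("box", c(282, 313, 20), c(10, 43.5, -130), rotation_about_z(25)),
    solid("ellipsoid", c(230, 330, 275), c(5, -3, 17.5), rotation_about_y(-12))
  )
  # cone spans z in [cad, had] = [256, 437]
  expect_equal(unname(mesh_extents(solid_mesh(shapes[[1]]))["z", ]),
               c(256, 437), tolerance = 1e-12)
  for (s in shapes) {
    mesh <- solid_mesh(s, 16)
    P <- mesh_points(mesh)
    expect_true(all(contains_points(s, P, tol = 1e-9)))
    out <- P + 1e-6 * outward_normals(s, mesh)
    expect_false(any(contains_points(s, out, tol = 0)))
  }
})

test_that("point projection matches closed forms", {
  el <- solid("ellipsoid", c(200, 300, 400))
  expect_equal(point_solid_distance(el, c(300, 0, 0)), 200)
  expect_equal(project_point_solid(el, c(300, 0, 0)), c(100, 0, 0),
               tolerance = 1e-9)
  expect_equal(point_solid_distance(el, c(10, 20, 30)), 0)  # interior
  bx <- solid("box", c(2, 2, 2), c(10, 0, 0))
  expect_equal(point_solid_distance(bx, c(12, 2, 1)), sqrt(1 + 1 + 0))
  cy <- solid("cylinder", c(100, 100, 50))
  expect_equal(point_solid_distance(cy, c(80, 0, 0)), 30)
  expect_equal(point_solid_distance(cy, c(0, 0, 100)), 75)
  expect_equal(point_solid_distance(cy, c(80, 0, 65)), sqrt(30^2 + 40^2))
})
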