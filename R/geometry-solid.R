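#' Rotation descriptors for solids
#'
#' A solid carries at most one rotation, applied after scaling and
#' translation: gantry-mounted parts rotate about y, couch-mounted parts
#' about z.
#'
#' @param theta,phi rotation angle in degrees.
#' @return a rotation descriptor list with fields `axis` and `angle`.
#' @export
rotation_none <- function() list(axis = "none", angle = 0)

#' @rdname rotation_none
#' @export
rotation_about_y <- function(theta) {
  if (length(theta) != 1L || !is.finite(theta)) cc_stop("theta must be a finite scalar")
  list(axis = "y", angle = as.numeric(theta))
}

#' @rdname rotation_none
#' @export
rotation_about_z <- function(phi) {
  if (length(phi) != 1L || !is.finite(phi)) cc_stop("phi must be a finite scalar")
  list(axis = "z", angle = as.numeric(phi))
}

valid_rotation <- function(rot) {
  is.list(rot) && identical(sort(names(rot)), c("angle", "axis")) &&
    rot$axis %in% c("none", "y", "z") &&
    length(rot$angle) == 1L && is.finite(rot$angle)
}

#' 3 x 3 rotation matrix of a rotation descriptor
#'
#' Matches the componentwise rotation equations used on meshes, so
#' `R %*% p` and [rotate_about_y()] / [rotate_about_z()] agree exactly.
#'
#' @param rot a rotation descriptor from [rotation_none()],
#'   [rotation_about_y()] or [rotation_about_z()].
#' @return a 3 x 3 orthonormal matrix.
#' @export
rotation_matrix <- function(rot) {
  if (!valid_rotation(rot)) cc_stop("invalid rotation descriptor")
  t <- rot$angle * pi / 180
  c_ <- cos(t); s_ <- sin(t)
  switch(rot$axis,
    none = diag(3),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Transformed primitive solid
#'
#' A solid is a unit primitive carried into the room by the fixed
#' transform chain scale -> translate -> rotate.  `scale` holds the full
#' extents (or diameters) in mm, `translation` the centre position before
#' rotation, and `rotation` the single optional rotation (about y for
#' gantry-mounted parts, about z for couch-mounted parts).
#'
#' @param kind `"box"`, `"cylinder"` or `"ellipsoid"`.
#' @param scale length-3 positive numeric, full extents/diameters (mm).
#' @param translation length-3 numeric centre before rotation (mm).
#' @param rotation a rotation descriptor; default none.
#' @param role free-text label (e.g. `"cone"`, `"couch_head"`).
#' @param color length-3 rgb in \[0, 1\].
#' @return an object of class `solid`.
#' @export
#' @examples
#' cone <- solid("cylinder", c(75, 75, 181), c(0, 0, 346.5), role = "cone")
#' contains_point(cone, c(0, 0, 300))
solid <- function(kind, scale, translation = c(0, 0, 0),
                  rotation = rotation_none(), role = "solid",
                  color = c(0.5, 0.5, 0.5)) {
  if (length(kind) != 1L || !kind %in% c("box", "cylinder", "ellipsoid")) {
    cc_stop("unknown primitive kind (use box, cylinder or ellipsoid)")
  }
  scale <- as.numeric(scale); translation <- as.numeric(translation)
  if (length(scale) != 3L || !all(is.finite(scale)) || any(scale <= 0)) {
    cc_stop("solid scale must be three positive finite extents (mm)")
  }
  if (length(translation) != 3L || !all(is.finite(translation))) {
    cc_stop("solid translation must be three finite values (mm)")
  }
  if (!valid_rotation(rotation)) cc_stop("invalid rotation descriptor")
  color <- as.numeric(color)
  if (length(color) != 3L || any(!is.finite(color)) || any(color < 0) || any(color > 1)) {
    cc_stop("color must be three rgb values in [0, 1]")
  }
  structure(list(kind = kind, scale = scale, translation = translation,
                 rotation = rotation, role = as.character(role)[1],
                 color = color),
            class = "solid")
}

#' @export
print.solid <- function(x, ...) {
  rot <- if (x$rotation$axis == "none") "no rotation" else
    sprintf("rotated %.6g deg about %s", x$rotation$angle, x$rotation$axis)
  cat(sprintf("<solid> %s '%s': extents (%.6g, %.6g, %.6g) mm at (%.6g, %.6g, %.6g), %s\n",
              x$kind, x$role, x$scale[1], x$scale[2], x$scale[3],
              x$translation[1], x$translation[2], x$translation[3], rot))
  invisible(x)
}

assert_solid <- function(s) {
  if (!inherits(s, "solid")) cc_stop("expected a solid object")
  invisible(s)
}

#' Centre of a solid in room coordinates
#'
#' @param s a [solid].
#' @return length-3 numeric (mm).
#' @export
solid_center <- function(s) {
  assert_solid(s)
  as.vector(rotation_matrix(s$rotation) %*% s$translation)
}

# Map room points into the solid's local (unrotated, centred) frame.
to_local <- function(s, P) {
  L <- P %*% rotation_matrix(s$rotation)  # row-vector form of t(R) %*% p
  sweep(L, 2L, s$translation)
}

#' Exact point containment test
#'
#' A point is inside when its inverse-transformed image lies in the unit
#' primitive; boundary points count as inside (conservative for collision
#' screening).  `tol` expands the solid by approximately `tol` mm in every
#' direction, which lets callers ask "within tol of the surface or inside".
#'
#' @param s a [solid].
#' @param p length-3 numeric room point (mm).
#' @param tol non-negative surface tolerance in mm (default 0: exact).
#' @return logical scalar.
#' @export
contains_point <- function(s, p, tol = 0) {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) cc_stop("point must be three finite values")
  contains_points(s, matrix(p, 1L, 3L), tol = tol)[1]
}

#' Vectorised point containment
#'
#' @param s a [solid].
#' @param P n x 3 numeric matrix of room points (mm).
#' @inheritParams contains_point
#' @return logical vector of length n.
#' @export
contains_points <- function(s, P, tol = 0) {
  assert_solid(s)
  if (!is.matrix(P) || ncol(P) != 3L) cc_stop("P must be an n x 3 matrix")
  if (length(tol) != 1L || !is.finite(tol) || tol < 0) cc_stop("tol must be >= 0")
  W <- to_local(s, P)
  h <- s$scale / 2 + tol
  switch(s$kind,
    box = abs(W[, 1]) <= h[1] & abs(W[, 2]) <= h[2] & abs(W[, 3]) <= h[3],
    cylinder = (W[, 1] / h[1])^2 + (W[, 2] / h[2])^2 <= 1 & abs(W[, 3]) <= h[3],
    ellipsoid = (W[, 1] / h[1])^2 + (W[, 2] / h[2])^2 + (W[, 3] / h[3])^2 <= 1
  )
}

#' Surface mesh of a solid
#'
#' Applies the fixed chain `rotate(scale_translate(unit_mesh(kind)))` with
#' the solid's own rotation.
#'
#' @param s a [solid].
#' @param resolution passed to [unit_mesh()]; defaults per kind.
#' @return a [surface_mesh] in room coordinates.
#' @export
solid_mesh <- function(s, resolution = NULL) {
  assert_solid(s)
  m <- if (is.null(resolution)) unit_mesh(s$kind) else unit_mesh(s$kind, resolution)
  m <- scale_translate(m, s$scale, s$translation)
  switch(s$rotation$axis,
    none = m,
    y = rotate_about_y(m, s$rotation$angle),
    z = rotate_about_z(m, s$rotation$angle)
  )
}

# ---- exact convex projections -------------------------------------------
#
# Every primitive here is convex, so the Euclidean projection of a point
# onto a solid is unique and has either a closed form (box; cylinder as a
# product of a disk and an interval) or a 1D root (ellipse/ellipsoid,
# solved by bisection on the Lagrange multiplier).  These projections are
# the workhorse of the clearance engine.

# Closest point on/in the elliptic disk (x/a)^2 + (y/b)^2 <= 1.
project_ellipse_disk <- function(x, y, a, b) {
  if ((x / a)^2 + (y / b)^2 <= 1) return(c(x, y))
  f <- function(t) (a * x / (a^2 + t))^2 + (b * y / (b^2 + t))^2 - 1
  lo <- 0
  hi <- max(a, b) * sqrt(x^2 + y^2) + max(a, b)^2
  while (f(hi) > 0) hi <- hi * 2
  for (i in 1:100) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  t <- 0.5 * (lo + hi)
  c(a^2 * x / (a^2 + t), b^2 * y / (b^2 + t))
}

# Closest point on/in the solid ellipsoid with semi-axes h (local frame).
project_ellipsoid_solid <- function(w, h) {
  if (sum((w / h)^2) <= 1) return(w)
  f <- function(t) sum((h * w / (h^2 + t))^2) - 1
  lo <- 0
  hi <- max(h) * sqrt(sum(w^2)) + max(h)^2
  while (f(hi) > 0) hi <- hi * 2
  for (i in 1:100) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  t <- 0.5 * (lo + hi)
  h^2 * w / (h^2 + t)
}

#' Euclidean projection of a point onto a solid
#'
#' Returns the closest point of the (filled, convex) solid to `p`; `p`
#' itself when `p` is inside.
#'
#' @param s a [solid].
#' @param p length-3 numeric room point (mm).
#' @return length-3 numeric room point (mm).
#' @export
project_point_solid <- function(s, p) {
  assert_solid(s)
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) cc_stop("point must be three finite values")
  R <- rotation_matrix(s$rotation)
  w <- as.vector(crossprod(R, p)) - s$translation
  h <- s$scale / 2
  q <- switch(s$kind,
    box = pmin(pmax(w, -h), h),
    cylinder = {
      xy <- project_ellipse_disk(w[1], w[2], h[1], h[2])
      c(xy, min(max(w[3], -h[3]), h[3]))
    },
    ellipsoid = project_ellipsoid_solid(w, h)
  )
  as.vector(R %*% (q + s$translation))
}

#' Distance from a point to a solid
#'
#' @param s a [solid].
#' @param p length-3 numeric room point (mm).
#' @return non-negative distance in mm (0 when `p` is inside).
#' @export
point_solid_distance <- function(s, p) {
  q <- project_point_solid(s, p)
  sqrt(sum((as.numeric(p) - q)^2))
}
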