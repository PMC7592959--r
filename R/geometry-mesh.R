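#' Room-frame vector (mm)
#'
#' Coordinates follow the IEC 61217 fixed system for a head-first supine
#' patient: `x` points to the patient's left, `y` superior, `z` anterior.
#' All geometry in the package lives in this frame, in millimetres.
#'
#' @param x,y,z finite numeric scalars (mm).
#' @return a named numeric vector of length 3.
#' @export
#' @examples
#' vec3(10, 0, -5)
vec3 <- function(x, y, z) {
  v <- c(x = as.numeric(x)[1], y = as.numeric(y)[1], z = as.numeric(z)[1])
  if (!all(is.finite(v))) cc_stop("vec3 components must be finite")
  v
}

#' Parametric surface mesh
#'
#' A surface sampled on a rectangular (u, v) grid, stored as three
#' equal-shape matrices of vertex coordinates.  Primitives whose boundary is
#' not a single smooth patch (box faces, cylinder caps) are stitched
#' row-wise into one mesh; `blocks` records the row count of each smooth
#' patch so renderers and samplers never quad across a seam.
#'
#' @param xs,ys,zs numeric matrices of identical shape, at least 2 x 2,
#'   all entries finite (mm).
#' @param blocks integer vector of per-patch row counts summing to
#'   `nrow(xs)`; defaults to a single block.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(xs, ys, zs, blocks = NULL) {
  if (!is.matrix(xs) || !is.matrix(ys) || !is.matrix(zs) ||
      !identical(dim(xs), dim(ys)) || !identical(dim(xs), dim(zs))) {
    cc_stop("xs, ys, zs must be matrices of identical shape")
  }
  if (nrow(xs) < 2L || ncol(xs) < 2L) cc_stop("mesh grids must be at least 2 x 2")
  if (!all(is.finite(xs)) || !all(is.finite(ys)) || !all(is.finite(zs))) {
    cc_stop("mesh coordinates must be finite")
  }
  blocks <- as.integer(blocks %||% nrow(xs))
  if (sum(blocks) != nrow(xs) || any(blocks < 2L)) {
    cc_stop("blocks must be >= 2 rows each and sum to nrow(xs)")
  }
  structure(list(xs = xs, ys = ys, zs = zs, blocks = blocks),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d x %d grid, %d patch(es)\n",
              nrow(x$xs), ncol(x$xs), length(x$blocks)))
  ext <- mesh_extents(x)
  cat(sprintf("  extents x [%.6g, %.6g]  y [%.6g, %.6g]  z [%.6g, %.6g]\n",
              ext[1, 1], ext[1, 2], ext[2, 1], ext[2, 2], ext[3, 1], ext[3, 2]))
  invisible(x)
}

#' Surface mesh of a unit primitive
#'
#' Unit primitives are centred on the origin with size 1 in every
#' direction: the box has all edges of length 1, the cylinder (axis along
#' z) has diameter and height 1, and the ellipsoid is a sphere of
#' diameter 1.  Every commissioned component is obtained from one of these
#' by scaling, translating and (optionally) rotating.
#'
#' @param kind one of `"box"`, `"cylinder"`, `"ellipsoid"`.
#' @param resolution for the box, vertices per face edge (>= 2, 2 gives
#'   sharp-cornered quads); for curved primitives, azimuthal sample count
#'   (>= 2; the axial/polar count is `resolution / 2 + 1`).  Even values
#'   keep the mesh symmetric under lateral mirroring.
#' @return a [surface_mesh] whose vertices lie on the primitive boundary,
#'   with bounding extents exactly \[-0.5, 0.5\] on every axis.
#' @export
#' @examples
#' m <- unit_mesh("cylinder", 64)
#' range(m$zs)
unit_mesh <- function(kind, resolution = if (identical(kind, "box")) 2L else 64L) {
  if (length(kind) != 1L || !kind %in% c("box", "cylinder", "ellipsoid")) {
    cc_stop("unknown primitive kind (use box, cylinder or ellipsoid)")
  }
  resolution <- as.integer(resolution)
  if (length(resolution) != 1L || is.na(resolution) || resolution < 2L) {
    cc_stop("resolution must be an integer >= 2")
  }
  switch(kind,
    box = unit_box_mesh(resolution),
    cylinder = unit_cylinder_mesh(resolution),
    ellipsoid = unit_ellipsoid_mesh(resolution)
  )
}

unit_box_mesh <- function(r) {
  s <- seq(-0.5, 0.5, length.out = r)
  along_rows <- matrix(s, r, r)               # varies down rows
  along_cols <- matrix(s, r, r, byrow = TRUE) # varies across columns
  flat <- function(v) matrix(v, r, r)
  xs <- ys <- zs <- vector("list", 6L)
  # faces x = +/-0.5, y = +/-0.5, z = +/-0.5
  xs[[1]] <- flat(0.5);  ys[[1]] <- along_rows; zs[[1]] <- along_cols
  xs[[2]] <- flat(-0.5); ys[[2]] <- along_rows; zs[[2]] <- along_cols
  xs[[3]] <- along_rows; ys[[3]] <- flat(0.5);  zs[[3]] <- along_cols
  xs[[4]] <- along_rows; ys[[4]] <- flat(-0.5); zs[[4]] <- along_cols
  xs[[5]] <- along_rows; ys[[5]] <- along_cols; zs[[5]] <- flat(0.5)
  xs[[6]] <- along_rows; ys[[6]] <- along_cols; zs[[6]] <- flat(-0.5)
  surface_mesh(do.call(rbind, xs), do.call(rbind, ys), do.call(rbind, zs),
               blocks = rep(r, 6L))
}

unit_cylinder_mesh <- function(r) {
  th <- seq(0, 2 * pi, length.out = r + 1L)
  na <- r %/% 2L + 1L                  # axial rows on the shell
  nr <- max(3L, r %/% 8L + 1L)         # radial rings on each cap
  zz <- seq(-0.5, 0.5, length.out = na)
  shell_x <- matrix(0.5 * cos(th), na, r + 1L, byrow = TRUE)
  shell_y <- matrix(0.5 * sin(th), na, r + 1L, byrow = TRUE)
  shell_z <- matrix(zz, na, r + 1L)
  rad <- seq(0, 0.5, length.out = nr)
  cap_x <- outer(rad, cos(th))
  cap_y <- outer(rad, sin(th))
  cap <- function(z0) matrix(z0, nr, r + 1L)
  surface_mesh(rbind(shell_x, cap_x, cap_x),
               rbind(shell_y, cap_y, cap_y),
               rbind(shell_z, cap(0.5), cap(-0.5)),
               blocks = c(na, nr, nr))
}

unit_ellipsoid_mesh <- function(r) {
  th <- seq(0, 2 * pi, length.out = r + 1L)
  ph <- seq(0, pi, length.out = r %/% 2L + 1L)
  surface_mesh(0.5 * outer(sin(ph), cos(th)),
               0.5 * outer(sin(ph), sin(th)),
               0.5 * matrix(cos(ph), length(ph), r + 1L))
}

#' Scale and translate a mesh componentwise
#'
#' Applies `x_scaled = C_x * x_unit + delta_x` (and likewise for y, z): the
#' second step of the unit-object construction.
#'
#' @param mesh a [surface_mesh].
#' @param C numeric length-3 positive scale (full extents / diameters, mm).
#' @param delta numeric length-3 translation (mm).
#' @return the transformed [surface_mesh] (same shape and blocks).
#' @export
scale_translate <- function(mesh, C, delta = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  C <- as.numeric(C); delta <- as.numeric(delta)
  if (length(C) != 3L || !all(is.finite(C)) || any(C <= 0)) {
    cc_stop("scale C must be three positive finite values")
  }
  if (length(delta) != 3L || !all(is.finite(delta))) {
    cc_stop("translation must be three finite values")
  }
  surface_mesh(C[1] * mesh$xs + delta[1],
               C[2] * mesh$ys + delta[2],
               C[3] * mesh$zs + delta[3],
               blocks = mesh$blocks)
}

#' Rotate a mesh about the y (gantry) axis
#'
#' Implements `x' = x cos(theta) - z sin(theta); z' = x sin(theta) +
#' z cos(theta)` with `y` unchanged.  Positive `theta` carries +x towards
#' +z; machine sign conventions are absorbed upstream by the commissioning
#' flags, never here.
#'
#' @param mesh a [surface_mesh].
#' @param theta rotation angle in degrees.
#' @return the rotated [surface_mesh].
#' @export
rotate_about_y <- function(mesh, theta) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(theta) != 1L || !is.finite(theta)) cc_stop("theta must be a finite scalar")
  t <- theta * pi / 180
  xs <- mesh$xs * cos(t) - mesh$zs * sin(t)
  zs <- mesh$xs * sin(t) + mesh$zs * cos(t)
  surface_mesh(xs, mesh$ys, zs, blocks = mesh$blocks)
}

#' Rotate a mesh about the z (couch) axis
#'
#' Implements `x' = x cos(phi) - y sin(phi); y' = x sin(phi) + y cos(phi)`
#' with `z` unchanged; positive `phi` carries +x towards +y.
#'
#' @inheritParams rotate_about_y
#' @param phi rotation angle in degrees.
#' @return the rotated [surface_mesh].
#' @export
rotate_about_z <- function(mesh, phi) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(phi) != 1L || !is.finite(phi)) cc_stop("phi must be a finite scalar")
  t <- phi * pi / 180
  xs <- mesh$xs * cos(t) - mesh$ys * sin(t)
  ys <- mesh$xs * sin(t) + mesh$ys * cos(t)
  surface_mesh(xs, ys, mesh$zs, blocks = mesh$blocks)
}

#' Flatten a mesh to an n x 3 vertex matrix
#'
#' @param mesh a [surface_mesh].
#' @return numeric matrix with columns x, y, z (mm), one row per vertex.
#' @export
mesh_points <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  cbind(x = as.vector(mesh$xs), y = as.vector(mesh$ys), z = as.vector(mesh$zs))
}

#' Axis-aligned bounding extents of a mesh
#'
#' @param mesh a [surface_mesh].
#' @return 3 x 2 matrix of (min, max) per room axis (mm).
#' @export
mesh_extents <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  rbind(x = range(mesh$xs), y = range(mesh$ys), z = range(mesh$zs))
}
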