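#' Rendering options for room views
#'
#' @param resolution per-kind mesh resolution used for drawing (box faces
#'   stay sharp at 2; curved solids default to smooth 64-sample shells).
#' @param alpha transparency of the safety zone in \[0, 1\] (other solids
#'   are opaque); 0.8 keeps the couch visible through the envelope.
#' @param view c(azimuth, elevation) in degrees; the default looks from
#'   the foot of the couch, slightly elevated.
#' @param show_axes draw room axes with the configured planning-system
#'   labels.
#' @return a list of class `render_spec`.
#' @export
render_spec <- function(resolution = list(box = 2L, cylinder = 64L,
                                          ellipsoid = 64L),
                        alpha = 0.8,
                        view = c(azimuth = -50, elevation = 18),
                        show_axes = TRUE) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha > 1) {
    cc_stop("alpha must be in [0, 1]")
  }
  structure(list(resolution = resolution, alpha = alpha,
                 view = c(azimuth = as.numeric(view[[1]]),
                          elevation = as.numeric(view[[2]])),
                 show_axes = isTRUE(show_axes)),
            class = "render_spec")
}

# Orthographic projection: screen (sx, sy) plus depth towards the viewer.
project_view <- function(P, view) {
  a <- view[["azimuth"]] * pi / 180
  e <- view[["elevation"]] * pi / 180
  fwd <- P[, 1] * cos(a) + P[, 2] * sin(a)
  cbind(sx = -P[, 1] * sin(a) + P[, 2] * cos(a),
        sy = -fwd * sin(e) + P[, 3] * cos(e),
        depth = fwd * cos(e) + P[, 3] * sin(e))
}

# Split a mesh into quads: 4 x nquad coordinate matrices per axis.
mesh_quads <- function(mesh) {
  qx <- qy <- qz <- list()
  row0 <- 0L
  nc <- ncol(mesh$xs)
  for (b in mesh$blocks) {
    rows <- row0 + seq_len(b)
    i <- rep(seq_len(b - 1L), nc - 1L)
    j <- rep(seq_len(nc - 1L), each = b - 1L)
    idx <- function(ii, jj) cbind(rows[ii], jj)
    corner <- function(M, di, dj) M[idx(i + di, j + dj)]
    take <- function(M) rbind(corner(M, 0L, 0L), corner(M, 1L, 0L),
                              corner(M, 1L, 1L), corner(M, 0L, 1L))
    qx[[length(qx) + 1L]] <- take(mesh$xs)
    qy[[length(qy) + 1L]] <- take(mesh$ys)
    qz[[length(qz) + 1L]] <- take(mesh$zs)
    row0 <- row0 + b
  }
  list(x = do.call(cbind, qx), y = do.call(cbind, qy), z = do.call(cbind, qz))
}

solid_draw_data <- function(s, spec) {
  mesh <- solid_mesh(s, spec$resolution[[s$kind]])
  quads <- mesh_quads(mesh)
  alpha <- if (identical(s$role, "safety_zone")) spec$alpha else 1
  list(role = s$role, color = s$color, alpha = alpha,
       mesh = mesh, quads = quads)
}

draw_quads <- function(draw_list, spec, main = NULL, labels = NULL) {
  allx <- unlist(lapply(draw_list, function(d) d$quads$x))
  ally <- unlist(lapply(draw_list, function(d) d$quads$y))
  allz <- unlist(lapply(draw_list, function(d) d$quads$z))
  proj_all <- project_view(cbind(allx, ally, allz), spec$view)
  sx <- matrix(proj_all[, "sx"], nrow = 4L)
  sy <- matrix(proj_all[, "sy"], nrow = 4L)
  depth <- colMeans(matrix(proj_all[, "depth"], nrow = 4L))
  cols <- unlist(lapply(draw_list, function(d) {
    base <- grDevices::rgb(d$color[1], d$color[2], d$color[3], alpha = d$alpha)
    rep(base, ncol(d$quads$x))
  }))
  ord <- order(depth)  # farthest first
  graphics::par(mar = c(1, 1, if (is.null(main)) 1 else 2, 1))
  graphics::plot(range(sx), range(sy), type = "n", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  px <- rbind(sx[, ord], NA)
  py <- rbind(sy[, ord], NA)
  graphics::polygon(as.vector(px), as.vector(py), col = cols[ord],
                    border = grDevices::adjustcolor("black", alpha.f = 0.15),
                    lwd = 0.3)
  if (spec$show_axes && !is.null(labels)) {
    L <- 400
    axes <- rbind(c(L, 0, 0), c(0, L, 0), c(0, 0, L), c(0, 0, 0))
    pa <- project_view(axes, spec$view)
    for (i in 1:3) {
      graphics::segments(pa[4, "sx"], pa[4, "sy"], pa[i, "sx"], pa[i, "sy"],
                         col = "grey40", lty = 3)
    }
    graphics::text(pa[1:3, "sx"], pa[1:3, "sy"],
                   labels = c(labels$lat, labels$si, labels$ap),
                   col = "grey25", cex = 0.8)
  }
}

#' Render a room scene
#'
#' Draws one surface per solid (safety zone, couch head/body, cone,
#' gantry head) with the commissioned colors, depth-sorted for a simple
#' room's-eye view.  With `out` set, a PNG is written; with `out = NULL`
#' the current graphics device is used, and `draw = FALSE` skips drawing
#' entirely while still returning the projected geometry (useful headless).
#'
#' @param scene a scene from [build_scene()].
#' @param spec a [render_spec()].
#' @param out PNG path, or `NULL` for the active device.
#' @param draw logical; set `FALSE` to compute geometry without a device.
#' @param width,height PNG size in pixels.
#' @return (invisibly) a list with `file`, `n_surfaces`, per-solid `roles`,
#'   `colors` and vertex sets (`vertices`), identical whether or not a
#'   device was involved.
#' @export
render_scene <- function(scene, spec = render_spec(), out = NULL,
                         draw = TRUE, width = 900, height = 700) {
  stopifnot(inherits(scene, "scene"), inherits(spec, "render_spec"))
  draw_list <- lapply(scene$solids, solid_draw_data, spec = spec)
  labels <- list(ap = scene$cfg$label_ap, lat = scene$cfg$label_lat,
                 si = scene$cfg$label_si)
  if (!is.null(out)) {
    ok <- tryCatch({
      grDevices::png(out, width = width, height = height)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) cc_io_error(sprintf("cannot open output image: %s", out))
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_quads(draw_list, spec, labels = labels)
  } else if (isTRUE(draw)) {
    draw_quads(draw_list, spec, labels = labels)
  }
  invisible(list(file = out,
                 n_surfaces = length(draw_list),
                 roles = vapply(draw_list, `[[`, character(1), "role"),
                 colors = lapply(draw_list, `[[`, "color"),
                 vertices = lapply(draw_list, function(d) mesh_points(d$mesh))))
}

#' Render an arc overlay
#'
#' Patient-mounted solids are drawn once; the cone and gantry head are
#' drawn once per sampled gantry angle (the identical angles that
#' [sweep_arc()] scores), giving the swept-arc view used to judge
#' clearance at a glance.
#'
#' @param cfg a [machine_config()].
#' @param plan a [plan_context()].
#' @param arc an [arc_spec()].
#' @param spec a [render_spec()].
#' @param direction sweep direction, see [arc_angles()].
#' @inheritParams render_scene
#' @return (invisibly) a list as in [render_scene()]; machine-side
#'   surfaces appear once per sampled angle.
#' @export
render_arc <- function(cfg, plan, arc, spec = render_spec(), out = NULL,
                       draw = TRUE, direction = "forward",
                       width = 900, height = 700) {
  stopifnot(inherits(arc, "arc_spec"), inherits(spec, "render_spec"))
  angles <- arc_angles(arc, direction)
  scene0 <- build_scene(cfg, plan, arc$couch, angles[1])
  draw_list <- lapply(scene0$solids[patient_roles], solid_draw_data,
                      spec = spec)
  for (g in angles) {
    sc <- build_scene(cfg, plan, arc$couch, g)
    for (m in machine_roles) {
      draw_list[[length(draw_list) + 1L]] <- solid_draw_data(sc$solids[[m]],
                                                             spec)
    }
  }
  labels <- list(ap = cfg$label_ap, lat = cfg$label_lat, si = cfg$label_si)
  id <- if (is.na(arc$id)) "" else sprintf("beam %s: ", arc$id)
  main <- sprintf("%scouch %g, gantry %g to %g", id, arc$couch,
                  arc$gantry_start, arc$gantry_stop)
  if (!is.null(out)) {
    ok <- tryCatch({
      grDevices::png(out, width = width, height = height)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) cc_io_error(sprintf("cannot open output image: %s", out))
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_quads(draw_list, spec, main = main, labels = labels)
  } else if (isTRUE(draw)) {
    draw_quads(draw_list, spec, main = main, labels = labels)
  }
  invisible(list(file = out,
                 n_surfaces = length(draw_list),
                 roles = vapply(draw_list, `[[`, character(1), "role"),
                 colors = lapply(draw_list, `[[`, "color"),
                 vertices = lapply(draw_list, function(d) mesh_points(d$mesh))))
}
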