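#' Numerical precision controls for clearance evaluation
#'
#' `sample_resolution` sets the surface sampling used for the intersection
#' test (and for projection starting points); `max_iter` / `tol` control
#' the alternating-projection minimiser; `contact_tol` is the separation
#' (mm) below which two solids are reported as touching/intersecting.
#'
#' @param box,cylinder,ellipsoid per-kind mesh resolution for boundary
#'   sampling (see [unit_mesh()]).
#' @param max_iter maximum alternating-projection iterations.
#' @param tol relative stopping tolerance on the distance iterate.
#' @param contact_tol contact separation in mm.
#' @return a list of class `clearance_precision`.
#' @export
clearance_precision <- function(box = 8L, cylinder = 24L, ellipsoid = 24L,
                                max_iter = 200L, tol = 1e-12,
                                contact_tol = 1e-6) {
  structure(list(sample_resolution = list(box = as.integer(box),
                                          cylinder = as.integer(cylinder),
                                          ellipsoid = as.integer(ellipsoid)),
                 max_iter = as.integer(max_iter), tol = tol,
                 contact_tol = contact_tol),
            class = "clearance_precision")
}

sample_solid_points <- function(s, precision) {
  mesh_points(solid_mesh(s, precision$sample_resolution[[s$kind]]))
}

# Core clearance on precomputed boundary samples.  Intersection is decided
# by boundary-sample/centroid containment, backed by the minimiser driving
# the separation to ~0.  Both solids are convex, so alternating Euclidean
# projections converge to the globally closest pair from any start
# (and to a common point when the solids overlap).
pair_clearance_core <- function(a, b, pts_a, pts_b, precision) {
  inter <- any(contains_points(b, pts_a)) || any(contains_points(a, pts_b)) ||
    contains_point(b, solid_center(a)) || contains_point(a, solid_center(b))
  d <- 0
  if (!inter) {
    p <- solid_center(a)
    d_prev <- Inf
    for (i in seq_len(precision$max_iter)) {
      q <- project_point_solid(b, p)
      p <- project_point_solid(a, q)
      d <- sqrt(sum((p - q)^2))
      if (is.finite(d_prev) && d_prev - d <= precision$tol * max(1, d)) break
      d_prev <- d
    }
    if (d <= precision$contact_tol) {
      inter <- TRUE
      d <- 0
    }
  }
  list(distance = d, intersecting = inter)
}

#' Minimum clearance between two solids
#'
#' Reports whether the two convex solids intersect and, when disjoint,
#' their minimum surface-to-surface distance.  Intersection is detected by
#' exact containment of sampled boundary points (and of either centre);
#' the distance is computed to machine precision by alternating convex
#' projections, so the result is accurate far inside the max(1 mm, 1%)
#' band expected of it.
#'
#' @param a,b [solid] objects.
#' @param precision a [clearance_precision()].
#' @return a list of class `pair_clearance` with fields `role_a`,
#'   `role_b`, `distance` (mm, 0 when intersecting) and `intersecting`.
#' @export
#' @examples
#' a <- solid("box", c(1, 1, 1))
#' b <- solid("box", c(1, 1, 1), c(3, 0, 0))
#' pair_clearance(a, b)$distance
pair_clearance <- function(a, b, precision = clearance_precision()) {
  assert_solid(a); assert_solid(b)
  stopifnot(inherits(precision, "clearance_precision"))
  res <- pair_clearance_core(a, b,
                             sample_solid_points(a, precision),
                             sample_solid_points(b, precision),
                             precision)
  structure(list(role_a = a$role, role_b = b$role,
                 distance = res$distance, intersecting = res$intersecting),
            class = "pair_clearance")
}

#' @export
print.pair_clearance <- function(x, ...) {
  cat(sprintf("<pair_clearance> %s vs %s: %s (%.3f mm)\n", x$role_a, x$role_b,
              if (x$intersecting) "INTERSECTING" else "disjoint", x$distance))
  invisible(x)
}

#' Three-way clearance classification
#'
#' An arc collides when any pose intersects, is close when the minimum
#' clearance is under the threshold (default 10 mm, i.e. "under 1 cm"),
#' and clears otherwise; a clearance exactly at the threshold counts as
#' clear.
#'
#' @param min_clearance minimum clearance in mm.
#' @param intersecting logical: did any pair intersect?
#' @param threshold close-call threshold in mm (> 0).
#' @return `"collide"`, `"close"` or `"clear"`.
#' @export
classify <- function(min_clearance, intersecting, threshold = 10) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0) {
    cc_stop("threshold must be a positive number of mm")
  }
  if (isTRUE(intersecting)) return("collide")
  if (min_clearance < threshold) return("close")
  "clear"
}

#' Arc specification
#'
#' One treatment arc: fixed couch angle, gantry sweeping from
#' `gantry_start` to `gantry_stop` on the machine readout scale, sampled
#' at `n_points` linearly spaced angles (endpoints included).
#'
#' @param couch couch angle (degrees, readout scale).
#' @param gantry_start,gantry_stop gantry angles (degrees, readout scale).
#' @param n_points number of sampled gantry angles (>= 2); the default 36
#'   keeps the spacing at or under ~5 degrees for a 175-degree arc.
#' @param id optional beam identifier used in reports.
#' @return an object of class `arc_spec`.
#' @export
arc_spec <- function(couch, gantry_start, gantry_stop, n_points = 36L,
                     id = NULL) {
  vals <- c(couch, gantry_start, gantry_stop)
  if (length(vals) != 3L || !all(is.finite(vals))) {
    cc_stop("arc angles must be finite scalars")
  }
  n_points <- as.integer(n_points)
  if (length(n_points) != 1L || is.na(n_points) || n_points < 2L) {
    cc_stop("n_points must be an integer >= 2")
  }
  structure(list(couch = as.numeric(couch),
                 gantry_start = as.numeric(gantry_start),
                 gantry_stop = as.numeric(gantry_stop),
                 n_points = n_points,
                 id = if (is.null(id)) NA_character_ else as.character(id)),
            class = "arc_spec")
}

#' Gantry angles sampled along an arc
#'
#' Linear spacing from start to stop on the readout scale, with no 0/360
#' wrapping; `direction = "reverse"` sweeps the complementary way around
#' the circle between the same endpoints.
#'
#' @param arc an [arc_spec()].
#' @param direction `"forward"` or `"reverse"`.
#' @return numeric vector of `n_points` gantry angles (degrees).
#' @export
arc_angles <- function(arc, direction = c("forward", "reverse")) {
  stopifnot(inherits(arc, "arc_spec"))
  direction <- match.arg(direction)
  stop <- arc$gantry_stop
  if (direction == "reverse") {
    stop <- stop + if (stop >= arc$gantry_start) -360 else 360
  }
  seq(arc$gantry_start, stop, length.out = arc$n_points)
}

#' Sweep one arc and score every machine-patient pair
#'
#' At each sampled gantry angle the scene is rebuilt and all six
#' machine-side x patient-side pairs ({cone, gantry_head} x {couch_head,
#' couch_body, safety_zone}) are evaluated.  Machine self-pairs and
#' couch-vs-safety-zone are rigidly attached and never scored.
#'
#' @param cfg a [machine_config()].
#' @param plan a [plan_context()].
#' @param arc an [arc_spec()].
#' @param precision a [clearance_precision()].
#' @param direction sweep direction, see [arc_angles()].
#' @return an object of class `clearance_result` with the per-sample pair
#'   table (`samples`), `min_clearance` (mm), `argmin_gantry` (degrees),
#'   `limiting_pair` and `classification`.
#' @export
sweep_arc <- function(cfg, plan, arc, precision = clearance_precision(),
                      direction = "forward") {
  stopifnot(inherits(cfg, "machine_config"), inherits(plan, "plan_context"),
            inherits(arc, "arc_spec"))
  angles <- arc_angles(arc, direction)
  scene0 <- build_scene(cfg, plan, arc$couch, angles[1])
  pts_patient <- lapply(scene0$solids[patient_roles], sample_solid_points,
                        precision = precision)
  n_rows <- length(angles) * length(machine_roles) * length(patient_roles)
  gantry_col <- numeric(n_rows); ra <- character(n_rows)
  rb <- character(n_rows); dist_col <- numeric(n_rows)
  int_col <- logical(n_rows)
  k <- 0L
  for (g in angles) {
    sc <- build_scene(cfg, plan, arc$couch, g)
    for (m in machine_roles) {
      sm <- sc$solids[[m]]
      pts_m <- sample_solid_points(sm, precision)
      for (p in patient_roles) {
        res <- pair_clearance_core(sm, sc$solids[[p]], pts_m,
                                   pts_patient[[p]], precision)
        k <- k + 1L
        gantry_col[k] <- g; ra[k] <- m; rb[k] <- p
        dist_col[k] <- res$distance; int_col[k] <- res$intersecting
      }
    }
  }
  samples <- data.frame(gantry_user = gantry_col, role_a = ra, role_b = rb,
                        distance = dist_col, intersecting = int_col,
                        stringsAsFactors = FALSE)
  imin <- which.min(samples$distance)
  structure(list(arc = arc, samples = samples,
                 min_clearance = samples$distance[imin],
                 argmin_gantry = samples$gantry_user[imin],
                 limiting_pair = paste(samples$role_a[imin],
                                       samples$role_b[imin], sep = ":"),
                 classification = classify(samples$distance[imin],
                                           any(samples$intersecting),
                                           cfg$close_threshold_mm)),
            class = "clearance_result")
}

#' @export
print.clearance_result <- function(x, ...) {
  id <- if (is.na(x$arc$id)) "" else sprintf(" beam %s", x$arc$id)
  cat(sprintf("<clearance_result>%s couch %g, gantry %g -> %g: %s\n",
              id, x$arc$couch, x$arc$gantry_start, x$arc$gantry_stop,
              toupper(x$classification)))
  cat(sprintf("  min clearance %.2f mm (%s at gantry %.1f)\n",
              x$min_clearance, x$limiting_pair, x$argmin_gantry))
  invisible(x)
}

#' Evaluate a list of arcs against one plan
#'
#' @param cfg a [machine_config()].
#' @param plan a [plan_context()].
#' @param arcs non-empty list of [arc_spec()] objects.
#' @param ... passed on to [sweep_arc()].
#' @return list of `clearance_result`, one per arc, order preserved.
#' @export
evaluate_plan <- function(cfg, plan, arcs, ...) {
  if (!is.list(arcs) || length(arcs) < 1L ||
      !all(vapply(arcs, inherits, logical(1), "arc_spec"))) {
    cc_stop("arcs must be a non-empty list of arc_spec objects")
  }
  lapply(arcs, function(a) sweep_arc(cfg, plan, a, ...))
}
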