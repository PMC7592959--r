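#' Plan context: reference point, isocenter and safety-zone shape
#'
#' Planning-system coordinates are given per axis (`lat`, `ap`, `si`) in
#' the same units as the commissioning survey (mm here).  The reference
#' point is a CT-visible landmark whose commissioning-time relation to the
#' safety-zone centre lets the plan coordinates place the collision
#' envelope relative to the treatment isocenter.
#'
#' @param ref_plan named numeric with elements `lat`, `ap`, `si`:
#'   reference-point coordinates in the current plan.
#' @param iso_plan named numeric with elements `lat`, `ap`, `si`:
#'   treatment isocenter coordinates in the current plan.
#' @param sz_shape `"box"` (localization-frame envelope) or `"ellipsoid"`.
#' @return an object of class `plan_context`.
#' @export
#' @examples
#' plan_context(c(lat = 103.1, ap = 4, si = 23.3),
#'              c(lat = 2, ap = 1.8, si = 0.8))
plan_context <- function(ref_plan, iso_plan, sz_shape = c("box", "ellipsoid")) {
  sz_shape <- match.arg(sz_shape)
  axis3 <- function(v, what) {
    v <- unlist(v)
    if (length(v) != 3L || !all(c("lat", "ap", "si") %in% names(v)) ||
        !all(is.finite(v))) {
      cc_stop(sprintf("%s must be finite values named lat, ap, si", what))
    }
    v[c("lat", "ap", "si")]
  }
  structure(list(ref_plan = axis3(ref_plan, "ref_plan"),
                 iso_plan = axis3(iso_plan, "iso_plan"),
                 sz_shape = sz_shape),
            class = "plan_context")
}

#' Room-frame offset of the safety-zone centre from the isocenter
#'
#' Per planning axis `a` in lat/ap/si the offset is
#' `dir_a * ((szcomm_a - refcomm_a) + (ref_plan_a - iso_plan_a))`: the
#' commissioned vector from reference point to safety-zone centre, carried
#' to the current plan through the reference point and re-expressed
#' relative to the isocenter, with the planning system's shift sign flags
#' applied.  Planning axes map to room axes as lat -> x, ap -> z,
#' si -> y.
#'
#' @param plan a [plan_context()].
#' @param cfg a [machine_config()].
#' @return a [vec3()]: safety-zone centre relative to isocenter (mm).
#' @export
patient_offset <- function(plan, cfg) {
  stopifnot(inherits(plan, "plan_context"), inherits(cfg, "machine_config"))
  szcomm <- c(lat = cfg$szlatcomm, ap = cfg$szapcomm, si = cfg$szsicomm)
  refcomm <- c(lat = cfg$reflatcomm, ap = cfg$refapcomm, si = cfg$refsicomm)
  dirs <- c(lat = cfg$latdir, ap = cfg$apdir, si = cfg$sidir)
  off <- dirs * ((szcomm - refcomm) + (plan$ref_plan - plan$iso_plan))
  vec3(off[["lat"]], off[["si"]], off[["ap"]])
}

#' Build the full room scene for one couch/gantry pose
#'
#' Places five solids around the isocenter (the origin):
#' \describe{
#'   \item{safety_zone}{box or ellipsoid of extents
#'     `(szr+szl, szs+szi, sza+szp)` centred on the patient offset plus
#'     the asymmetry of the commissioned extents.}
#'   \item{couch_head, couch_body}{boxes of thickness `cht` whose top
#'     surface sits `chad` below the safety-zone centre; the body abuts
#'     the head at its inferior edge.}
#'   \item{cone}{cylinder of diameter `cod` spanning `z` in `[cad, had]`
#'     on the beam axis.}
#'   \item{gantry_head}{cylinder of diameter `hod` spanning `z` in
#'     `[had, had + ht]`.}
#' }
#' Couch-mounted solids carry the internal couch rotation about z;
#' gantry-mounted solids the internal gantry rotation about y.
#'
#' @param cfg a [machine_config()].
#' @param plan a [plan_context()].
#' @param couch_user couch angle on the machine readout scale (degrees).
#' @param gantry_user gantry angle on the machine readout scale (degrees).
#' @return an object of class `scene` with fields `solids` (named list),
#'   `gantry_internal`, `couch_internal`, `patient_offset`.
#' @export
build_scene <- function(cfg, plan, couch_user, gantry_user) {
  stopifnot(inherits(cfg, "machine_config"), inherits(plan, "plan_context"))
  g_int <- internal_gantry_angle(gantry_user, cfg)
  c_int <- internal_couch_angle(couch_user, cfg)
  off <- patient_offset(plan, cfg)
  rot_c <- rotation_about_z(c_int)
  rot_g <- rotation_about_y(g_int)

  sz <- solid(plan$sz_shape,
              scale = c(cfg$szr + cfg$szl, cfg$szs + cfg$szi, cfg$sza + cfg$szp),
              translation = off + c((cfg$szl - cfg$szr) / 2,
                                    (cfg$szs - cfg$szi) / 2,
                                    (cfg$sza - cfg$szp) / 2),
              rotation = rot_c, role = "safety_zone", color = cfg$szcolor)
  couch_top_z <- off[["z"]] - cfg$chad
  couch_head <- solid("box",
                      scale = c(cfg$chw, cfg$chse - cfg$chie, cfg$cht),
                      translation = c(off[["x"]],
                                      off[["y"]] + (cfg$chse + cfg$chie) / 2,
                                      couch_top_z - cfg$cht / 2),
                      rotation = rot_c, role = "couch_head", color = cfg$chcolor)
  couch_body <- solid("box",
                      scale = c(cfg$cbw, cfg$chie - cfg$cbie, cfg$cht),
                      translation = c(off[["x"]],
                                      off[["y"]] + (cfg$chie + cfg$cbie) / 2,
                                      couch_top_z - cfg$cht / 2),
                      rotation = rot_c, role = "couch_body", color = cfg$chcolor)
  cone <- solid("cylinder",
                scale = c(cfg$cod, cfg$cod, cfg$had - cfg$cad),
                translation = c(0, 0, (cfg$cad + cfg$had) / 2),
                rotation = rot_g, role = "cone", color = cfg$ccolor)
  head <- solid("cylinder",
                scale = c(cfg$hod, cfg$hod, cfg$ht),
                translation = c(0, 0, cfg$had + cfg$ht / 2),
                rotation = rot_g, role = "gantry_head", color = cfg$hcolor)

  structure(list(solids = list(cone = cone, gantry_head = head,
                               couch_head = couch_head,
                               couch_body = couch_body,
                               safety_zone = sz),
                 gantry_internal = g_int, couch_internal = c_int,
                 patient_offset = off, cfg = cfg),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> gantry %+g deg, couch %+g deg (internal); safety zone at (%.6g, %.6g, %.6g) mm\n",
              x$gantry_internal, x$couch_internal,
              x$patient_offset[["x"]], x$patient_offset[["y"]],
              x$patient_offset[["z"]]))
  for (s in x$solids) print(s)
  invisible(x)
}

machine_roles <- c("cone", "gantry_head")
patient_roles <- c("couch_head", "couch_body", "safety_zone")
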