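# Required commissioning keys: every measured length/angle/sign from the
# machine, couch, cone and localization-frame survey.
cfg_required_keys <- c(
  "szs", "szi", "sza", "szp", "szr", "szl",
  "cod", "cht", "chad", "cad", "chw", "chse", "chie", "cbie", "cbw",
  "hod", "ht", "had",
  "gia", "gicw", "cia", "cicw",
  "szlatcomm", "szapcomm", "szsicomm",
  "reflatcomm", "refapcomm", "refsicomm",
  "apdir", "latdir", "sidir"
)

cfg_optional_defaults <- function() {
  list(
    szcolor = c(1, 0, 0),            # safety zone: red
    chcolor = c(0.3, 0.3, 0.3),      # couch: dark gray
    ccolor  = c(0.75, 0.75, 0.75),   # cone: light gray
    hcolor  = c(0.72, 0.62, 0.08),   # gantry head: dark yellow
    label_ap = "Y", label_lat = "X", label_si = "Z",
    close_threshold_mm = 10
  )
}

#' Construct and validate a machine commissioning configuration
#'
#' The configuration captures every commissioning measurement needed to
#' build the room scene: safety-zone half-extents from its centre (`szs`,
#' `szi`, `sza`, `szp`, `szr`, `szl`), cone and gantry-head cylinder
#' dimensions (`cod`, `cad`, `hod`, `ht`, `had`), couch-head/body box
#' dimensions (`cht`, `chad`, `chw`, `chse`, `chie`, `cbie`, `cbw`),
#' angular conventions (`gia`, `gicw`, `cia`, `cicw`), the planning-system
#' coordinates of the safety-zone centre and reference point at
#' commissioning, and the planning-system shift sign flags (`apdir`,
#' `latdir`, `sidir`).  Lengths are in whatever unit the planning system
#' reports shifts in (mm throughout this package); angles are degrees.
#'
#' @param ... named commissioning values; see [load_config()] for the full
#'   key list and file format.
#' @return an object of class `machine_config`.
#' @export
machine_config <- function(...) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.list(vals[[1]])) {
    vals <- vals[[1]]
  }
  defaults <- cfg_optional_defaults()
  known <- c(cfg_required_keys, names(defaults))
  nm <- names(vals)
  if ("vertdir" %in% nm && !"sidir" %in% nm) {   # accepted alias
    vals$sidir <- vals$vertdir
    nm <- names(vals)
  }
  vals$vertdir <- NULL
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown config key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    vals[unknown] <- NULL
  }
  missing <- setdiff(cfg_required_keys, names(vals))
  if (length(missing)) {
    cc_config_error(sprintf("missing required config key(s): %s",
                            paste(missing, collapse = ", ")))
  }
  for (k in names(defaults)) vals[[k]] <- vals[[k]] %||% defaults[[k]]
  cfg <- structure(vals[c(cfg_required_keys, names(defaults))],
                   class = "machine_config")
  validate_machine_config(cfg)
  cfg
}

validate_machine_config <- function(cfg) {
  num1 <- function(k) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      cc_config_error(sprintf("config key '%s' must be a finite number (got %s)",
                              k, paste(format(v), collapse = ", ")))
    }
    v
  }
  positive <- c("szs", "szi", "sza", "szp", "szr", "szl", "cod", "cht",
                "chad", "cad", "chw", "cbw", "hod", "ht", "had",
                "close_threshold_mm")
  for (k in positive) {
    if (num1(k) <= 0) cc_config_error(sprintf("config key '%s' must be > 0 (got %g)", k, cfg[[k]]))
  }
  signed <- c("chse", "chie", "cbie", "gia", "cia",
              "szlatcomm", "szapcomm", "szsicomm",
              "reflatcomm", "refapcomm", "refsicomm")
  for (k in signed) num1(k)
  for (k in c("gicw", "cicw")) {
    if (!num1(k) %in% c(0, 1)) cc_config_error(sprintf("config key '%s' must be 0 or 1 (got %g)", k, cfg[[k]]))
  }
  for (k in c("apdir", "latdir", "sidir")) {
    if (!num1(k) %in% c(-1, 1)) cc_config_error(sprintf("config key '%s' must be -1 or +1 (got %g)", k, cfg[[k]]))
  }
  if (!(cfg$chie < cfg$chse)) cc_config_error("couch head needs chie < chse")
  if (!(cfg$cbie < cfg$chie)) cc_config_error("couch body needs cbie < chie")
  if (!(cfg$had > cfg$cad)) cc_config_error("head axis distance had must exceed cone axis distance cad")
  for (k in c("szcolor", "chcolor", "ccolor", "hcolor")) {
    v <- as.numeric(cfg[[k]])
    if (length(v) != 3L || any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      cc_config_error(sprintf("config key '%s' must be three rgb values in [0, 1]", k))
    }
  }
  for (k in c("label_ap", "label_lat", "label_si")) {
    if (!is.character(cfg[[k]]) || length(cfg[[k]]) != 1L) {
      cc_config_error(sprintf("config key '%s' must be a single string", k))
    }
  }
  invisible(cfg)
}

#' @export
print.machine_config <- function(x, ...) {
  cat("<machine_config>\n")
  cat(sprintf("  cone: diameter %g mm, axis span [%g, %g] mm from isocenter\n",
              x$cod, x$cad, x$had))
  cat(sprintf("  gantry head: diameter %g mm, thickness %g mm\n", x$hod, x$ht))
  cat(sprintf("  couch head %g x %g x %g mm; body width %g mm to y = %g mm\n",
              x$chw, x$chse - x$chie, x$cht, x$cbw, x$cbie))
  cat(sprintf("  safety zone extents S/I/A/P/R/L: %g/%g/%g/%g/%g/%g mm\n",
              x$szs, x$szi, x$sza, x$szp, x$szr, x$szl))
  cat(sprintf("  angles: GIA %g (CW=%g), CIA %g (CW=%g); close threshold %g mm\n",
              x$gia, x$gicw, x$cia, x$cicw, x$close_threshold_mm))
  invisible(x)
}

#' Load a machine configuration from YAML or JSON
#'
#' The file holds the lowercase commissioning keys listed in
#' [machine_config()] plus optional `szcolor` / `chcolor` / `ccolor` /
#' `hcolor` (3-element rgb lists), `label_ap` / `label_lat` / `label_si`
#' (planning-system axis labels, Brainlab-style defaults "Y"/"X"/"Z") and
#' `close_threshold_mm` (default 10).  `vertdir` is accepted as an alias
#' for `sidir`.  Unknown keys raise a warning, not an error.
#'
#' @param source path to a `.yaml`/`.yml`/`.json` file, or a single string
#'   of YAML/JSON text.
#' @return a validated [machine_config()].
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "machine_demo.yaml",
#'                                package = "conearc"))
#' cfg$had
load_config <- function(source) {
  if (!is.character(source) || length(source) != 1L) {
    cc_config_error("config source must be a file path or a text string")
  }
  if (file.exists(source)) {
    vals <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::read_json(source, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (grepl("[:{\\n]", source)) {
    vals <- tryCatch(jsonlite::parse_json(source, simplifyVector = TRUE),
                     error = function(e) yaml::yaml.load(source))
  } else {
    cc_io_error(sprintf("config file not found: %s", source))
  }
  if (!is.list(vals)) cc_config_error("config source did not parse to a key/value map")
  machine_config(vals)
}

#' Map a user-scale gantry angle to the internal rotation angle
#'
#' The internal angle is the signed rotation applied to the gantry-mounted
#' solids about y, with 0 at the commissioned pose (gantry directly
#' overhead).  `internal = s * (user - gia)` normalized to (-180, 180],
#' where `s = +1` if the machine's readout increases clockwise
#' (`gicw = 1`) and `-1` otherwise.
#'
#' @param user gantry angle on the machine readout scale (degrees).
#' @param cfg a [machine_config()].
#' @return internal rotation angle in degrees, in (-180, 180].
#' @export
internal_gantry_angle <- function(user, cfg) {
  stopifnot(inherits(cfg, "machine_config"))
  s <- if (cfg$gicw == 1) 1 else -1
  norm_angle(s * (user - cfg$gia))
}

#' Map a user-scale couch angle to the internal rotation angle
#'
#' Same rule as [internal_gantry_angle()] with `cia` / `cicw`; the result
#' rotates the couch-mounted solids about z.
#'
#' @inheritParams internal_gantry_angle
#' @return internal rotation angle in degrees, in (-180, 180].
#' @export
internal_couch_angle <- function(user, cfg) {
  stopifnot(inherits(cfg, "machine_config"))
  s <- if (cfg$cicw == 1) 1 else -1
  norm_angle(s * (user - cfg$cia))
}
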