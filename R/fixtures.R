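#' Shipped machine configurations
#'
#' Two commissioning variants are installed with the package:
#' \describe{
#'   \item{verbatim}{every surveyed value exactly as recorded, including
#'     two entries this package flags on load: the anterior safety-zone
#'     extent `sza`, whose survey sheet reads "155 cm" amid otherwise
#'     all-mm rows and is coerced to 155 mm with a warning, and a cone
#'     outer diameter of 750 mm, which exceeds the 670 mm gantry-head
#'     diameter and is physically implausible for a stereotactic cone.}
#'   \item{demo}{identical except `cod = 75` mm, a realistic cone housing
#'     diameter, for use in examples and demonstrations.  This override is
#'     a package choice, not a surveyed value.}
#' }
#'
#' @param variant `"demo"` or `"verbatim"`.
#' @return a validated [machine_config()].
#' @export
#' @examples
#' cfg <- default_machine_config("demo")
#' cfg$cod
default_machine_config <- function(variant = c("demo", "verbatim")) {
  variant <- match.arg(variant)
  file <- system.file("extdata",
                      sprintf("machine_%s.yaml",
                              if (variant == "demo") "demo" else "table1"),
                      package = "conearc")
  cfg <- load_config(file)
  if (variant == "verbatim") {
    warning(paste("verbatim config: 'sza' was surveyed as '155 cm' and is",
                  "used as 155 in the config units (mm); 'cod' = 750 mm",
                  "exceeds the gantry-head diameter"), call. = FALSE)
  }
  cfg
}

#' Shipped demonstration plans
#'
#' Three intracranial SRS cases with their couch/gantry arc geometries
#' transcribed verbatim (8, 5 and 7 arcs).  The isocenter and reference
#' point of each plan are SYNTHETIC demonstration values -- the published
#' cases do not include them -- chosen so the first demo plan shows both a
#' collision and a clear arc with the demo machine configuration.
#'
#' @param table `"t2"` (8 arcs), `"t3"` (5 arcs) or `"t4"` (7 arcs).
#' @return a `plan_file`, see [read_plan()].
#' @export
#' @examples
#' pf <- demo_plan("t3")
#' length(pf$arcs)
demo_plan <- function(table = c("t2", "t3", "t4")) {
  table <- match.arg(table)
  n <- c(t2 = "2", t3 = "3", t4 = "4")[[table]]
  read_plan(system.file("extdata", sprintf("plan_table%s.json", n),
                        package = "conearc"))
}

#' Seeded random solid pair
#'
#' Reproducible generator of solid pairs for stress-testing the clearance
#' engine: random primitive kinds, full extents in \[50, 700\] mm, centres
#' in +/-400 mm and a random single-axis rotation.  The ranges straddle
#' realistic treatment-room dimensions and yield a healthy mix of
#' intersecting and well-separated pairs.  The global RNG state is left
#' untouched.
#'
#' @param seed integer seed; identical seeds give identical pairs.
#' @return a list with solids `a` and `b`.
#' @export
#' @examples
#' pr <- random_solid_pair(7)
#' pr$a$kind
random_solid_pair <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  gen <- function(role) {
    kind <- sample(c("box", "cylinder", "ellipsoid"), 1L)
    sc <- stats::runif(3, 50, 700)
    tr <- stats::runif(3, -400, 400)
    axis <- sample(c("none", "y", "z"), 1L)
    ang <- stats::runif(1, 0, 360)
    rot <- switch(axis, none = rotation_none(),
                  y = rotation_about_y(ang), z = rotation_about_z(ang))
    solid(kind, sc, tr, rot, role = role)
  }
  list(a = gen("a"), b = gen("b"))
}
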