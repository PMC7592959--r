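#' Read a plan file
#'
#' A plan file (JSON, or YAML by extension) carries the plan context and
#' a non-empty list of named arcs:
#' \preformatted{
#' {
#'   "name": "...",
#'   "reference_point": {"lat": ..., "ap": ..., "si": ...},
#'   "isocenter":       {"lat": ..., "ap": ..., "si": ...},
#'   "sz_shape": "box",
#'   "arcs": [
#'     {"id": "1", "couch": 180, "gantry_start": 200,
#'      "gantry_stop": 350, "n_points": 19}, ...
#'   ]
#' }
#' }
#' `n_points` per arc is optional (default 36).
#'
#' @param path path to the plan file.
#' @return a list of class `plan_file` with fields `name`, `plan`
#'   (a [plan_context()]) and `arcs` (list of [arc_spec()]).
#' @export
read_plan <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    cc_io_error(sprintf("plan file not found: %s", path))
  }
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  plan_file_from_list(vals, name = vals$name %||% basename(path))
}

#' Build a plan file object from a parsed list
#'
#' Validates the structure documented in [read_plan()].
#'
#' @param vals named list with `reference_point`, `isocenter`, optional
#'   `sz_shape`, and `arcs`.
#' @param name plan name used in reports.
#' @return a `plan_file` object.
#' @export
plan_file_from_list <- function(vals, name = NULL) {
  if (!is.list(vals) || is.null(vals$reference_point) || is.null(vals$isocenter)) {
    cc_config_error("plan file must provide reference_point and isocenter")
  }
  plan <- plan_context(vals$reference_point, vals$isocenter,
                       vals$sz_shape %||% "box")
  arcs_in <- vals$arcs
  if (is.data.frame(arcs_in)) {
    arcs_in <- lapply(seq_len(nrow(arcs_in)), function(i) as.list(arcs_in[i, ]))
  }
  if (!is.list(arcs_in) || length(arcs_in) < 1L) {
    cc_config_error("plan file must list at least one arc")
  }
  arcs <- lapply(seq_along(arcs_in), function(i) {
    a <- arcs_in[[i]]
    for (k in c("couch", "gantry_start", "gantry_stop")) {
      if (is.null(a[[k]])) cc_config_error(sprintf("arc %d is missing '%s'", i, k))
    }
    arc_spec(a$couch, a$gantry_start, a$gantry_stop,
             n_points = a$n_points %||% 36L, id = a$id %||% as.character(i))
  })
  structure(list(name = name %||% "plan", plan = plan, arcs = arcs),
            class = "plan_file")
}

#' Write a plan file (JSON)
#'
#' Inverse of [read_plan()]; round-trips losslessly.
#'
#' @param pf a `plan_file` from [read_plan()] or [plan_file_from_list()].
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_plan <- function(pf, path) {
  stopifnot(inherits(pf, "plan_file"))
  out <- list(
    name = pf$name,
    reference_point = as.list(pf$plan$ref_plan),
    isocenter = as.list(pf$plan$iso_plan),
    sz_shape = pf$plan$sz_shape,
    arcs = lapply(pf$arcs, function(a) {
      list(id = a$id, couch = a$couch, gantry_start = a$gantry_start,
           gantry_stop = a$gantry_stop, n_points = a$n_points)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

report_header <- c("beam", "couch_angle", "gantry_start", "gantry_stop",
                   "min_clearance_mm", "argmin_gantry", "limiting_pair",
                   "classification")

#' Tabulate clearance results, one row per arc
#'
#' @param results list of `clearance_result` from [evaluate_plan()].
#' @return a data.frame with columns beam, couch_angle, gantry_start,
#'   gantry_stop, min_clearance_mm, argmin_gantry, limiting_pair,
#'   classification.
#' @export
report_table <- function(results) {
  stopifnot(is.list(results),
            all(vapply(results, inherits, logical(1), "clearance_result")))
  data.frame(
    beam = vapply(results, function(r) r$arc$id, character(1)),
    couch_angle = vapply(results, function(r) r$arc$couch, numeric(1)),
    gantry_start = vapply(results, function(r) r$arc$gantry_start, numeric(1)),
    gantry_stop = vapply(results, function(r) r$arc$gantry_stop, numeric(1)),
    min_clearance_mm = vapply(results, function(r) r$min_clearance, numeric(1)),
    argmin_gantry = vapply(results, function(r) r$argmin_gantry, numeric(1)),
    limiting_pair = vapply(results, function(r) r$limiting_pair, character(1)),
    classification = vapply(results, function(r) r$classification, character(1)),
    stringsAsFactors = FALSE
  )
}

format_report_csv <- function(tab) {
  num <- function(v) sprintf("%.3f", v)
  ang <- function(v) ifelse(v == round(v), sprintf("%d", as.integer(round(v))),
                            sprintf("%.3f", v))
  rows <- paste(tab$beam, ang(tab$couch_angle), ang(tab$gantry_start),
                ang(tab$gantry_stop), num(tab$min_clearance_mm),
                num(tab$argmin_gantry), tab$limiting_pair,
                tab$classification, sep = ",")
  c(paste(report_header, collapse = ","), rows)
}

batch_exit_status <- function(tab) {
  if (any(tab$classification == "collide")) return(3L)
  if (any(tab$classification == "close")) return(2L)
  0L
}

#' Batch clearance check of a plan
#'
#' Evaluates every arc of a plan against a machine configuration and
#' writes a CSV and a JSON report (one row per arc) plus, optionally, a
#' per-arc PNG overlay.  Runs are deterministic: repeated runs write
#' byte-identical reports.  The returned `exit_status` follows the
#' pipeline convention 0 = all clear, 2 = some close call, 3 = some
#' collision.
#'
#' @param config path to a machine config file, or a [machine_config()].
#' @param plan path to a plan file, or a `plan_file`.
#' @param out_dir output directory (created if needed).
#' @param n_points optional override of every arc's gantry sample count.
#' @param threshold_mm optional override of the close-call threshold.
#' @param sz_shape optional override of the safety-zone shape.
#' @param direction sweep direction, see [arc_angles()].
#' @param render write `arc_<id>.png` overlays.
#' @param precision a [clearance_precision()].
#' @param quiet suppress log messages.
#' @return (invisibly) a list with `results`, `table`, `exit_status` and
#'   the written `files`.
#' @export
run_batch <- function(config, plan, out_dir, n_points = NULL,
                      threshold_mm = NULL, sz_shape = NULL,
                      direction = "forward", render = FALSE,
                      precision = clearance_precision(), quiet = FALSE) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- load_config(config)
  }
  stopifnot(inherits(config, "machine_config"))
  plan_path <- NULL
  if (is.character(plan)) {
    plan_path <- plan
    plan <- read_plan(plan)
  }
  stopifnot(inherits(plan, "plan_file"))
  if (!is.null(threshold_mm)) config$close_threshold_mm <- threshold_mm
  ctx <- plan$plan
  if (!is.null(sz_shape)) {
    ctx <- plan_context(ctx$ref_plan, ctx$iso_plan, sz_shape)
  }
  arcs <- plan$arcs
  if (!is.null(n_points)) {
    arcs <- lapply(arcs, function(a) {
      arc_spec(a$couch, a$gantry_start, a$gantry_stop, n_points, a$id)
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!quiet) {
    message(sprintf("conearc batch: config=%s plan=%s (md5 %s)",
                    cfg_path %||% "<in-memory>", plan_path %||% "<in-memory>",
                    if (is.null(plan_path)) "-" else
                      unname(tools::md5sum(plan_path))))
    message(sprintf("  %d arc(s), threshold %g mm, shape %s, direction %s, n_points %s",
                    length(arcs), config$close_threshold_mm, ctx$sz_shape,
                    direction, if (is.null(n_points)) "per-arc" else n_points))
  }
  results <- evaluate_plan(config, ctx, arcs, precision = precision,
                           direction = direction)
  tab <- report_table(results)
  csv_path <- file.path(out_dir, "report.csv")
  writeLines(format_report_csv(tab), csv_path)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(plan = plan$name, threshold_mm = config$close_threshold_mm,
         sz_shape = ctx$sz_shape, direction = direction,
         arcs = tab),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  files <- c(csv_path, json_path)
  if (isTRUE(render)) {
    for (i in seq_along(arcs)) {
      f <- file.path(out_dir, sprintf("arc_%s.png", arcs[[i]]$id))
      render_arc(config, ctx, arcs[[i]], out = f, direction = direction)
      files <- c(files, f)
    }
  }
  status <- batch_exit_status(tab)
  if (!quiet) {
    message(sprintf("  wrote %s; status %d (%s)", csv_path, status,
                    paste(sprintf("%d %s", table(tab$classification),
                                  names(table(tab$classification))),
                          collapse = ", ")))
  }
  invisible(list(results = results, table = tab, exit_status = status,
                 files = files))
}

# ---- interactive session -------------------------------------------------

read_line_con <- function(con) {
  line <- tryCatch(readLines(con, n = 1L, warn = FALSE),
                   error = function(e) character(0))
  if (length(line) == 0L) NULL else trimws(line)
}

prompt_number <- function(label, con, out, default = NULL) {
  repeat {
    hint <- if (!is.null(default)) sprintf(" [%g]", default) else ""
    cat(sprintf("%s%s: ", label, hint), file = out)
    line <- read_line_con(con)
    if (is.null(line)) return(NULL)                    # EOF
    if (!nzchar(line) && !is.null(default)) return(default)
    val <- suppressWarnings(as.numeric(line))
    if (length(val) == 1L && is.finite(val)) return(val)
    cat("  please enter a number\n", file = out)
  }
}

prompt_choice <- function(label, choices, con, out, default = NULL) {
  repeat {
    hint <- if (!is.null(default)) sprintf(" [%s]", default) else ""
    cat(sprintf("%s (%s)%s: ", label, paste(choices, collapse = "/"), hint),
        file = out)
    line <- read_line_con(con)
    if (is.null(line)) return(NULL)
    if (!nzchar(line) && !is.null(default)) return(default)
    hit <- choices[match(tolower(line), tolower(choices))]
    if (!is.na(hit)) return(hit)
    cat(sprintf("  please answer one of: %s\n", paste(choices, collapse = ", ")),
        file = out)
  }
}

#' Interactive clearance session
#'
#' Mirrors the guided workflow of the original GUI: enter the
#' reference-point coordinates, then the isocenter together with the
#' safety-zone shape and the number of gantry angles to visualize, then
#' the beam geometry; the arc is then evaluated (and rendered), and a
#' configuration menu lets any one of the three groups be changed
#' individually before re-running.  Prompts use the planning-system axis
#' labels from the configuration.  Non-numeric input re-prompts; end of
#' input exits cleanly.
#'
#' @param config path to a machine config file, or a [machine_config()].
#' @param input,output connections (defaults: stdin/stdout); pass a
#'   [textConnection()] to script a session.
#' @param out_dir directory for rendered PNGs.
#' @param render write a PNG per evaluated arc.
#' @return (invisibly) a list with the final `state`, number of `runs`,
#'   evaluated `results` and rendered `files`.
#' @export
run_interactive <- function(config, input = stdin(), output = stdout(),
                            out_dir = tempdir(), render = TRUE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "machine_config"))
  st <- list(ref = NULL, iso = NULL, shape = "box", n_angles = 36,
             gantry_start = NULL, gantry_stop = NULL, couch = NULL)
  runs <- 0L; files <- character(0); results <- list()

  ask_ref <- function(st) {
    cat("-- Reference location (current plan) --\n", file = output)
    ap <- prompt_number(sprintf("  AP coordinate (%s)", config$label_ap),
                        input, output, st$ref[["ap"]])
    if (is.null(ap)) return(NULL)
    lat <- prompt_number(sprintf("  Lateral coordinate (%s)", config$label_lat),
                         input, output, st$ref[["lat"]])
    if (is.null(lat)) return(NULL)
    si <- prompt_number(sprintf("  Sup/inf coordinate (%s)", config$label_si),
                        input, output, st$ref[["si"]])
    if (is.null(si)) return(NULL)
    st$ref <- c(lat = lat, ap = ap, si = si)
    st
  }
  ask_iso <- function(st) {
    cat("-- Treatment isocenter --\n", file = output)
    ap <- prompt_number(sprintf("  AP coordinate (%s)", config$label_ap),
                        input, output, st$iso[["ap"]])
    if (is.null(ap)) return(NULL)
    lat <- prompt_number(sprintf("  Lateral coordinate (%s)", config$label_lat),
                         input, output, st$iso[["lat"]])
    if (is.null(lat)) return(NULL)
    si <- prompt_number(sprintf("  Sup/inf coordinate (%s)", config$label_si),
                        input, output, st$iso[["si"]])
    if (is.null(si)) return(NULL)
    shape <- prompt_choice("  Safety zone shape", c("box", "ellipsoid"),
                           input, output, st$shape)
    if (is.null(shape)) return(NULL)
    n <- prompt_number("  Number of gantry angles to visualize", input,
                       output, st$n_angles)
    if (is.null(n)) return(NULL)
    st$iso <- c(lat = lat, ap = ap, si = si)
    st$shape <- shape
    st$n_angles <- max(2, round(n))
    st
  }
  ask_beam <- function(st) {
    cat("-- Beam geometry --\n", file = output)
    gs <- prompt_number("  Initial gantry angle", input, output,
                        st$gantry_start)
    if (is.null(gs)) return(NULL)
    ge <- prompt_number("  Terminal gantry angle", input, output,
                        st$gantry_stop)
    if (is.null(ge)) return(NULL)
    cc <- prompt_number("  Couch angle", input, output, st$couch)
    if (is.null(cc)) return(NULL)
    st$gantry_start <- gs; st$gantry_stop <- ge; st$couch <- cc
    st
  }
  finish <- function() invisible(list(state = st, runs = runs,
                                      results = results, files = files))

  for (step in list(ask_ref, ask_iso, ask_beam)) {
    st2 <- step(st)
    if (is.null(st2)) return(finish())
    st <- st2
  }
  repeat {
    plan <- plan_context(st$ref, st$iso, st$shape)
    arc <- arc_spec(st$couch, st$gantry_start, st$gantry_stop,
                    n_points = st$n_angles, id = as.character(runs + 1L))
    res <- sweep_arc(config, plan, arc)
    runs <- runs + 1L
    results[[runs]] <- res
    cat(sprintf("Arc %d: %s  (min clearance %.1f mm, %s at gantry %.1f)\n",
                runs, toupper(res$classification), res$min_clearance,
                res$limiting_pair, res$argmin_gantry), file = output)
    if (isTRUE(render)) {
      f <- file.path(out_dir, sprintf("interactive_arc_%03d.png", runs))
      render_arc(config, plan, arc, out = f)
      files <- c(files, f)
      cat(sprintf("  view written to %s\n", f), file = output)
    }
    ans <- prompt_choice("Change [r]eference, [i]socenter, [b]eam geometry, or [q]uit",
                         c("r", "i", "b", "q"), input, output)
    if (is.null(ans) || ans == "q") return(finish())
    st2 <- switch(ans, r = ask_ref(st), i = ask_iso(st), b = ask_beam(st))
    if (is.null(st2)) return(finish())
    st <- st2
  }
}
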