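# Classed conditions so callers can distinguish user error from IO trouble.
cc_stop <- function(msg, class = "conearc_invalid_argument", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "conearc_error", "error", "condition")))
}

cc_config_error <- function(msg) cc_stop(msg, class = "conearc_config_error")
cc_io_error <- function(msg) cc_stop(msg, class = "conearc_io_error")

#' Normalize an angle to (-180, 180] degrees
#'
#' Used for all internal gantry/couch angles so an arc specification never
#' aliases across the 0/360 seam.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in the half-open interval (-180, 180].
#' @export
#' @examples
#' norm_angle(c(0, 180, -180, 360, 540))
norm_angle <- function(x) {
  if (!all(is.finite(x))) cc_stop("angles must be finite")
  x - 360 * ceiling((x - 180) / 360)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
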