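#' @keywords internal
"_PACKAGE"

# internal: abort with a classed condition so callers can test error types
qg_stop <- function(msg, class = "dendroQG_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# month-per-year completeness check used by several climate operations
check_complete_months <- function(x) {
  tab <- table(x$year)
  bad <- names(tab)[tab != 12L]
  if (length(bad)) {
    qg_stop(sprintf(
      "incomplete years (need 12 months each): %s",
      paste(bad, collapse = ", ")
    ), class = "dendroQG_incomplete_year")
  }
  invisible(TRUE)
}

#' Saturation vapour pressure (Tetens)
#'
#' Saturation vapour pressure over water at air temperature `t_c`, used to
#' derive vapour-pressure deficit and the evapotranspiration term of the
#' soil-moisture bucket model.
#'
#' @param t_c air temperature, degrees Celsius.
#' @return saturation vapour pressure in kPa.
#' @export
svp_kpa <- function(t_c) {
  0.6108 * exp(17.27 * t_c / (t_c + 237.3))
}
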