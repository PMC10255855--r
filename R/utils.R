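#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Stop with a classed condition
#'
#' All package errors carry a subclass so callers can trap them selectively.
#' @noRd
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "fieldtriage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

VITAL_SIGNS <- c("rr", "hr", "sbp", "spo2")

TRIAGE_COLORS <- c("green", "yellow", "red", "black", "blue")

BODY_POSITIONS <- c("upright", "supine", "prone", "lateral", "moving")
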