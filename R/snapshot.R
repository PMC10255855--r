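#' One windowed set of vital signs for one soldier
#'
#' A vital snapshot is the unit the triage engine consumes: the value of each
#' monitored sign over one analysis window, ending at `timestamp`. Any sign
#' may be absent (`NULL`/`NA`), which downstream triage interprets as the
#' corresponding sensor having dropped out. Mean physical activity and body
#' position are carried for context and logging; they do not enter the colour
#' decision.
#'
#' @param soldier_id Identifier shared with the soldier's [reference_profile()].
#' @param timestamp Milliseconds UTC, >= 0.
#' @param rr Respiratory rate, breaths/min, or `NA` if unavailable.
#' @param hr Heart rate, beats/min, or `NA`.
#' @param sbp Systolic blood pressure, mmHg, or `NA`.
#' @param spo2 Peripheral oxygen saturation, percent in (0, 100], or `NA`.
#' @param mpa Mean physical activity, g-units, or `NA`.
#' @param body_position One of `"upright"`, `"supine"`, `"prone"`,
#'   `"lateral"`, `"moving"`, or `NA`.
#' @return An object of class `vital_snapshot`.
#' @export
vital_snapshot <- function(soldier_id, timestamp, rr = NA, hr = NA, sbp = NA,
                           spo2 = NA, mpa = NA, body_position = NA) {
  if (!is_scalar_number(timestamp) || timestamp < 0) {
    abort("timestamp must be a finite number >= 0 (ms UTC)",
          "fieldtriage_input_error")
  }
  check_sign <- function(x, name, hi = Inf) {
    if (is.null(x) || (length(x) == 1L && is.na(x))) return(NA_real_)
    if (!is_scalar_number(x) || x <= 0 || x > hi) {
      abort(sprintf("%s must be finite, > 0%s, or NA", name,
                    if (is.finite(hi)) sprintf(" and <= %g", hi) else ""),
            "fieldtriage_input_error")
    }
    as.numeric(x)
  }
  bp <- if (is.null(body_position) || is.na(body_position[1])) {
    NA_character_
  } else {
    match.arg(body_position, BODY_POSITIONS)
  }
  structure(list(
    soldier_id = soldier_id,
    timestamp = as.numeric(timestamp),
    rr = check_sign(rr, "rr"),
    hr = check_sign(hr, "hr"),
    sbp = check_sign(sbp, "sbp"),
    spo2 = check_sign(spo2, "spo2", hi = 100),
    mpa = if (is.null(mpa) || is.na(mpa[1])) NA_real_ else as.numeric(mpa),
    body_position = bp
  ), class = "vital_snapshot")
}

#' @export
print.vital_snapshot <- function(x, ...) {
  fmt <- function(v, unit) if (is.na(v)) "--" else sprintf("%.4g %s", v, unit)
  cat(sprintf("<vital_snapshot> %s @ %.0f ms\n", x$soldier_id, x$timestamp))
  cat(sprintf("  RR %s | HR %s | SBP %s | SpO2 %s | MPA %s | pos %s\n",
              fmt(x$rr, "/min"), fmt(x$hr, "bpm"), fmt(x$sbp, "mmHg"),
              fmt(x$spo2, "%"), fmt(x$mpa, "g"),
              if (is.na(x$body_position)) "--" else x$body_position))
  invisible(x)
}

#' Which of the four triage signs are present in a snapshot
#' @param snapshot A [vital_snapshot()].
#' @return Character vector, subset of `c("rr","hr","sbp","spo2")`.
#' @export
available_signs <- function(snapshot) {
  VITAL_SIGNS[vapply(VITAL_SIGNS, function(s) !is.na(snapshot[[s]]), logical(1))]
}
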