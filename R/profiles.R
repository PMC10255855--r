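#' Per-soldier reference profile
#'
#' A reference profile holds, for each of the four triage-relevant vital signs
#' (respiratory rate, heart rate, systolic blood pressure, oxygen saturation),
#' the personalised reference interval \[ref_lo, ref_hi\] inside which the sign
#' is considered normal, and the critical thresholds beyond which the sign
#' indicates an immediate threat to life. RR, HR and SBP carry two-sided
#' critical thresholds; SpO2 is one-sided (only a critical low; its reference
#' ceiling is 100).
#'
#' @param soldier_id Identifier of the soldier this profile belongs to.
#' @param rr,hr,sbp,spo2 Named numeric vectors with elements `ref_lo`,
#'   `ref_hi`, `crit_lo` and (except `spo2`) `crit_hi`. Any omitted sign falls
#'   back to the typical ranges of [default_reference_profile()].
#' @return An object of class `reference_profile`: a list with one element per
#'   sign, each a list with fields `ref_lo`, `ref_hi`, `crit_lo`, `crit_hi`
#'   (`crit_hi` is `NA` for spo2).
#' @examples
#' prof <- default_reference_profile("alpha-1")
#' severity_of(15, "rr", prof)   # in_reference
#' severity_of(25, "rr", prof)   # out_of_reference
#' severity_of(35, "rr", prof)   # critical
#' @export
reference_profile <- function(soldier_id, rr = NULL, hr = NULL, sbp = NULL,
                              spo2 = NULL) {
  defaults <- list(
    rr   = list(ref_lo = 9,   ref_hi = 20,  crit_lo = 5,  crit_hi = 30),
    hr   = list(ref_lo = 50,  ref_hi = 110, crit_lo = 40, crit_hi = 140),
    sbp  = list(ref_lo = 100, ref_hi = 180, crit_lo = 80, crit_hi = 220),
    spo2 = list(ref_lo = 94,  ref_hi = 100, crit_lo = 85, crit_hi = NA_real_)
  )
  given <- list(rr = rr, hr = hr, sbp = sbp, spo2 = spo2)
  out <- defaults
  for (sign in VITAL_SIGNS) {
    g <- given[[sign]]
    if (is.null(g)) next
    g <- as.list(g)
    for (f in names(g)) {
      if (!f %in% c("ref_lo", "ref_hi", "crit_lo", "crit_hi")) {
        abort(sprintf("unknown threshold field '%s' for sign '%s'", f, sign),
              "fieldtriage_config_error")
      }
      out[[sign]][[f]] <- as.numeric(g[[f]])
    }
  }
  for (sign in VITAL_SIGNS) {
    s <- out[[sign]]
    if (!(s$crit_lo < s$ref_lo && s$ref_lo <= s$ref_hi)) {
      abort(sprintf("profile for '%s' violates crit_lo < ref_lo <= ref_hi", sign),
            "fieldtriage_config_error")
    }
    if (!is.na(s$crit_hi) && !(s$ref_hi < s$crit_hi)) {
      abort(sprintf("profile for '%s' violates ref_hi < crit_hi", sign),
            "fieldtriage_config_error")
    }
  }
  structure(c(list(soldier_id = soldier_id), out),
            class = "reference_profile")
}

#' @rdname reference_profile
#' @export
default_reference_profile <- function(soldier_id = "unknown") {
  reference_profile(soldier_id)
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("<reference_profile>", x$soldier_id, "\n")
  for (sign in VITAL_SIGNS) {
    s <- x[[sign]]
    cat(sprintf("  %-4s ref [%g, %g]  crit lo %g%s\n", sign,
                s$ref_lo, s$ref_hi, s$crit_lo,
                if (is.na(s$crit_hi)) "" else sprintf(", hi %g", s$crit_hi)))
  }
  invisible(x)
}

SEVERITY_LEVELS <- c("in_reference", "out_of_reference", "critical")

#' Severity of a single vital-sign measurement
#'
#' Classifies one measurement against a soldier's profile:
#' `in_reference` if the value lies inside the reference interval,
#' `critical` if it reaches a critical threshold (value <= crit_lo, or
#' value >= crit_hi where a high threshold exists), and `out_of_reference`
#' for anything in between. The three levels are totally ordered
#' in_reference < out_of_reference < critical; [triage()] maps them to
#' green/yellow/red.
#'
#' @param value Finite positive measurement.
#' @param sign One of `"rr"`, `"hr"`, `"sbp"`, `"spo2"`.
#' @param profile A [reference_profile()].
#' @return An ordered factor of length `length(value)` with levels
#'   `in_reference < out_of_reference < critical`.
#' @export
severity_of <- function(value, sign, profile) {
  sign <- tolower(sign)
  if (!sign %in% VITAL_SIGNS || is.null(profile[[sign]])) {
    abort(sprintf("unknown vital sign '%s'", sign), "fieldtriage_config_error")
  }
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
    abort("measurement values must be finite and > 0", "fieldtriage_input_error")
  }
  s <- profile[[sign]]
  sev <- severity_code(value, s$ref_lo, s$ref_hi, s$crit_lo, s$crit_hi)
  factor(SEVERITY_LEVELS[sev], levels = SEVERITY_LEVELS, ordered = TRUE)
}

# vectorised severity as integer code 1/2/3; crit_hi may be NA (one-sided)
severity_code <- function(value, ref_lo, ref_hi, crit_lo, crit_hi) {
  crit <- value <= crit_lo
  if (!is.na(crit_hi)) crit <- crit | value >= crit_hi
  inref <- value >= ref_lo & value <= ref_hi
  ifelse(crit, 3L, ifelse(inref, 1L, 2L))
}
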