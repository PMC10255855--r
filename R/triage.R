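#' Triage decision object
#'
#' Result of one run of the triage cascade (or of a manual override). The
#' colour follows START semantics: green (no assistance needed), yellow
#' (second evacuation priority), red (immediate), black (no heart-rate
#' signal; needs on-scene confirmation), blue (manually tagged, minimal
#' survival chance, evacuated last). `reliability` reflects which sensors
#' contributed (see [reliability_of()]); `survival_chance` is attached only
#' at full reliability.
#'
#' @param soldier_id,timestamp Identity and time (ms UTC) of the decision.
#' @param color One of `"green"`, `"yellow"`, `"red"`, `"black"`, `"blue"`.
#' @param reliability Percent in \{50, 60, 70, 80, 90, 100\}, or `NA`.
#' @param survival_chance Integer percent in \[1, 100\], or `NA`.
#' @param source `"automatic"` or `"manual"`.
#' @param needs_confirmation Logical; always `TRUE` for black tags.
#' @param history List of superseded decisions (most recent last).
#' @return An object of class `triage_decision`.
#' @export
triage_decision <- function(soldier_id, timestamp, color,
                            reliability = NA, survival_chance = NA,
                            source = c("automatic", "manual"),
                            needs_confirmation = FALSE, history = list()) {
  source <- match.arg(source)
  color <- match.arg(color, TRIAGE_COLORS)
  if (color == "blue" && source != "manual") {
    abort("blue tags can only be assigned manually", "fieldtriage_invariant_error")
  }
  if (color == "black") needs_confirmation <- TRUE
  if (!is.na(reliability) &&
      !reliability %in% c(50, 60, 70, 80, 90, 100)) {
    abort("reliability must be one of 50/60/70/80/90/100 or NA",
          "fieldtriage_invariant_error")
  }
  if (!is.na(survival_chance)) {
    if (is.na(reliability) || reliability != 100 ||
        !color %in% c("green", "yellow", "red")) {
      abort("survival_chance requires reliability 100 and a green/yellow/red tag",
            "fieldtriage_invariant_error")
    }
    if (survival_chance < 1 || survival_chance > 100) {
      abort("survival_chance must lie in [1, 100]", "fieldtriage_invariant_error")
    }
  }
  structure(list(
    soldier_id = soldier_id, timestamp = as.numeric(timestamp), color = color,
    reliability = as.numeric(reliability),
    survival_chance = as.numeric(survival_chance),
    source = source, needs_confirmation = isTRUE(needs_confirmation),
    history = history
  ), class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("<triage_decision> %s @ %.0f ms: %s (%s)%s%s%s\n",
              x$soldier_id, x$timestamp, toupper(x$color), x$source,
              if (is.na(x$reliability)) "" else
                sprintf(", reliability %g%%", x$reliability),
              if (is.na(x$survival_chance)) "" else
                sprintf(", survival %g%%", x$survival_chance),
              if (x$needs_confirmation) " [needs confirmation]" else ""))
  invisible(x)
}

# reliability lookup keyed by sorted sign subset (HR always present)
RELIABILITY_TABLE <- c(
  "rr,hr,sbp,spo2" = 100,  # all four sensors
  "rr,hr,sbp"      = 90,   # SpO2 lost
  "rr,hr,spo2"     = 80,   # SBP lost
  "rr,hr"          = 70,   # SpO2 + SBP lost
  "hr,sbp,spo2"    = 80,   # RR lost
  "hr,sbp"         = 70,   # RR + SpO2 lost
  "hr,spo2"        = 60,   # RR + SBP lost
  "hr"             = 50    # HR only
)

#' Degraded-mode reliability score
#'
#' Battlefield sensors drop out; the triage engine still runs on whatever
#' signs arrive, but annotates the decision with a confidence percentage
#' fixed by which sensors delivered data. Heart rate is indispensable:
#' without it the system cannot operate and signals a black tag instead.
#'
#' @param available Character vector of available sign ids, a subset of
#'   `c("rr", "hr", "sbp", "spo2")` (case-insensitive).
#' @return The reliability percentage (one of 50, 60, 70, 80, 90, 100), or
#'   `NA` — the black signal — when `"hr"` is not available.
#' @examples
#' reliability_of(c("rr", "hr", "sbp", "spo2"))  # 100
#' reliability_of(c("hr", "rr", "sbp"))          # 90 (SpO2 sensor lost)
#' reliability_of("hr")                          # 50
#' reliability_of(c("rr", "sbp", "spo2"))        # NA: no HR -> black signal
#' @export
reliability_of <- function(available) {
  available <- unique(tolower(available))
  bad <- setdiff(available, VITAL_SIGNS)
  if (length(bad)) {
    abort(sprintf("unknown vital sign(s): %s", paste(bad, collapse = ", ")),
          "fieldtriage_config_error")
  }
  if (!"hr" %in% available) return(NA_real_)
  key <- paste(VITAL_SIGNS[VITAL_SIGNS %in% available], collapse = ",")
  unname(RELIABILITY_TABLE[[key]])
}

# The cascade, vectorised over rows of a data.frame with columns rr, hr,
# sbp, spo2 (all present). Signs are examined in fixed priority order
# RR, HR, SBP, SpO2; each stage may only upgrade the running colour
# (green -> yellow -> red), never downgrade it.
cascade_codes <- function(values, profile, signs = VITAL_SIGNS) {
  state <- rep(1L, length(values[[signs[1]]]))  # 1 green, 2 yellow, 3 red
  for (sign in signs) {
    s <- profile[[sign]]
    sev <- severity_code(values[[sign]], s$ref_lo, s$ref_hi, s$crit_lo, s$crit_hi)
    state <- pmax(state, sev)   # upgrade-only
  }
  state
}

#' Label a grid of cases with triage colours
#'
#' Runs the same cascade as [triage()] over every row of a data frame of
#' full four-sign cases (used to label the survival-model training grid and
#' for exhaustive verification against a brute-force oracle).
#'
#' @param cases Data frame with numeric columns `rr`, `hr`, `sbp`, `spo2`.
#' @param profile A [reference_profile()].
#' @return Character vector of `"green"`/`"yellow"`/`"red"`, one per row.
#' @export
triage_colors <- function(cases, profile) {
  missing_cols <- setdiff(VITAL_SIGNS, names(cases))
  if (length(missing_cols)) {
    abort(sprintf("cases must have columns %s", paste(VITAL_SIGNS, collapse = ", ")),
          "fieldtriage_input_error")
  }
  c("green", "yellow", "red")[cascade_codes(cases, profile)]
}

#' Run the triage cascade on one snapshot
#'
#' Applies the rule cascade: each available sign, in priority order RR, HR,
#' SBP, SpO2, is compared against the soldier's reference interval (-> green),
#' the band between reference and critical (-> yellow) or the critical region
#' (-> red); a later sign can upgrade but never downgrade the colour. If the
#' heart-rate signal is missing the soldier is tagged black (communication
#' loss or death — confirmation required) and no reliability is attached.
#' Missing non-HR signs merely skip their stage and lower the decision's
#' reliability per the degraded-mode table. The chance-of-survival percentage
#' is attached only at reliability 100: exactly 100 for green, and the
#' calibrated model value for yellow/red when `model` is supplied.
#'
#' @param snapshot A [vital_snapshot()].
#' @param profile The soldier's [reference_profile()].
#' @param model Optional [survival_model] used to score yellow/red cases.
#' @return A [triage_decision()].
#' @examples
#' prof <- default_reference_profile("a1")
#' triage(vital_snapshot("a1", 0, rr = 14, hr = 72, sbp = 120, spo2 = 97), prof)
#' triage(vital_snapshot("a1", 0, rr = 14, sbp = 120, spo2 = 97), prof)  # black
#' @export
triage <- function(snapshot, profile, model = NULL) {
  stopifnot(inherits(snapshot, "vital_snapshot"),
            inherits(profile, "reference_profile"))
  if (!identical(snapshot$soldier_id, profile$soldier_id)) {
    abort("snapshot and profile belong to different soldiers",
          "fieldtriage_input_error")
  }
  avail <- available_signs(snapshot)
  if (!"hr" %in% avail) {
    return(triage_decision(snapshot$soldier_id, snapshot$timestamp, "black",
                           needs_confirmation = TRUE))
  }
  vals <- lapply(snapshot[avail], identity)
  code <- cascade_codes(vals, profile, signs = avail)
  color <- c("green", "yellow", "red")[code]
  rel <- reliability_of(avail)
  chance <- NA_real_
  if (!is.na(rel) && rel == 100) {
    if (color == "green") {
      chance <- 100
    } else if (!is.null(model)) {
      # the cascade colour is authoritative; near class boundaries the
      # model may disagree, so its score is clamped into the colour's band
      band <- model$bands[[color]]
      chance <- clamp(survival_chance(model, snapshot), band[1], band[2])
    }
  }
  triage_decision(snapshot$soldier_id, snapshot$timestamp, color,
                  reliability = rel, survival_chance = chance)
}

#' Manual override of a triage decision
#'
#' Medical personnel or rescuers from the evacuation group may re-tag a
#' casualty after on-scene verification; this is the only path by which the
#' blue tag (minimal survival chance, evacuated last) can be assigned. The
#' superseded decision is preserved in the new decision's history.
#'
#' @param decision The current [triage_decision()].
#' @param new_color `"green"`, `"yellow"`, `"red"` or `"blue"`.
#' @param actor Role of the person overriding; must be `"medic"` or
#'   `"rescuer"`.
#' @return A new manual [triage_decision()] with the old one appended to
#'   `history`.
#' @export
apply_override <- function(decision, new_color, actor) {
  stopifnot(inherits(decision, "triage_decision"))
  if (!actor %in% c("medic", "rescuer")) {
    abort(sprintf("actor '%s' is not authorised to override triage", actor),
          "fieldtriage_permission_error")
  }
  new_color <- match.arg(new_color, c("green", "yellow", "red", "blue"))
  triage_decision(
    decision$soldier_id, decision$timestamp, new_color,
    reliability = decision$reliability,
    survival_chance = if (new_color == decision$color) decision$survival_chance
                      else NA,
    source = "manual",
    history = c(decision$history, list(strip_history(decision)))
  )
}

strip_history <- function(d) { d$history <- list(); d }

#' Evacuation priority ordering
#'
#' Orders casualties for evacuation. In `standard` mode the most urgent go
#' first: red before yellow before green, and within a colour ascending
#' chance of survival (the "more red" of the reds first). In `reverse`
#' (tactical) mode the lightest wounded are recovered first to restore
#' combat capability: descending chance of survival. Blue-tagged casualties
#' are evacuated last in both modes; black tags are not queued — they are
#' returned separately for on-scene confirmation. Ties break on earlier
#' decision timestamp.
#'
#' @param casualties List of [triage_decision()] objects.
#' @param mode `"standard"` or `"reverse"`.
#' @return The ordered list of non-black decisions, with black decisions in
#'   attribute `"unconfirmed"`.
#' @export
evacuation_order <- function(casualties, mode = c("standard", "reverse")) {
  mode <- match.arg(mode)
  if (length(casualties) == 0) {
    return(structure(list(), unconfirmed = list()))
  }
  colors <- vapply(casualties, `[[`, character(1), "color")
  black <- casualties[colors == "black"]
  rest <- casualties[colors != "black"]
  if (length(rest) == 0) {
    return(structure(list(), unconfirmed = black))
  }
  colors <- vapply(rest, `[[`, character(1), "color")
  chance <- vapply(rest, `[[`, numeric(1), "survival_chance")
  ts <- vapply(rest, `[[`, numeric(1), "timestamp")
  if (mode == "standard") {
    # urgency rank: red 1, yellow 2, green 3; blue always sinks to the end
    rank <- c(red = 1, yellow = 2, green = 3, blue = 4)[colors]
    key2 <- ifelse(is.na(chance), Inf, chance)        # unknown chance last in colour
    ord <- order(rank, key2, ts)
  } else {
    rank <- ifelse(colors == "blue", 2, 1)
    key2 <- ifelse(is.na(chance), Inf, -chance)       # lightest (highest chance) first
    ord <- order(rank, key2, ts)
  }
  structure(rest[ord], unconfirmed = black)
}
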