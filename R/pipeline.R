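iso8601 <- function(ms) {
  format(as.POSIXct(ms / 1000, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS3Z")
}

decision_event <- function(d) {
  list(soldier_id = d$soldier_id, time = iso8601(d$timestamp),
       timestamp_ms = d$timestamp, color = d$color,
       reliability = d$reliability, survival_chance = d$survival_chance,
       source = d$source, needs_confirmation = d$needs_confirmation)
}

#' Pipeline configuration
#'
#' Validated bundle of everything one end-to-end run needs: the soldiers
#' (with optional per-soldier profile threshold overrides), their scenario
#' timelines, window/reporting settings, survival-model hyperparameters and
#' the master seed. Can be built in code or loaded from YAML with
#' [read_pipeline_config()].
#'
#' @param soldiers List of `list(id =, profile = (optional overrides),
#'   demographics = (optional))`.
#' @param scenarios Named list (by soldier id) of segment lists; each
#'   segment is a [scenario_segment()] or a plain list of its arguments.
#' @param seed Master seed; per-soldier noise seeds are derived from it.
#' @param period_s Reporting period (s). @param window_s Analysis window (s).
#' @param snr_db Generator noise level.
#' @param survival List with `train` (logical), `seed`, `cost`, `gamma`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(soldiers, scenarios, seed, period_s = 10,
                            window_s = 10, snr_db = 20,
                            survival = list(train = TRUE, seed = 42,
                                            cost = 100, gamma = 1)) {
  if (!length(soldiers)) {
    abort("config field 'soldiers' must be a non-empty list",
          "fieldtriage_validation_error")
  }
  ids <- vapply(soldiers, function(s) {
    if (is.null(s$id)) {
      abort("config field 'soldiers': every entry needs an 'id'",
            "fieldtriage_validation_error")
    }
    as.character(s$id)
  }, character(1))
  if (anyDuplicated(ids)) {
    abort("config field 'soldiers' contains duplicate ids",
          "fieldtriage_validation_error")
  }
  unknown <- setdiff(names(scenarios), ids)
  if (length(unknown)) {
    abort(sprintf("config field 'scenarios' references unknown soldier id(s): %s",
                  paste(unknown, collapse = ", ")),
          "fieldtriage_validation_error")
  }
  if (missing(seed) || !is_scalar_number(seed)) {
    abort("config field 'seed' must be an explicit integer",
          "fieldtriage_validation_error")
  }
  survival <- utils::modifyList(list(train = TRUE, seed = 42, cost = 100,
                                     gamma = 1), survival)
  structure(list(soldiers = soldiers, scenarios = scenarios,
                 seed = as.integer(seed), period_s = period_s,
                 window_s = window_s, snr_db = snr_db, survival = survival),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; top-level keys mirror the [pipeline_config()]
#'   arguments, with scenario segments as plain mappings.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    list(soldiers = y$soldiers, scenarios = y$scenarios, seed = y$seed),
    y[intersect(names(y), c("period_s", "window_s", "snr_db", "survival"))]
  ))
}

as_segment <- function(seg) {
  if (inherits(seg, "scenario_segment")) seg else do.call(scenario_segment, seg)
}

#' Run the full decision pipeline
#'
#' For every soldier: synthesise the scenario biosignals, extract windowed
#' vital snapshots, run the triage cascade (with the chance-of-survival
#' model attached at full reliability), log a decision event whenever the
#' colour changes, and fill the electronic casualty card. Everything is
#' seeded, so a rerun of the same config reproduces every artifact
#' byte-for-byte.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @param out_dir Optional directory; decision events are written to
#'   `decisions.jsonl`, cards to `tccc_<id>.json` and the board to
#'   `board.csv`.
#' @param mode Evacuation ordering mode for the board.
#' @return List with `streams`, `snapshots`, `decisions` (colour-change
#'   events only), `latest` (last decision per soldier), `cards`, `board`
#'   and the trained `model` (or `NULL`).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         mode = c("standard", "reverse")) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  model <- NULL
  if (isTRUE(config$survival$train)) {
    model <- train_survival_model(generate_case_grid(),
                                  seed = config$survival$seed,
                                  cost = config$survival$cost,
                                  gamma = config$survival$gamma)
  }
  streams <- list(); snapshots <- list(); cards <- list()
  events <- list(); latest <- list()
  for (k in seq_along(config$soldiers)) {
    sol <- config$soldiers[[k]]
    id <- as.character(sol$id)
    prof <- do.call(reference_profile, c(list(soldier_id = id),
                                         sol$profile %||% list()))
    segs <- lapply(config$scenarios[[id]] %||%
                     list(list(duration_s = 120, state = "baseline")),
                   as_segment)
    spec <- scenario_spec(id, seed = config$seed + 1000L * k, segments = segs,
                          snr_db = config$snr_db)
    stream <- generate_scenario(spec)
    snaps <- stream_to_snapshots(stream, period_s = config$period_s,
                                 window_s = config$window_s)
    card <- tccc_card(id, sex = sol$demographics$sex %||% NA_character_,
                      birth_date = sol$demographics$birth_date %||% NA_character_,
                      weight_kg = sol$demographics$weight_kg %||% NA_real_)
    prev_color <- NULL
    for (s in snaps) {
      card <- update_tccc(card, s)
      d <- triage(s, prof, model = model)
      # decision events go downstream only when the colour changes
      if (is.null(prev_color) || d$color != prev_color) {
        card <- update_tccc(card, d)
        events <- c(events, list(d))
        prev_color <- d$color
      }
      latest[[id]] <- d
    }
    streams[[id]] <- stream
    snapshots[[id]] <- snaps
    cards[[id]] <- card
  }
  board <- render_board(latest, mode = mode)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(vapply(events, function(d) {
      as.character(jsonlite::toJSON(decision_event(d), auto_unbox = TRUE,
                                    digits = NA, na = "null"))
    }, character(1)), file.path(out_dir, "decisions.jsonl"))
    for (id in names(cards)) {
      export_tccc(cards[[id]], file.path(out_dir, paste0("tccc_", id, ".json")))
    }
    utils::write.csv(board, file.path(out_dir, "board.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(streams = streams, snapshots = snapshots, decisions = events,
       latest = latest, cards = cards, board = board, model = model)
}

#' Medical-board table
#'
#' The tabular situational picture the evacuation group works from: one row
#' per soldier with the latest triage colour, chance of survival,
#' decision reliability and last-update time, ordered by evacuation
#' priority ([evacuation_order()]); black (silent) soldiers are listed at
#' the bottom, flagged for confirmation.
#'
#' @param decisions Named list (or list) of latest [triage_decision()]s.
#' @param mode `"standard"` (most urgent first) or `"reverse"` (lightest
#'   first).
#' @return Data frame with columns id, color, survival_chance, reliability,
#'   last_update, needs_confirmation.
#' @export
render_board <- function(decisions, mode = c("standard", "reverse")) {
  mode <- match.arg(mode)
  decisions <- unname(decisions)
  empty <- data.frame(id = character(0), color = character(0),
                      survival_chance = numeric(0), reliability = numeric(0),
                      last_update = character(0),
                      needs_confirmation = logical(0))
  if (!length(decisions)) return(empty)
  ordered <- evacuation_order(decisions, mode = mode)
  rows <- c(ordered, attr(ordered, "unconfirmed"))
  if (!length(rows)) return(empty)
  data.frame(
    id = vapply(rows, `[[`, character(1), "soldier_id"),
    color = vapply(rows, `[[`, character(1), "color"),
    survival_chance = vapply(rows, `[[`, numeric(1), "survival_chance"),
    reliability = vapply(rows, `[[`, numeric(1), "reliability"),
    last_update = vapply(rows, function(d) iso8601(d$timestamp), character(1)),
    needs_confirmation = vapply(rows, `[[`, logical(1), "needs_confirmation")
  )
}
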