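#' Four-dimensional training case grid
#'
#' The chance-of-survival function is trained on a grid of synthetic cases
#' covering the four-dimensional vital-sign space (RR x HR x SBP x SpO2),
#' each axis spanning from below the critical threshold to inside the
#' reference interval. The default axis resolutions 10 x 12 x 12 x 5 yield
#' 7200 cases (SpO2 gets the fewest levels since its thresholds are
#' one-sided).
#'
#' @param rr,hr,sbp,spo2 Strictly increasing numeric axis value vectors
#'   (>= 2 values each). The default levels span below-critical through
#'   in-reference values for the typical profile and are placed so that the
#'   midpoint of each adjacent pair that crosses a clinical threshold falls
#'   exactly on that threshold — a max-margin classifier trained on the grid
#'   then puts its decision surface where the cascade puts the colour change.
#' @param grid_id Label carried in exports.
#' @return An object of class `case_grid`: list with `cases` (data frame of
#'   all combinations, columns rr/hr/sbp/spo2), the axes, and `grid_id`.
#' @examples
#' g <- generate_case_grid()
#' nrow(g$cases)  # 7200
#' @export
generate_case_grid <- function(
    rr   = c(2.5, 7.5, 10.5, 12.5, 15, 16.5, 18, 22, 27, 33),
    hr   = c(32.5, 47.5, 52.5, 65, 80, 90, 95, 107.5, 112.5, 120, 127.5,
             152.5),
    sbp  = c(65, 95, 105, 115, 125, 135, 155, 165, 175, 185, 200, 240),
    spo2 = c(75, 80, 90, 98, 99.5),
    grid_id = "default") {
  axes <- list(rr = rr, hr = hr, sbp = sbp, spo2 = spo2)
  for (nm in names(axes)) {
    ax <- axes[[nm]]
    if (length(ax) < 2) {
      abort(sprintf("axis '%s' needs at least 2 values", nm),
            "fieldtriage_validation_error")
    }
    if (anyDuplicated(ax)) {
      abort(sprintf("axis '%s' contains duplicate values", nm),
            "fieldtriage_validation_error")
    }
    if (is.unsorted(ax, strictly = TRUE)) {
      abort(sprintf("axis '%s' must be strictly increasing", nm),
            "fieldtriage_validation_error")
    }
  }
  cases <- expand.grid(spo2 = spo2, sbp = sbp, hr = hr, rr = rr,
                       KEEP.OUT.ATTRS = FALSE)[, c("rr", "hr", "sbp", "spo2")]
  structure(list(cases = cases, axes = axes, grid_id = grid_id),
            class = "case_grid")
}

#' @export
print.case_grid <- function(x, ...) {
  cat(sprintf("<case_grid> '%s': %d cases (%s)\n", x$grid_id, nrow(x$cases),
              paste(vapply(x$axes, length, integer(1)), collapse = " x ")))
  invisible(x)
}

#' Train the two-stage chance-of-survival classifier
#'
#' Fits the ordinal survival function as a composition of two nonlinear
#' large-margin (RBF-kernel support-vector) classifiers: stage A separates
#' red from \{yellow, green\}, stage B separates yellow from green among the
#' not-red. Their signed margin distances are later squashed through a
#' logistic map into the colour's survival band (red 1-50, yellow 51-99,
#' green exactly 100); see [survival_chance()].
#'
#' @param grid A [generate_case_grid()] result.
#' @param labels Character vector of `"green"`/`"yellow"`/`"red"`, one per
#'   grid case, as produced by [triage_colors()] under the same profile.
#'   If `NULL`, labels are computed from `profile`.
#' @param seed Integer seed controlling the fit (mandatory).
#' @param profile Profile used to label the grid when `labels` is `NULL`.
#' @param cost,gamma RBF hyperparameters passed to both machines. The
#'   defaults are chosen so the deterministic grid labels are interpolated
#'   essentially exactly.
#' @return An object of class `survival_model`.
#' @export
train_survival_model <- function(grid, labels = NULL, seed,
                                 profile = default_reference_profile(),
                                 cost = 100, gamma = 1) {
  stopifnot(inherits(grid, "case_grid"))
  if (missing(seed)) abort("a training seed is mandatory", "fieldtriage_config_error")
  cases <- grid$cases
  if (is.null(labels)) labels <- triage_colors(cases, profile)
  if (length(labels) != nrow(cases)) {
    abort("one label per grid case required", "fieldtriage_training_error")
  }
  if (!all(c("green", "yellow", "red") %in% labels)) {
    abort("training labels must contain all of green, yellow and red",
          "fieldtriage_training_error")
  }
  set.seed(as.integer(seed))
  # standardise features once; both stages share the scaling
  ctr <- vapply(cases, mean, numeric(1))
  scl <- vapply(cases, stats::sd, numeric(1))
  x <- scale(as.matrix(cases), center = ctr, scale = scl)

  y_a <- factor(ifelse(labels == "red", "red", "notred"),
                levels = c("red", "notred"))
  fit_a <- e1071::svm(x, y_a, kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
  d_a <- orient_margin(fit_a, x, y_a == "red")

  nr <- labels != "red"
  y_b <- factor(ifelse(labels[nr] == "yellow", "yellow", "green"),
                levels = c("yellow", "green"))
  fit_b <- e1071::svm(x[nr, , drop = FALSE], y_b, kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
  d_b <- orient_margin(fit_b, x[nr, , drop = FALSE], y_b == "yellow")

  model <- structure(list(
    stage_a = fit_a, stage_b = fit_b,
    orient_a = attr(d_a, "orient"), orient_b = attr(d_b, "orient"),
    # margin scales normalise the logistic squash (median absolute margin)
    scale_a = stats::median(abs(d_a)), scale_b = stats::median(abs(d_b)),
    center = ctr, scale = scl, seed = as.integer(seed),
    bands = list(red = c(1, 50), yellow = c(51, 99), green = c(100, 100)),
    profile = profile
  ), class = "survival_model")
  model$training_agreement <-
    mean(predict_color(model, cases) == labels)
  model
}

# signed decision values oriented so positive = first ("positive") class
orient_margin <- function(fit, x, is_positive) {
  d <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  orient <- if (mean(d[is_positive]) >= mean(d[!is_positive])) 1 else -1
  structure(d * orient, orient = orient)
}

#' @export
print.survival_model <- function(x, ...) {
  cat(sprintf(
    "<survival_model> two-stage RBF large-margin classifier (seed %d)\n",
    x$seed))
  cat(sprintf("  training-label agreement: %.2f%%\n", 100 * x$training_agreement))
  cat("  bands: red 1-50%, yellow 51-99%, green 100%\n")
  invisible(x)
}

model_margins <- function(model, cases) {
  x <- scale(as.matrix(cases[, VITAL_SIGNS, drop = FALSE]),
             center = model$center, scale = model$scale)
  d_a <- attr(stats::predict(model$stage_a, x, decision.values = TRUE),
              "decision.values")[, 1] * model$orient_a
  d_b <- attr(stats::predict(model$stage_b, x, decision.values = TRUE),
              "decision.values")[, 1] * model$orient_b
  list(red = d_a, yellow = d_b)
}

predict_color <- function(model, cases) {
  m <- model_margins(model, cases)
  ifelse(m$red > 0, "red", ifelse(m$yellow > 0, "yellow", "green"))
}

chance_from_margins <- function(model, m) {
  color <- ifelse(m$red > 0, "red", ifelse(m$yellow > 0, "yellow", "green"))
  # logistic squash of the signed margin, affinely mapped into the band
  raw_red <- 100 * stats::plogis(-m$red / model$scale_a)
  raw_yel <- 51 + 48 * stats::plogis(-m$yellow / model$scale_b)
  chance <- ifelse(color == "green", 100,
            ifelse(color == "red",
                   clamp(round(raw_red), 1, 50),
                   clamp(round(raw_yel), 51, 99)))
  list(chance = chance, color = color,
       raw = ifelse(color == "green", 100,
                    ifelse(color == "red", raw_red, raw_yel)))
}

#' Calibrated chance of survival for one casualty
#'
#' Only defined at full reliability: all four signs must be present. The
#' predicted colour fixes the band (red 1-50%, yellow 51-99%, green exactly
#' 100%); the signed margin distance of the deciding machine is squashed
#' through a logistic map, affinely placed inside the band, rounded to an
#' integer percent and clamped.
#'
#' @param model A [train_survival_model()] fit.
#' @param case A [vital_snapshot()] (all four signs present) or a data frame
#'   with columns rr/hr/sbp/spo2.
#' @return Integer percent(s) in \[1, 100\].
#' @export
survival_chance <- function(model, case) {
  stopifnot(inherits(model, "survival_model"))
  if (inherits(case, "vital_snapshot")) {
    if (length(available_signs(case)) < 4) {
      abort("survival chance is only defined when all four signs are present",
            "fieldtriage_unsupported_input")
    }
    case <- as.data.frame(case[VITAL_SIGNS])
  }
  if (any(is.na(case[, VITAL_SIGNS]))) {
    abort("survival chance is only defined when all four signs are present",
          "fieldtriage_unsupported_input")
  }
  chance_from_margins(model, model_margins(model, case))$chance
}

#' Band-compliance report for a fitted survival model
#'
#' Audits the fitted chance-of-survival function over a labelled grid:
#' per-colour case counts, the fraction of calibrated outputs inside their
#' colour's band (1.0 by construction, since outputs are clamped into the
#' band of the predicted class), the pre-clamp fraction (diagnostic for how
#' often the raw logistic map leaves the band), and the agreement between
#' the model's predicted colour and the triage label.
#'
#' @param model A [train_survival_model()] fit.
#' @param grid A [generate_case_grid()] result.
#' @param labels Optional triage labels; recomputed from the model's profile
#'   when omitted.
#' @return List with `counts`, `fraction_in_band`, `pre_clamp_in_band`,
#'   `label_agreement` and the per-case table.
#' @export
band_compliance <- function(model, grid, labels = NULL) {
  stopifnot(inherits(model, "survival_model"), inherits(grid, "case_grid"))
  cases <- grid$cases
  if (is.null(labels)) labels <- triage_colors(cases, model$profile)
  res <- chance_from_margins(model, model_margins(model, cases))
  bands <- model$bands
  in_band <- function(v, col) {
    b <- bands[[col]]
    v >= b[1] & v <= b[2]
  }
  post <- mapply(in_band, res$chance, labels)
  pre <- mapply(in_band, res$raw, labels)
  tab <- data.frame(cases, label = labels, predicted = res$color,
                    chance = res$chance)
  list(
    counts = table(labels),
    fraction_in_band = mean(post),
    pre_clamp_in_band = mean(pre),
    label_agreement = mean(res$color == labels),
    cases = tab
  )
}

#' Monte-Carlo off-grid audit of the survival classifier
#'
#' Samples cases the model was never trained on by jittering random grid
#' cases within their cells (each coordinate moved up to `margin` of the gap
#' towards its neighbouring level) and compares the model's predicted colour
#' with the triage cascade's label. The default margin stays clear of the
#' thin slab around each clinical threshold whose sub-cell position the
#' training grid cannot resolve; widen `margin` to 0.5 to cover the cells
#' completely, boundary slivers included.
#'
#' @param model A [train_survival_model()] fit.
#' @param grid The training [generate_case_grid()].
#' @param n Number of audit cases.
#' @param seed RNG seed.
#' @param margin Fraction of the inter-level gap used for jitter (0, 0.5].
#' @return List with `agreement` (fraction of audit cases whose predicted
#'   colour matches the cascade label), `n`, and the audit `cases`.
#' @export
audit_off_grid <- function(model, grid, n = 1000, seed = 7, margin = 0.4) {
  stopifnot(inherits(model, "survival_model"), inherits(grid, "case_grid"))
  set.seed(as.integer(seed))
  idx <- sample(nrow(grid$cases), n, replace = TRUE)
  cases <- grid$cases[idx, , drop = FALSE]
  for (s in names(grid$axes)) {
    ax <- grid$axes[[s]]
    pos <- match(cases[[s]], ax)
    lo_gap <- ifelse(pos > 1, ax[pos] - ax[pmax(pos - 1, 1)], 0)
    hi_gap <- ifelse(pos < length(ax), ax[pmin(pos + 1, length(ax))] - ax[pos], 0)
    u <- stats::runif(n, -margin, margin)
    cases[[s]] <- cases[[s]] + ifelse(u < 0, u * lo_gap, u * hi_gap)
  }
  labs <- triage_colors(cases, model$profile)
  pred <- predict_color(model, cases)
  list(agreement = mean(pred == labs), n = n, cases = cases,
       labels = labs, predicted = pred)
}

#' Export a labelled case grid as CSV
#' @param grid A [generate_case_grid()] result.
#' @param path Output file.
#' @param profile Profile used to label the cases.
#' @return Invisibly, the written data frame (columns rr,hr,sbp,spo2,color).
#' @export
export_case_grid <- function(grid, path, profile = default_reference_profile()) {
  df <- grid$cases
  df$color <- triage_colors(df, profile)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
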