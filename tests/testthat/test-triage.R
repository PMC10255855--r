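test_that("severity_of classifies against reference and critical bounds", {
  prof <- typical_profile()
  cases <- list(
    list(15, "rr", "in_reference"),   # inside 9-20
    list(25, "rr", "out_of_reference"),
    list(35, "rr", "critical"),       # beyond crit_hi 30
    list(4,  "rr", "critical"),
    list(9,  "rr", "in_reference"),   # interval edges are in-reference
    list(20, "rr", "in_reference"),
    list(30, "rr", "critical"),       # critical edge is critical
    list(97, "spo2", "in_reference"),
    list(90, "spo2", "out_of_reference"),
    list(85, "spo2", "critical")      # one-sided low threshold
  )
  for (cs in cases) {
    expect_equal(as.character(severity_of(cs[[1]], cs[[2]], prof)), cs[[3]],
                 label = sprintf("%s=%g", cs[[2]], cs[[1]]))
  }
  expect_error(severity_of(15, "temperature", prof), class = "fieldtriage_config_error")
  expect_error(severity_of(-3, "rr", prof), class = "fieldtriage_input_error")
  expect_true(severity_of(15, "rr", prof) < severity_of(25, "rr", prof))
  expect_true(severity_of(25, "rr", prof) < severity_of(35, "rr", prof))
})

test_that("cascade colours match the printed examples", {
  prof <- typical_profile()
  d <- triage(snap(), prof)
  expect_equal(d$color, "green")
  expect_equal(d$reliability, 100)
  expect_equal(d$survival_chance, 100)

  expect_equal(triage(snap(rr = 25), prof)$color, "yellow")
  expect_equal(triage(snap(hr = 150), prof)$color, "red")

  blk <- triage(snap(hr = NA), prof)
  expect_equal(blk$color, "black")
  expect_true(blk$needs_confirmation)
  expect_true(is.na(blk$reliability))
})

test_that("missing non-HR signs skip their stage and lower reliability", {
  prof <- typical_profile()
  d <- triage(snap(spo2 = NA), prof)
  expect_equal(d$color, "green")
  expect_equal(d$reliability, 90)
  expect_true(is.na(d$survival_chance))  # survival only at full reliability

  d2 <- triage(snap(rr = NA, sbp = NA, spo2 = 80), prof)
  expect_equal(d2$reliability, 60)
  expect_equal(d2$color, "red")  # SpO2 80 is at/below the critical 85
})

test_that("reliability table is exact over all HR-containing subsets", {
  expected <- list(
    list(c("rr", "hr", "sbp", "spo2"), 100),
    list(c("hr", "rr", "sbp"), 90),
    list(c("hr", "rr", "spo2"), 80),
    list(c("hr", "rr"), 70),
    list(c("hr", "sbp", "spo2"), 80),
    list(c("hr", "sbp"), 70),
    list(c("hr", "spo2"), 60),
    list("hr", 50)
  )
  for (e in expected) {
    expect_equal(reliability_of(e[[1]]), e[[2]],
                 label = paste(e[[1]], collapse = "+"))
  }
  # image is exactly the printed score set
  scores <- vapply(expected, function(e) reliability_of(e[[1]]), numeric(1))
  expect_setequal(scores, c(50, 60, 70, 80, 90, 100))
  # every HR-less subset signals black
  for (s in list(character(0), "rr", c("rr", "sbp"), c("rr", "sbp", "spo2"))) {
    expect_true(is.na(reliability_of(s)))
  }
  expect_error(reliability_of("ecg"), class = "fieldtriage_config_error")
})

test_that("cascade equals the max-severity oracle on an exhaustive grid", {
  prof <- typical_profile()
  # 20 values per sign spanning below-critical to above-critical
  axes <- list(
    rr = seq(2, 40, length.out = 20),
    hr = seq(20, 170, length.out = 20),
    sbp = seq(50, 260, length.out = 20),
    spo2 = seq(70, 100, length.out = 20)
  )
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  got <- triage_colors(grid, prof)
  want <- mapply(oracle_color, grid$rr, grid$hr, grid$sbp, grid$spo2,
                 MoreArgs = list(profile = prof))
  expect_identical(got, unname(want))

  # scalar triage() agrees with the vectorised cascade on a random sample
  set.seed(1)
  idx <- sample(nrow(grid), 300)
  for (i in idx) {
    d <- triage(snap(grid$rr[i], grid$hr[i], grid$sbp[i], grid$spo2[i]), prof)
    expect_identical(d$color, got[i])
  }
})

test_that("worsening any single sign never lowers the colour severity", {
  prof <- typical_profile()
  rank <- c(green = 1, yellow = 2, red = 3)
  set.seed(42)
  for (rep in 1:200) {
    base <- list(rr = runif(1, 6, 28), hr = runif(1, 42, 135),
                 sbp = runif(1, 82, 215), spo2 = runif(1, 86, 100))
    s <- sample(names(base), 1)
    worse <- base
    th <- prof[[s]]
    mid <- (th$ref_lo + th$ref_hi) / 2
    # move the sign further from the reference midpoint
    delta <- runif(1, 0, 30)
    worse[[s]] <- if (base[[s]] >= mid) base[[s]] + delta
                  else max(base[[s]] - delta, 0.1)
    if (s == "spo2") worse[[s]] <- min(worse[[s]], 100)
    c0 <- triage(do.call(snap, base), prof)$color
    c1 <- triage(do.call(snap, worse), prof)$color
    expect_gte(rank[[c1]], rank[[c0]])
  }
})

test_that("manual override rules: blue only via authorised roles", {
  prof <- typical_profile()
  auto <- triage(snap(rr = 25), prof)
  expect_equal(auto$source, "automatic")

  blue <- apply_override(auto, "blue", "medic")
  expect_equal(blue$color, "blue")
  expect_equal(blue$source, "manual")
  expect_length(blue$history, 1)
  expect_equal(blue$history[[1]]$color, "yellow")

  confirm <- apply_override(auto, "yellow", "rescuer")
  expect_equal(confirm$color, "yellow")
  expect_equal(confirm$source, "manual")
  expect_equal(confirm$survival_chance, auto$survival_chance)

  expect_error(apply_override(auto, "blue", "commander"),
               class = "fieldtriage_permission_error")
  # no automatic path to blue
  expect_error(triage_decision("s1", 0, "blue", source = "automatic"),
               class = "fieldtriage_invariant_error")
})

test_that("evacuation ordering: urgency, survival chance, blue last, black aside", {
  d <- function(color, chance = NA, ts = 0, id = "x") {
    triage_decision(id, ts, color,
                    reliability = if (color %in% c("black", "blue")) NA else 100,
                    survival_chance = chance,
                    source = if (color == "blue") "manual" else "automatic")
  }
  cs <- list(d("yellow", 70), d("red", 45), d("blue"), d("red", 20),
             d("green", 100), d("black"))
  std <- evacuation_order(cs, "standard")
  expect_equal(vapply(std, `[[`, character(1), "color"),
               c("red", "red", "yellow", "green", "blue"))
  expect_equal(vapply(std, `[[`, numeric(1), "survival_chance")[1:2], c(20, 45))
  expect_length(attr(std, "unconfirmed"), 1)
  expect_equal(attr(std, "unconfirmed")[[1]]$color, "black")

  rev <- evacuation_order(cs, "reverse")
  expect_equal(vapply(rev, `[[`, character(1), "color"),
               c("green", "yellow", "red", "red", "blue"))

  # ties break on earlier timestamp
  tie <- evacuation_order(list(d("red", 30, ts = 5000, id = "late"),
                               d("red", 30, ts = 1000, id = "early")),
                          "standard")
  expect_equal(tie[[1]]$soldier_id, "early")

  empty <- evacuation_order(list())
  expect_length(empty, 0)
})

test_that("decision invariants hold by construction", {
  expect_error(triage_decision("s1", 0, "green", reliability = 95),
               class = "fieldtriage_invariant_error")
  expect_error(triage_decision("s1", 0, "yellow", reliability = 90,
                               survival_chance = 80),
               class = "fieldtriage_invariant_error")
  blk <- triage_decision("s1", 0, "black")
  expect_true(blk$needs_confirmation)
})
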