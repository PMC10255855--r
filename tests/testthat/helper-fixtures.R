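# shared fixtures, built in code

typical_profile <- function(id = "s1") default_reference_profile(id)

snap <- function(rr = 14, hr = 72, sbp = 120, spo2 = 97, id = "s1", ts = 0,
                 ...) {
  vital_snapshot(id, ts, rr = rr, hr = hr, sbp = sbp, spo2 = spo2, ...)
}

# independent oracle: colour = maximum single-sign severity, computed sign
# by sign with scalar interval logic (no shared code with the cascade)
oracle_color <- function(rr, hr, sbp, spo2, profile) {
  sev1 <- function(v, th) {
    if (v <= th$crit_lo || (!is.na(th$crit_hi) && v >= th$crit_hi)) return(3L)
    if (v >= th$ref_lo && v <= th$ref_hi) return(1L)
    2L
  }
  worst <- max(sev1(rr, profile$rr), sev1(hr, profile$hr),
               sev1(sbp, profile$sbp), sev1(spo2, profile$spo2))
  c("green", "yellow", "red")[worst]
}

# small deterministic training grid (all three colours, quick to fit)
small_grid <- function() {
  generate_case_grid(
    rr = c(4, 10, 15, 19, 25, 31),
    hr = c(35, 60, 90, 105, 125, 145),
    sbp = c(75, 105, 140, 175, 200, 225),
    spo2 = c(84, 90, 95, 98),
    grid_id = "small"
  )
}

baseline_scenario <- function(id = "s1", seed = 7, dur = 90) {
  scenario_spec(id, seed = seed,
                segments = list(scenario_segment(dur, "baseline")))
}
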