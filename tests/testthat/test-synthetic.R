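test_that("ECG synthesis: sample count, truth peaks, determinism, ramps", {
  e <- synth_ecg(60, fs = 250, seed = 1, duration_s = 10)
  expect_equal(length(e$frame$samples), 2500)
  expect_equal(length(e$r_peaks), 10)

  e2 <- synth_ecg(60, fs = 250, seed = 1, duration_s = 10)
  expect_identical(e$frame$samples, e2$frame$samples)
  e3 <- synth_ecg(60, fs = 250, seed = 2, duration_s = 10)
  expect_false(identical(e$frame$samples, e3$frame$samples))
  # seeds change noise, not truth
  expect_identical(as.numeric(e$r_peaks), as.numeric(e3$r_peaks))

  ramp <- synth_ecg(data.frame(time_s = c(0, 30), value = c(60, 120)),
                    seed = 1, duration_s = 30)
  expect_true(all(diff(diff(as.numeric(ramp$r_peaks))) < 0))

  expect_error(synth_ecg(-10, seed = 1), class = "fieldtriage_validation_error")
})

test_that("PPG pair embeds PAT and the red/IR amplitude ratio exactly", {
  cal <- calibration_record("sim")
  p <- synth_ppg_pair(60, 120, 94, fs = 100, seed = 1, duration_s = 20,
                      cal = cal, snr_db = Inf)
  # target SBP 120 with a=-0.4, b=220 -> embedded PAT = 250 ms
  e <- synth_ecg(60, fs = 250, seed = 1, duration_s = 20, snr_db = Inf)
  pats <- as.numeric(p$feet) - as.numeric(e$r_peaks)[seq_along(p$feet)]
  expect_equal(stats::median(pats), 250, tolerance = 1e-6)
  # target SpO2 94 -> embedded amplitude ratio R = 0.64
  r_est <- (stats::sd(p$red$samples) / mean(p$red$samples)) /
    (stats::sd(p$ir$samples) / mean(p$ir$samples))
  expect_equal(r_est, 0.64, tolerance = 0.01)
})

test_that("round trip: extraction recovers generator targets on clean streams", {
  st <- generate_scenario(baseline_scenario(dur = 70, seed = 20))
  s <- snapshot_from_signals(st$frames, st$spec$cal, c(60000, 70000))
  truth <- st$truth[st$truth$time_s == 60, ]
  expect_lt(abs(s$hr - truth$hr), 2)
  expect_lt(abs(s$rr - truth$rr), 1)
  expect_lt(abs(s$spo2 - truth$spo2), 2)
  expect_lt(abs(s$sbp - truth$sbp), 5)
})

test_that("hemorrhage scenario drives the triage sequence green->yellow->red", {
  spec <- scenario_spec("h1", seed = 21, segments = list(
    scenario_segment(60, "baseline"),
    scenario_segment(120, "hemorrhage")
  ))
  st <- generate_scenario(spec)
  # truth trajectories move the right way over the hemorrhage segment
  seg <- st$truth[st$truth$state == "hemorrhage", ]
  expect_gt(tail(seg$hr, 1), head(seg$hr, 1))
  expect_lt(tail(seg$sbp, 1), head(seg$sbp, 1))
  expect_lt(tail(seg$spo2, 1), head(seg$spo2, 1))

  snaps <- stream_to_snapshots(st, period_s = 10)
  prof <- default_reference_profile("h1")
  cols <- vapply(snaps, function(s) triage(s, prof)$color, character(1))
  rank <- c(green = 1, yellow = 2, red = 3)[cols]
  expect_equal(cols[1], "green")
  expect_equal(cols[length(cols)], "red")
  expect_true(any(cols == "yellow"))
  expect_true(all(diff(rank) >= 0))  # monotone deterioration
})

test_that("baseline scenario triages green throughout", {
  st <- generate_scenario(baseline_scenario(dur = 120, seed = 22))
  snaps <- stream_to_snapshots(st, period_s = 20, window_s = 10)
  prof <- typical_profile()
  # skip the first window: the respiration estimate needs 30 s of signal
  for (s in snaps[-1]) {
    expect_equal(triage(s, prof)$color, "green")
  }
})

test_that("identical spec and seed reproduce the stream bit for bit", {
  a <- generate_scenario(baseline_scenario(seed = 23, dur = 40))
  b <- generate_scenario(baseline_scenario(seed = 23, dur = 40))
  for (ch in names(a$frames)) {
    expect_identical(a$frames[[ch]]$samples, b$frames[[ch]]$samples)
  }
  expect_identical(a$truth, b$truth)
})

test_that("dropout masks only the targeted interval and annotates the log", {
  st <- generate_scenario(baseline_scenario(dur = 120, seed = 24))
  st2 <- inject_dropout(st, "ecg", c(60000, 120000))
  tms <- fieldtriage:::frame_times(st2$frames$ecg)
  inside <- tms >= 60000 & tms < 120000
  expect_true(all(is.na(st2$frames$ecg$samples[inside])))
  # surviving samples unaltered
  expect_identical(st2$frames$ecg$samples[!inside],
                   st$frames$ecg$samples[!inside])
  expect_identical(st2$frames$ppg_ir$samples, st$frames$ppg_ir$samples)
  expect_length(st2$dropouts, 1)

  # snapshots inside the interval lose HR -> black
  prof <- typical_profile()
  s_in <- snapshot_from_signals(st2$frames, st2$spec$cal, c(80000, 90000))
  expect_true(is.na(s_in$hr))
  expect_equal(triage(s_in, prof)$color, "black")
  s_out <- snapshot_from_signals(st2$frames, st2$spec$cal, c(30000, 40000))
  expect_false(is.na(s_out$hr))

  # PPG-pair dropout leaves HR/RR/SBP-free mode at reliability 90
  st3 <- inject_dropout(st, c("ppg_red", "ppg_ir"), c(60000, 120000))
  s3 <- snapshot_from_signals(st3$frames, st3$spec$cal, c(80000, 90000))
  expect_true(is.na(s3$spo2))
  expect_true(is.na(s3$sbp))
  d3 <- triage(s3, prof)
  expect_equal(d3$reliability, 70)  # HR + RR remain

  expect_identical(inject_dropout(st, character(0), c(0, 1000))$frames,
                   st$frames)
  expect_error(inject_dropout(st, "sonar", c(0, 1000)),
               class = "fieldtriage_validation_error")
})

test_that("scenario validation rejects implausible targets and bad labels", {
  expect_error(scenario_segment(0, "baseline"),
               class = "fieldtriage_validation_error")
  expect_error(
    scenario_spec("x", 1, list(scenario_segment(10, "baseline", hr = 400))),
    class = "fieldtriage_validation_error")
  expect_error(
    synth_resp_acc(15, data.frame(time_s = 0, posture = "hovering",
                                  activity = "rest"), seed = 1,
                   duration_s = 5),
    class = "fieldtriage_validation_error")
})
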