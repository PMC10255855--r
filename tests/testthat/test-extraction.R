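test_that("R-peak detection counts beats and survives noise", {
  e <- synth_ecg(60, fs = 250, seed = 1, duration_s = 30, snr_db = Inf)
  peaks <- detect_r_peaks(e$frame)
  expect_true(abs(length(peaks) - 30) <= 1)
  # detected times match truth within 20 ms
  matched <- vapply(as.numeric(peaks), function(p)
    min(abs(as.numeric(e$r_peaks) - p)), numeric(1))
  expect_lt(max(matched), 20)

  flat <- biosignal_frame("ECG", 250, 0, rep(0, 2500))
  expect_length(detect_r_peaks(flat), 0)

  noisy <- synth_ecg(80, fs = 250, seed = 2, duration_s = 30, snr_db = 10)
  hr <- hr_from_beats(detect_r_peaks(noisy$frame), c(0, 30000))
  expect_lt(abs(hr - 80), 2)

  expect_error(detect_r_peaks(biosignal_frame("RESP", 25, 0, rep(0, 100))),
               class = "fieldtriage_input_error")
  expect_error(detect_r_peaks(biosignal_frame("ECG", 250, 0, rep(0, 100))),
               class = "fieldtriage_input_error")  # < 2 s
})

test_that("pulse-foot detection recovers embedded foot times", {
  p <- synth_ppg_pair(60, 120, 97, fs = 100, seed = 1, duration_s = 30,
                      snr_db = Inf)
  feet <- detect_pulse_feet(p$ir)
  expect_true(abs(length(feet) - length(p$feet)) <= 1)
  err <- vapply(as.numeric(feet), function(f)
    min(abs(as.numeric(p$feet) - f)), numeric(1))
  expect_lt(stats::median(err), 20)

  flat <- biosignal_frame("PPG_IR", 100, 0, rep(2, 1000))
  expect_length(detect_pulse_feet(flat), 0)

  # with default noise the median foot error stays inside 20 ms
  pn <- synth_ppg_pair(60, 120, 97, fs = 100, seed = 3, duration_s = 30)
  fn <- detect_pulse_feet(pn$ir)
  errn <- vapply(as.numeric(fn), function(f)
    min(abs(as.numeric(pn$feet) - f)), numeric(1))
  expect_lt(stats::median(errn), 20)

  expect_error(detect_pulse_feet(biosignal_frame("ECG", 250, 0, rep(0, 500))),
               class = "fieldtriage_input_error")
})

test_that("heart rate from beat intervals is the closed-form mean", {
  beats <- beat_series(seq(0, 10000, by = 1000), "ECG")
  expect_equal(hr_from_beats(beats, c(0, 10001)), 60)
  expect_true(is.na(hr_from_beats(beat_series(500, "ECG"), c(0, 10000))))
  b750 <- beat_series(seq(0, 9750, by = 750), "ECG")
  expect_lt(abs(hr_from_beats(b750, c(0, 10000)) - 80), 1)
})

test_that("pulse arrival times pair peaks with following feet", {
  r <- beat_series(c(0, 1000, 2000), "ECG")
  f <- beat_series(c(250, 1250, 2250), "PPG_IR")
  expect_equal(pat_series(r, f), c(250, 250, 250))
  # a foot before the first peak is ignored
  f2 <- beat_series(c(-100, 250, 1250), "PPG_IR")
  expect_equal(pat_series(r, f2), c(250, 250))
  # unmatched peaks (no foot within 600 ms) are skipped
  f3 <- beat_series(c(250, 1700), "PPG_IR")
  expect_equal(pat_series(r, f3), 250)
})

test_that("SBP calibration is the linear PAT map", {
  cal <- calibration_record("s1", a = -0.4, b = 220)
  expect_equal(sbp_from_pat(c(250, 250, 250), cal), 120)
  expect_equal(sbp_from_pat(c(200, 200, 200, 200), cal), 140)
  expect_true(is.na(sbp_from_pat(c(250, 250), cal)))  # < 3 values
  expect_error(calibration_record("s1", a = 0.4),
               class = "fieldtriage_config_error")
})

test_that("SpO2 follows the ratio-of-ratios calibration curve", {
  cal <- calibration_record("s1")
  # closed form on constructed windows: sd ratio encodes R, equal DC
  mk <- function(amp) {
    t <- seq(0, 10, by = 0.01)
    base <- sin(2 * pi * t)
    biosignal_frame("PPG_RED", 100, 0, 2 + amp * base - mean(amp * base))
  }
  red <- mk(0.4); red$channel <- "PPG_RED"
  ir <- mk(1.0); ir$channel <- "PPG_IR"
  expect_equal(spo2_from_ppg(red, ir, c(0, 10000), cal), 100)  # R=0.4 clamps
  red64 <- mk(0.64)
  expect_equal(spo2_from_ppg(red64, ir, c(0, 10000), cal), 94, tolerance = 1e-6)

  # synthetic pair with target saturation 94
  p <- synth_ppg_pair(60, 120, 94, fs = 100, seed = 5, duration_s = 30)
  est <- spo2_from_ppg(p$red, p$ir, c(0, 30000), cal)
  expect_lt(abs(est - 94), 2)
})

test_that("respiratory rate is the dominant spectral frequency", {
  t <- seq(0, 60, by = 1 / 25)[-1]
  f <- biosignal_frame("RESP", 25, 0, sin(2 * pi * 0.25 * t))
  expect_lt(abs(rr_from_resp(f, c(0, 60000)) - 15), 0.3)

  flat <- biosignal_frame("RESP", 25, 0, rep(0.3, 1500))
  expect_true(is.na(rr_from_resp(flat, c(0, 60000))))
  expect_error(rr_from_resp(f, c(0, 20000)), class = "fieldtriage_input_error")

  ra <- synth_resp_acc(20, data.frame(time_s = 0, posture = "upright",
                                      activity = "rest"),
                       seed = 4, duration_s = 60)
  expect_lt(abs(rr_from_resp(ra$resp, c(0, 60000)) - 20), 1)
})

test_that("posture follows the gravity axis convention; movement overrides", {
  mk_acc <- function(g, n = 500) {
    biosignal_frame("ACC3", 50, 0, matrix(rep(g, each = n), ncol = 3))
  }
  expect_equal(activity_and_posture(mk_acc(c(1, 0, 0)), c(0, 10000))$body_position,
               "upright")
  expect_equal(activity_and_posture(mk_acc(c(0, 0, 1)), c(0, 10000))$body_position,
               "supine")
  expect_equal(activity_and_posture(mk_acc(c(0, 0, -1)), c(0, 10000))$body_position,
               "prone")
  expect_equal(activity_and_posture(mk_acc(c(0, 1, 0)), c(0, 10000))$body_position,
               "lateral")
  expect_lt(activity_and_posture(mk_acc(c(1, 0, 0)), c(0, 10000))$mpa, 0.1)

  ra <- synth_resp_acc(15, data.frame(time_s = 0, posture = "upright",
                                      activity = "run"),
                       seed = 6, duration_s = 20)
  ap <- activity_and_posture(ra$acc, c(0, 20000))
  expect_gt(ap$mpa, 0.1)
  expect_equal(ap$body_position, "moving")
})

test_that("snapshot assembly recovers clean 60 s stream vitals within tolerance", {
  st <- generate_scenario(baseline_scenario(dur = 70, seed = 11))
  s <- snapshot_from_signals(st$frames, st$spec$cal, c(60000, 70000),
                             soldier_id = "s1")
  expect_lt(abs(s$hr - 72), 2)
  expect_lt(abs(s$rr - 14), 1)
  expect_lt(abs(s$spo2 - 97), 2)
  expect_lt(abs(s$sbp - 120), 5)
  expect_equal(s$body_position, "upright")
  expect_equal(triage(s, typical_profile())$color, "green")
})

test_that("missing channels yield absent signs and degraded downstream modes", {
  st <- generate_scenario(baseline_scenario(dur = 70, seed = 12))
  frames <- st$frames
  frames$ecg <- NULL
  s <- snapshot_from_signals(frames, st$spec$cal, c(60000, 70000),
                             soldier_id = "s1")
  expect_true(is.na(s$hr))
  expect_true(is.na(s$sbp))  # PAT needs the ECG fiducial
  d <- triage(s, typical_profile())
  expect_equal(d$color, "black")

  expect_error(
    snapshot_from_signals(st$frames, st$spec$cal, c(60000, 60000)),
    class = "fieldtriage_validation_error")
})

test_that("extraction is deterministic for a fixed frame", {
  st <- generate_scenario(baseline_scenario(dur = 70, seed = 13))
  s1 <- snapshot_from_signals(st$frames, st$spec$cal, c(60000, 70000))
  s2 <- snapshot_from_signals(st$frames, st$spec$cal, c(60000, 70000))
  expect_identical(s1, s2)
})

test_that("frame CSV round-trip preserves samples and metadata", {
  st <- generate_scenario(baseline_scenario(dur = 35, seed = 14))
  path <- withr::local_tempfile(fileext = ".csv")
  write_frame_csv(st$frames$resp, path)
  back <- read_frame_csv(path)
  expect_equal(back$channel, "RESP")
  expect_equal(back$sampling_rate, 25)
  expect_equal(back$samples, st$frames$resp$samples, tolerance = 1e-9)
  write_frame_csv(st$frames$acc, path)
  acc <- read_frame_csv(path)
  expect_equal(dim(acc$samples), dim(st$frames$acc$samples))
})
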