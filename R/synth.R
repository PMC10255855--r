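SCENARIO_STATES <- c("baseline", "exertion", "hemorrhage",
                     "respiratory_failure", "cardiac_arrest")

ACTIVITY_LEVELS <- c("rest", "walk", "run")

# physiological end-targets each scenario state drifts towards
STATE_TARGETS <- list(
  baseline            = list(hr = 72,  rr = 14, sbp = 120, spo2 = 97,
                             posture = "upright", activity = "rest"),
  exertion            = list(hr = 125, rr = 22, sbp = 135, spo2 = 96,
                             posture = "upright", activity = "run"),
  hemorrhage          = list(hr = 150, rr = 26, sbp = 75,  spo2 = 88,
                             posture = "supine", activity = "rest"),
  respiratory_failure = list(hr = 120, rr = 32, sbp = 110, spo2 = 80,
                             posture = "supine", activity = "rest"),
  cardiac_arrest      = list(hr = 0,   rr = 0,  sbp = 40,  spo2 = 60,
                             posture = "supine", activity = "rest")
)

#' One segment of a casualty scenario timeline
#'
#' Each segment lasts `duration_s` seconds in a named physiological state.
#' The four vital-sign trajectories ramp linearly from their value at the
#' end of the previous segment to the segment target; targets default to the
#' state's canonical endpoint (e.g. hemorrhage drifts HR up and SBP/SpO2
#' down) and can be overridden per sign with either a single target value or
#' an explicit `c(start, end)` pair.
#'
#' @param duration_s Segment length in seconds, > 0.
#' @param state One of `"baseline"`, `"exertion"`, `"hemorrhage"`,
#'   `"respiratory_failure"`, `"cardiac_arrest"`.
#' @param hr,rr,sbp,spo2 Optional trajectory overrides.
#' @param posture,activity Optional posture / activity label overrides.
#' @return A `scenario_segment` list.
#' @export
scenario_segment <- function(duration_s, state = "baseline", hr = NULL,
                             rr = NULL, sbp = NULL, spo2 = NULL,
                             posture = NULL, activity = NULL) {
  if (!is_scalar_number(duration_s) || duration_s <= 0) {
    abort("segment duration must be > 0", "fieldtriage_validation_error")
  }
  state <- match.arg(state, SCENARIO_STATES)
  tgt <- STATE_TARGETS[[state]]
  posture <- posture %||% tgt$posture
  activity <- activity %||% tgt$activity
  posture <- match.arg(posture, setdiff(BODY_POSITIONS, "moving"))
  activity <- match.arg(activity, ACTIVITY_LEVELS)
  structure(list(duration_s = duration_s, state = state,
                 hr = hr, rr = rr, sbp = sbp, spo2 = spo2,
                 posture = posture, activity = activity),
            class = "scenario_segment")
}

#' Casualty scenario specification
#'
#' Bundles a soldier id, a seed and an ordered segment timeline into the
#' input of [generate_scenario()]. Physical plausibility of the targets
#' (HR in \[0, 250\], SpO2 in \[0, 100\], SBP in \[0, 300\], RR in \[0, 60\])
#' is validated here.
#'
#' @param soldier_id Identifier.
#' @param seed Integer seed; noise (not the truth trajectories) depends on it.
#' @param segments List of [scenario_segment()]s.
#' @param snr_db Per-channel additive-noise signal-to-noise ratio in dB.
#' @param fs Named list of sampling rates (Hz); defaults ecg 250, ppg 100,
#'   resp 25, acc 50.
#' @param cal [calibration_record()] whose inverse maps embed SBP into pulse
#'   arrival time and SpO2 into the red/infrared amplitude ratio.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(soldier_id, seed, segments,
                          snr_db = 20,
                          fs = list(ecg = 250, ppg = 100, resp = 25, acc = 50),
                          cal = calibration_record(soldier_id)) {
  if (!length(segments) || !all(vapply(segments, inherits, logical(1),
                                       "scenario_segment"))) {
    abort("segments must be a non-empty list of scenario_segment objects",
          "fieldtriage_validation_error")
  }
  spec <- structure(list(soldier_id = soldier_id, seed = as.integer(seed),
                         segments = segments, snr_db = snr_db, fs = fs,
                         cal = cal),
                    class = "scenario_spec")
  tr <- scenario_trajectories(spec)
  lims <- list(hr = c(0, 250), rr = c(0, 60), sbp = c(0, 300),
               spo2 = c(0, 100))
  for (sgn in names(lims)) {
    v <- tr[[sgn]]$value
    if (any(v < lims[[sgn]][1] | v > lims[[sgn]][2])) {
      abort(sprintf("%s trajectory leaves plausible bounds [%g, %g]",
                    sgn, lims[[sgn]][1], lims[[sgn]][2]),
            "fieldtriage_validation_error")
    }
  }
  spec
}

# piecewise-linear breakpoints (time_s, value) per sign + label timeline
scenario_trajectories <- function(spec) {
  cur <- STATE_TARGETS$baseline[VITAL_SIGNS]
  out <- lapply(VITAL_SIGNS, function(s)
    data.frame(time_s = 0, value = cur[[s]]))
  names(out) <- VITAL_SIGNS
  labels <- data.frame(time_s = numeric(0), posture = character(0),
                       activity = character(0), state = character(0))
  t <- 0
  for (seg in spec$segments) {
    tgt <- STATE_TARGETS[[seg$state]]
    for (s in VITAL_SIGNS) {
      ov <- seg[[s]]
      pair <- if (is.null(ov)) c(out[[s]]$value[nrow(out[[s]])], tgt[[s]])
              else if (length(ov) == 1) c(out[[s]]$value[nrow(out[[s]])], ov)
              else ov[1:2]
      out[[s]] <- rbind(out[[s]],
                        data.frame(time_s = c(t, t + seg$duration_s),
                                   value = pair))
    }
    labels <- rbind(labels, data.frame(time_s = t, posture = seg$posture,
                                       activity = seg$activity,
                                       state = seg$state))
    t <- t + seg$duration_s
  }
  c(out, list(labels = labels, duration_s = t))
}

traj_fun <- function(br) {
  stats::approxfun(br$time_s, br$value, rule = 2, ties = "ordered")
}

# deterministic beat times (s) integrating an instantaneous-rate function;
# rates below 5 bpm generate no beats (arrest)
beat_times_from_rate <- function(rate_fun, duration_s, dt = 0.002) {
  t <- seq(0, duration_s, by = dt)
  r <- pmax(rate_fun(t), 0)
  r[r < 5] <- 0
  phase <- cumsum(r / 60 * dt)
  beats <- t[c(FALSE, diff(floor(phase)) >= 1)]
  beats
}

gauss_bump <- function(t, center, width) exp(-((t - center) / width)^2 / 2)

#' Synthesise an ECG frame with known R-peak times
#'
#' Template-based ECG: one Gaussian QRS bump (and a broad low T wave) per
#' beat, beat times obtained by integrating the instantaneous heart-rate
#' trajectory, plus seeded additive Gaussian noise. Verifiability over
#' realism: the true R-peak times are returned alongside the waveform.
#'
#' @param hr_traj Data frame of breakpoints `(time_s, value)` in bpm, a
#'   single number, or a function of time (s). Rates must lie in (20, 250)
#'   or be zero (arrest).
#' @param fs Sampling rate (Hz), default 250.
#' @param seed Integer seed for the noise.
#' @param duration_s Length of the frame in seconds.
#' @param snr_db Signal-to-noise ratio (QRS amplitude vs noise sd), dB;
#'   `Inf` for a noise-free trace.
#' @param start_time Frame start (ms UTC).
#' @return List with `frame` (the ECG [biosignal_frame()]) and `r_peaks`
#'   (truth [beat_series()], ms).
#' @export
synth_ecg <- function(hr_traj, fs = 250, seed = 1, duration_s = 30,
                      snr_db = 20, start_time = 0) {
  rate <- as_rate_fun(hr_traj, hi = 250)
  beats <- beat_times_from_rate(rate, duration_s)
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  x <- numeric(length(t))
  for (b in beats) {
    idx <- which(t >= b - 0.35 & t <= b + 0.45)
    if (!length(idx)) next
    x[idx] <- x[idx] + gauss_bump(t[idx], b, 0.012) +
      0.15 * gauss_bump(t[idx], b + 0.25, 0.05)
  }
  if (is.finite(snr_db)) {
    set.seed(seed)
    x <- x + stats::rnorm(length(x), sd = 10^(-snr_db / 20))
  }
  list(frame = biosignal_frame("ECG", fs, start_time, x),
       r_peaks = beat_series(start_time + beats * 1000, "ECG"))
}

as_rate_fun <- function(traj, hi) {
  if (is.function(traj)) return(traj)
  if (is.numeric(traj) && length(traj) == 1) {
    if (traj < 0 || traj > hi) {
      abort("rate outside plausible range", "fieldtriage_validation_error")
    }
    v <- traj
    return(function(t) rep(v, length(t)))
  }
  if (is.data.frame(traj)) {
    if (any(traj$value < 0 | traj$value > hi)) {
      abort("rate trajectory outside plausible range",
            "fieldtriage_validation_error")
    }
    return(traj_fun(traj))
  }
  abort("trajectory must be a number, breakpoint data frame or function",
        "fieldtriage_validation_error")
}

# log-normal-ish pulse template rising at u = 0 (the foot), peaking at tau
pulse_template <- function(u, tau = 0.15) {
  ifelse(u <= 0, 0, (u / tau) * exp(1 - u / tau))
}

#' Synthesise a red/infrared PPG pair encoding SBP and SpO2
#'
#' Pulse feet are delayed from the (noise-free) beat times by the pulse
#' arrival time that the calibration maps back to the target systolic
#' pressure, PAT = (SBP - b) / a; the red-channel pulsatile amplitude is
#' scaled relative to infrared so the ratio of ratios equals
#' R = (c0 - SpO2) / c1. Extracting PAT and R under the same calibration
#' therefore recovers the target trajectories.
#'
#' @param hr_traj,sbp_traj,spo2_traj Trajectories (number, breakpoint data
#'   frame or function of seconds).
#' @param fs Sampling rate, default 100 Hz.
#' @param seed Noise seed.
#' @param duration_s Frame length (s).
#' @param cal [calibration_record()] used for the inverse embedding.
#' @param snr_db Noise level relative to the pulsatile amplitude.
#' @param start_time Frame start (ms UTC).
#' @return List with `red` and `ir` [biosignal_frame()]s and the truth
#'   `feet` [beat_series()] (infrared foot times, ms).
#' @export
synth_ppg_pair <- function(hr_traj, sbp_traj, spo2_traj, fs = 100, seed = 1,
                           duration_s = 30, cal = calibration_record("sim"),
                           snr_db = 20, start_time = 0) {
  rate <- as_rate_fun(hr_traj, hi = 250)
  sbp <- as_rate_fun(sbp_traj, hi = 300)
  spo2 <- as_rate_fun(spo2_traj, hi = 100)
  beats <- beat_times_from_rate(rate, duration_s)
  pat_s <- (sbp(beats) - cal$b) / cal$a / 1000   # ms -> s
  if (length(pat_s) && any(pat_s <= 0 | pat_s > 0.6)) {
    abort("SBP trajectory implies pulse arrival times outside (0, 600] ms",
          "fieldtriage_validation_error")
  }
  feet <- beats + pat_s
  r_ratio <- (cal$c0 - spo2(feet %||% numeric(0))) / cal$c1
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  dc <- 2.0
  amp_ir <- 1.0
  mk <- function(amps) {
    x <- numeric(length(t))
    for (i in seq_along(feet)) {
      idx <- which(t >= feet[i] & t <= feet[i] + 1.8)
      if (!length(idx)) next
      x[idx] <- x[idx] + amps[i] * pulse_template(t[idx] - feet[i])
    }
    # zero-mean pulsatile component on a fixed DC level, so the windowed
    # mean is the same for both wavelengths and the AC/DC ratio of ratios
    # embeds R exactly
    dc + x - mean(x)
  }
  ir <- mk(rep(amp_ir, length(feet)))
  red <- mk(amp_ir * r_ratio)
  if (is.finite(snr_db)) {
    set.seed(seed + 1L)
    ir <- ir + stats::rnorm(length(ir), sd = amp_ir * 10^(-snr_db / 20))
    set.seed(seed + 2L)
    red <- red + stats::rnorm(length(red),
                              sd = amp_ir * mean(r_ratio) * 10^(-snr_db / 20))
  }
  list(red = biosignal_frame("PPG_RED", fs, start_time, red),
       ir = biosignal_frame("PPG_IR", fs, start_time, ir),
       feet = beat_series(start_time + feet * 1000, "PPG_IR"))
}

#' Synthesise respiration and 3-axis accelerometer frames
#'
#' Respiration is a unit sinusoid at the instantaneous target rate (flat
#' during apnoea). The accelerometer reads the gravity vector implied by the
#' posture label (axis convention x longitudinal, y lateral, z anterior:
#' upright (1,0,0), supine (0,0,1), prone (0,0,-1), lateral (0,1,0)) plus
#' seeded movement noise; walk/run activity adds dynamic acceleration that
#' raises the mean physical activity above the 0.1 g "moving" threshold.
#'
#' @param rr_traj Breaths/min trajectory (number, data frame or function).
#' @param labels Data frame `(time_s, posture, activity)` label timeline.
#' @param fs Named list with `resp` and `acc` rates (Hz).
#' @param seed Noise seed.
#' @param duration_s Frame length (s).
#' @param snr_db Respiration noise level.
#' @param start_time Frame start (ms UTC).
#' @return List with `resp` and `acc` [biosignal_frame()]s.
#' @export
synth_resp_acc <- function(rr_traj, labels, fs = list(resp = 25, acc = 50),
                           seed = 1, duration_s = 60, snr_db = 20,
                           start_time = 0) {
  rr <- as_rate_fun(rr_traj, hi = 60)
  bad <- setdiff(labels$posture, setdiff(BODY_POSITIONS, "moving"))
  if (length(bad)) {
    abort(sprintf("unknown posture label(s): %s", paste(bad, collapse = ", ")),
          "fieldtriage_validation_error")
  }
  tr <- (seq_len(round(duration_s * fs$resp)) - 1) / fs$resp
  rate <- pmax(rr(tr), 0)
  rate[rate < 2] <- 0
  phase <- cumsum(rate / 60 / fs$resp)
  resp <- sin(2 * pi * phase)
  resp[rate == 0] <- 0
  if (is.finite(snr_db)) {
    set.seed(seed + 3L)
    resp <- resp + stats::rnorm(length(resp), sd = 10^(-snr_db / 20))
  }
  gvec <- list(upright = c(1, 0, 0), supine = c(0, 0, 1),
               prone = c(0, 0, -1), lateral = c(0, 1, 0))
  ta <- (seq_len(round(duration_s * fs$acc)) - 1) / fs$acc
  seg_of <- findInterval(ta, labels$time_s)
  seg_of[seg_of == 0] <- 1L
  acc <- t(vapply(seg_of, function(i) gvec[[labels$posture[i]]], numeric(3)))
  set.seed(seed + 4L)
  acc <- acc + matrix(stats::rnorm(length(ta) * 3, sd = 0.01), ncol = 3)
  dyn_sd <- c(rest = 0, walk = 0.12, run = 0.25)[labels$activity[seg_of]]
  if (any(dyn_sd > 0)) {
    burst <- matrix(stats::rnorm(length(ta) * 3), ncol = 3) * dyn_sd
    # keep movement energy above 0.5 Hz so the high-pass MPA filter sees it
    acc <- acc + burst * sin(2 * pi * 2.1 * ta)
  }
  list(resp = biosignal_frame("RESP", fs$resp, start_time, resp),
       acc = biosignal_frame("ACC3", fs$acc, start_time, acc))
}

#' Generate a full multichannel casualty stream with ground truth
#'
#' Renders every channel of a [scenario_spec()] (ECG, red/IR PPG,
#' respiration, acceleration), using one shared set of noise-free beat times
#' so pulse arrival times are consistent across channels, and samples the
#' target trajectories once per second as the ground-truth record. The
#' truth, not the rendered waveforms, is what extraction accuracy is judged
#' against.
#'
#' @param spec A [scenario_spec()].
#' @return A `generated_stream`: list with `frames` (named list ecg /
#'   ppg_red / ppg_ir / resp / acc), `truth` (per-second data frame of hr,
#'   rr, sbp, spo2, posture, activity, state), `events` (segment-change
#'   log), `dropouts` (empty; see [inject_dropout()]) and the spec.
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  tr <- scenario_trajectories(spec)
  dur <- tr$duration_s
  hr_f <- traj_fun(tr$hr); rr_f <- traj_fun(tr$rr)
  sbp_f <- traj_fun(tr$sbp); spo2_f <- traj_fun(tr$spo2)
  ecg <- synth_ecg(hr_f, fs = spec$fs$ecg, seed = spec$seed,
                   duration_s = dur, snr_db = spec$snr_db)
  ppg <- synth_ppg_pair(hr_f, sbp_f, spo2_f, fs = spec$fs$ppg,
                        seed = spec$seed, duration_s = dur, cal = spec$cal,
                        snr_db = spec$snr_db)
  ra <- synth_resp_acc(rr_f, tr$labels,
                       fs = list(resp = spec$fs$resp, acc = spec$fs$acc),
                       seed = spec$seed, duration_s = dur,
                       snr_db = spec$snr_db)
  ts <- seq(0, dur - 1)
  seg_of <- findInterval(ts, tr$labels$time_s)
  seg_of[seg_of == 0] <- 1L
  truth <- data.frame(
    time_s = ts, hr = hr_f(ts), rr = rr_f(ts), sbp = sbp_f(ts),
    spo2 = spo2_f(ts),
    posture = tr$labels$posture[seg_of],
    activity = tr$labels$activity[seg_of],
    state = tr$labels$state[seg_of]
  )
  structure(list(
    frames = list(ecg = ecg$frame, ppg_red = ppg$red, ppg_ir = ppg$ir,
                  resp = ra$resp, acc = ra$acc),
    truth = truth,
    truth_beats = ecg$r_peaks, truth_feet = ppg$feet,
    events = tr$labels, dropouts = list(), spec = spec
  ), class = "generated_stream")
}

#' @export
print.generated_stream <- function(x, ...) {
  cat(sprintf("<generated_stream> %s: %.0f s, states %s\n",
              x$spec$soldier_id, max(x$truth$time_s) + 1,
              paste(unique(x$truth$state), collapse = " -> ")))
  invisible(x)
}

#' Mask sensor dropout into a generated stream
#'
#' Emulates a sensor being cut off: samples of the named channels inside
#' the interval are masked to missing. Surviving samples are untouched; the
#' dropout is appended to the stream's annotation log so downstream checks
#' know which windows were degraded on purpose.
#'
#' @param stream A [generate_scenario()] result.
#' @param channels Character vector among `"ecg"`, `"ppg_red"`, `"ppg_ir"`,
#'   `"resp"`, `"acc"` (empty = identity).
#' @param interval `c(start, end)` ms within the stream span.
#' @return The stream with masked samples and an annotated `dropouts` log.
#' @export
inject_dropout <- function(stream, channels, interval) {
  stopifnot(inherits(stream, "generated_stream"))
  bad <- setdiff(channels, names(stream$frames))
  if (length(bad)) {
    abort(sprintf("unknown channel(s): %s", paste(bad, collapse = ", ")),
          "fieldtriage_validation_error")
  }
  for (ch in channels) {
    fr <- stream$frames[[ch]]
    idx <- frame_window_idx(fr, interval)
    if (is.null(idx)) next
    if (fr$channel == "ACC3") fr$samples[idx, ] <- NA_real_
    else fr$samples[idx] <- NA_real_
    stream$frames[[ch]] <- fr
  }
  stream$dropouts <- c(stream$dropouts,
                       list(list(channels = channels, interval = interval)))
  stream
}

#' Extract a sequence of snapshots from a generated stream
#'
#' Slides the analysis window across the stream and assembles one
#' [vital_snapshot()] per step — the in-silico equivalent of the wearable
#' hub computing vitals every reporting period.
#'
#' @param stream A [generate_scenario()] result.
#' @param period_s Step between snapshot windows (s).
#' @param window_s Analysis window length (s), default 10.
#' @return List of [vital_snapshot()]s.
#' @export
stream_to_snapshots <- function(stream, period_s = 10, window_s = 10) {
  dur_ms <- (max(stream$truth$time_s) + 1) * 1000
  ends <- seq(window_s * 1000, dur_ms, by = period_s * 1000)
  lapply(ends, function(e) {
    snapshot_from_signals(stream$frames, stream$spec$cal,
                          c(e - window_s * 1000, e),
                          soldier_id = stream$spec$soldier_id)
  })
}
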