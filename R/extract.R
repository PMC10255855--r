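#' Beat event series
#'
#' Strictly increasing event times (ms UTC) of ECG R-peaks or PPG pulse
#' feet, tagged with the channel they came from.
#'
#' @param times Numeric vector of event times in ms, strictly increasing.
#' @param channel Source channel id.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(times, channel) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("beat times must be strictly increasing", "fieldtriage_input_error")
  }
  structure(times, channel = channel, class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d events from %s\n", length(x),
              attr(x, "channel")))
  invisible(x)
}

# clip a frame to [t0, t1) (ms); returns NULL when empty
clip_frame <- function(frame, t0, t1) {
  idx <- frame_window_idx(frame, c(t0, t1))
  if (is.null(idx)) return(NULL)
  samples <- if (frame$channel == "ACC3") frame$samples[idx, , drop = FALSE]
             else frame$samples[idx]
  biosignal_frame(frame$channel, frame$sampling_rate,
                  frame$start_time + (idx[1] - 1) * 1000 / frame$sampling_rate,
                  samples)
}

# local maxima above a threshold with a refractory period, greedily keeping
# the largest first; returns sorted sample indices
pick_peaks <- function(e, thr, refractory_samples) {
  n <- length(e)
  if (n < 3) return(integer(0))
  cand <- which(e[-c(1, n)] >= e[-c(n - 1, n)] & e[-c(1, n)] > e[-c(1, 2)] &
                  e[-c(1, n)] > thr) + 1L
  if (length(cand) == 0) return(integer(0))
  kept <- integer(0)
  for (i in cand[order(e[cand], decreasing = TRUE)]) {
    if (!length(kept) || all(abs(i - kept) >= refractory_samples)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Detect R-peaks in an ECG frame
#'
#' Band-passes the ECG to the QRS band (5-15 Hz, zero-phase Butterworth),
#' squares it, and picks local maxima above an adaptive two-pass threshold
#' (anchored to the median energy of the strongest beats) with a 250 ms
#' refractory period. Two clean-up rules handle noisy traces: a candidate
#' within 360 ms of a much stronger predecessor is discarded as a T wave,
#' and of any pair closer than 0.55 times the running median interval the
#' weaker is dropped. Detections are refined to the raw-signal maximum
#' within +/- 40 ms.
#'
#' @param ecg An ECG [biosignal_frame()], at least 2 s long.
#' @return A [beat_series()] of R-peak times (ms).
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "biosignal_frame"))
  if (ecg$channel != "ECG") {
    abort("detect_r_peaks expects the ECG channel", "fieldtriage_input_error")
  }
  fs <- ecg$sampling_rate
  if (frame_n(ecg) / fs < 2) {
    abort("ECG segment must be at least 2 s", "fieldtriage_input_error")
  }
  x <- ecg$samples
  x[is.na(x)] <- 0
  x <- x - mean(x)
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bf, x)
  e <- f^2
  if (max(e) < 1e-12) return(beat_series(numeric(0), "ECG"))
  refr <- round(0.25 * fs)
  # pass 1: strongest beats fix the QRS energy scale (quantile start point
  # also resists filter edge transients on clipped segments)
  anchor <- pick_peaks(e, thr = 0.5 * stats::quantile(e, 0.999),
                       refractory_samples = refr)
  if (!length(anchor)) return(beat_series(numeric(0), "ECG"))
  idx <- pick_peaks(e, thr = 0.3 * stats::median(e[anchor]),
                    refractory_samples = refr)
  # T-wave discriminator: close follower with much lower energy
  keep <- rep(TRUE, length(idx))
  for (k in seq_along(idx)[-1]) {
    prev <- max(which(keep[seq_len(k - 1)]))
    if ((idx[k] - idx[prev]) / fs < 0.36 && e[idx[k]] < 0.5 * e[idx[prev]]) {
      keep[k] <- FALSE
    }
  }
  idx <- idx[keep]
  # rhythm consistency: a split interval betrays a noise spike
  repeat {
    if (length(idx) < 3) break
    iv <- diff(idx)
    bad <- which(iv < 0.55 * stats::median(iv))
    if (!length(bad)) break
    b <- bad[1]
    idx <- idx[-(if (e[idx[b]] < e[idx[b + 1]]) b else b + 1)]
  }
  # refine to raw maximum near the energy peak
  half <- max(1L, round(0.04 * fs))
  idx <- vapply(idx, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  idx <- sort(unique(idx))
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) >= round(0.25 * fs))]
  beat_series(frame_times(ecg)[idx], "ECG")
}

#' Detect pulse feet in a PPG frame
#'
#' Finds systolic peaks on the band-passed pulsatile component, then walks
#' back from each peak to the preceding waveform minimum (the pulse foot,
#' the fiducial used for pulse-arrival-time measurement).
#'
#' @param ppg A `PPG_RED` or `PPG_IR` [biosignal_frame()].
#' @return A [beat_series()] of foot times (ms).
#' @export
detect_pulse_feet <- function(ppg) {
  stopifnot(inherits(ppg, "biosignal_frame"))
  if (!ppg$channel %in% c("PPG_RED", "PPG_IR")) {
    abort("detect_pulse_feet expects a PPG channel", "fieldtriage_input_error")
  }
  fs <- ppg$sampling_rate
  x <- ppg$samples
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  if (stats::sd(x) < 1e-9) return(beat_series(numeric(0), ppg$channel))
  bf <- signal::butter(2, c(0.5, 8) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bf, x - mean(x))
  e <- pmax(f, 0)^2
  if (max(e) < 1e-12) return(beat_series(numeric(0), ppg$channel))
  peaks <- pick_peaks(e, thr = 0.25 * stats::quantile(e, 0.99),
                      refractory_samples = round(0.3 * fs))
  if (length(peaks) == 0) return(beat_series(numeric(0), ppg$channel))
  # light smoothing before the foot (minimum) search
  k <- max(1L, round(0.02 * fs))
  xs <- as.numeric(stats::filter(x, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  # foot = onset of the systolic upstroke: walk back from the steepest
  # upslope until the (smoothed) derivative stops being positive; more
  # robust than an argmin search across the near-flat diastolic tail
  d <- c(0, diff(xs))
  back <- round(0.4 * fs)
  feet <- vapply(peaks, function(p) {
    lo <- max(2L, p - back)
    seg <- lo:p
    i <- seg[which.max(d[seg])]
    while (i > lo && d[i] > 0) i <- i - 1L
    # the zero-phase smoother smears the upstroke onset ~k samples early;
    # shift back to the true corner
    as.integer(min(i + k, p))
  }, integer(1))
  feet <- sort(unique(feet))
  beat_series(frame_times(ppg)[feet], ppg$channel)
}

#' Heart rate from a beat series
#'
#' Mean-interval estimate over a half-open window: 60000 divided by the mean
#' inter-beat interval (ms) of the beats falling in the window.
#'
#' @param beats A [beat_series()].
#' @param window `c(start, end)` in ms, half-open.
#' @return Beats per minute, or `NA` when fewer than 2 beats fall in the
#'   window.
#' @export
hr_from_beats <- function(beats, window) {
  b <- beats[beats >= window[1] & beats < window[2]]
  if (length(b) < 2) return(NA_real_)
  60000 / mean(diff(b))
}

#' Pulse arrival times from R-peaks and pulse feet
#'
#' For each R-peak, the pulse arrival time (PAT) is the delay to the first
#' pulse foot within the following 600 ms; R-peaks with no matching foot are
#' skipped. PAT shortens as systolic pressure rises, which is what makes
#' cuffless pressure tracking possible.
#'
#' @param r_peaks ECG [beat_series()].
#' @param feet PPG foot [beat_series()].
#' @return Numeric vector of PAT values in ms (possibly empty).
#' @export
pat_series <- function(r_peaks, feet) {
  if (length(r_peaks) == 0 || length(feet) == 0) return(numeric(0))
  ft <- as.numeric(feet)
  out <- vapply(as.numeric(r_peaks), function(r) {
    nxt <- ft[ft > r & ft <= r + 600]
    if (length(nxt)) nxt[1] - r else NA_real_
  }, numeric(1))
  out[!is.na(out)]
}

#' Cuffless systolic blood pressure from pulse arrival time
#'
#' Applies the per-soldier linear calibration SBP = a * median(PAT) + b.
#' The median over the window makes the estimate robust to isolated
#' mis-detected feet.
#'
#' @param pat Numeric PAT values (ms) from [pat_series()].
#' @param cal A [calibration_record()].
#' @return SBP in mmHg, or `NA` with fewer than 3 PAT values.
#' @export
sbp_from_pat <- function(pat, cal) {
  if (length(pat) < 3) return(NA_real_)
  cal$a * stats::median(pat) + cal$b
}

#' Oxygen saturation from a dual-wavelength PPG pair
#'
#' Ratio-of-ratios pulse oximetry: R = (AC/DC)_red / (AC/DC)_ir with AC the
#' standard deviation of the pulsatile component and DC the window mean,
#' mapped through the calibration curve SpO2 = c0 - c1 * R and clamped to
#' \[0, 100\].
#'
#' @param red,ir Red / infrared PPG [biosignal_frame()]s.
#' @param window `c(start, end)` ms, half-open.
#' @param cal A [calibration_record()].
#' @return Percent saturation, or `NA` when either DC is ~0 or the window is
#'   unusable.
#' @export
spo2_from_ppg <- function(red, ir, window, cal) {
  stopifnot(red$channel == "PPG_RED", ir$channel == "PPG_IR")
  if (!window_usable(red, window) || !window_usable(ir, window)) {
    return(NA_real_)
  }
  perfusion <- function(frame) {
    x <- frame$samples[frame_window_idx(frame, window)]
    x <- x[!is.na(x)]
    dc <- mean(x)
    if (abs(dc) < 1e-9) return(NA_real_)
    stats::sd(x) / dc
  }
  p_red <- perfusion(red); p_ir <- perfusion(ir)
  if (is.na(p_red) || is.na(p_ir) || p_ir < 1e-9) return(NA_real_)
  r <- p_red / p_ir
  clamp(cal$c0 - cal$c1 * r, 0, 100)
}

#' Respiratory rate by spectral peak
#'
#' Dominant-frequency estimate of the respiration channel over the window:
#' the detrended, Hann-windowed, zero-padded spectrum is searched in the
#' physiological band 4-60 breaths/min; the peak frequency times 60 is the
#' rate. A flat or broadband window (no clear spectral peak) yields `NA`.
#'
#' @param resp A RESP [biosignal_frame()].
#' @param window `c(start, end)` ms; at least 30 s.
#' @return Breaths per minute, or `NA`.
#' @export
rr_from_resp <- function(resp, window) {
  stopifnot(resp$channel == "RESP")
  if (diff(window) < 30000) {
    abort("respiratory-rate window must be at least 30 s",
          "fieldtriage_input_error")
  }
  if (!window_usable(resp, window)) return(NA_real_)
  idx <- frame_window_idx(resp, window)
  x <- resp$samples[idx]
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  x <- x - mean(x)
  if (stats::sd(x) < 1e-9) return(NA_real_)
  n <- length(x)
  fs <- resp$sampling_rate
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  nfft <- 2^ceiling(log2(n * 8))
  spec <- Mod(stats::fft(c(x * w, rep(0, nfft - n))))[1:(nfft %/% 2)]^2
  freq <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  band <- freq >= 4 / 60 & freq <= 1
  if (!any(band)) return(NA_real_)
  pk <- which.max(spec[band])
  # a real respiratory peak must dominate the band
  if (spec[band][pk] < 5 * stats::median(spec[band])) return(NA_real_)
  freq[band][pk] * 60
}

#' Activity level and body position from the chest accelerometer
#'
#' Mean physical activity (MPA) is the windowed mean magnitude of the
#' high-pass-filtered (0.5 Hz) acceleration, in g. When the casualty is
#' still (MPA < 0.1 g) posture is read off the gravity direction using the
#' chest-sensor axis convention x = longitudinal, y = lateral, z = anterior:
#' gravity on x means upright, +z supine, -z prone, y lateral. Above 0.1 g
#' the position is reported as `"moving"`.
#'
#' @param acc An ACC3 [biosignal_frame()], window at least 2 s.
#' @param window `c(start, end)` ms.
#' @return List with `mpa` (g) and `body_position`.
#' @export
activity_and_posture <- function(acc, window) {
  stopifnot(acc$channel == "ACC3")
  if (diff(window) < 2000) {
    abort("activity window must be at least 2 s", "fieldtriage_input_error")
  }
  if (!window_usable(acc, window)) {
    return(list(mpa = NA_real_, body_position = NA_character_))
  }
  idx <- frame_window_idx(acc, window)
  a <- acc$samples[idx, , drop = FALSE]
  a[is.na(a)] <- 0
  fs <- acc$sampling_rate
  bf <- signal::butter(2, 0.5 / (fs / 2), type = "high")
  hp <- apply(a, 2, function(col) signal::filtfilt(bf, col))
  mpa <- mean(sqrt(rowSums(hp^2)))
  if (mpa >= 0.1) {
    return(list(mpa = mpa, body_position = "moving"))
  }
  g <- colMeans(a)
  dominant <- which.max(abs(g))
  pos <- if (dominant == 1) "upright"
         else if (dominant == 2) "lateral"
         else if (g[3] > 0) "supine" else "prone"
  list(mpa = mpa, body_position = pos)
}

#' Assemble a vital snapshot from raw biosignal frames
#'
#' Runs the whole measurement chain for one analysis window: R-peak
#' detection and heart rate from the ECG, pulse feet and arrival times from
#' the infrared PPG for cuffless SBP, ratio-of-ratios SpO2 from the PPG
#' pair, spectral respiratory rate (over the trailing `rr_window_ms`), and
#' accelerometer activity/posture. Channels that are missing, too short or
#' masked by dropout simply yield absent signs, which downstream triage
#' handles as degraded modes (or black, for a missing heart rate).
#'
#' @param frames Named list of [biosignal_frame()]s; recognised names
#'   `ecg`, `ppg_red`, `ppg_ir`, `resp`, `acc`. Any subset may be present.
#' @param cal A [calibration_record()].
#' @param window `c(start, end)` ms, half-open, end > start.
#' @param soldier_id Id stamped on the snapshot (default: calibration's).
#' @param rr_window_ms Length of the trailing respiration window (default
#'   60 s; the respiratory band needs a longer observation than the pulse
#'   signs).
#' @return A [vital_snapshot()] timestamped at the window end.
#' @export
snapshot_from_signals <- function(frames, cal, window,
                                  soldier_id = cal$soldier_id,
                                  rr_window_ms = 60000) {
  if (length(window) != 2 || !all(is.finite(window)) || diff(window) <= 0) {
    abort("window must be half-open [start, end) with end > start",
          "fieldtriage_validation_error")
  }
  hr <- NA_real_; sbp <- NA_real_; spo2 <- NA_real_; rr <- NA_real_
  mpa <- NA_real_; pos <- NA_character_
  pad <- 1000  # detection margin (ms) around the window

  ecg_ok <- !is.null(frames$ecg) && window_usable(frames$ecg, window)
  r_peaks <- NULL
  if (ecg_ok) {
    seg <- clip_frame(frames$ecg, window[1] - pad, window[2] + pad)
    if (!is.null(seg) && frame_n(seg) / seg$sampling_rate >= 2) {
      r_peaks <- detect_r_peaks(seg)
      hr <- hr_from_beats(r_peaks, window)
    }
  }
  ir_ok <- !is.null(frames$ppg_ir) && window_usable(frames$ppg_ir, window)
  feet <- NULL
  if (ir_ok) {
    seg <- clip_frame(frames$ppg_ir, window[1] - pad, window[2] + pad)
    if (!is.null(seg)) feet <- detect_pulse_feet(seg)
  }
  if (!is.null(r_peaks) && length(r_peaks) && !is.null(feet) && length(feet)) {
    inw <- r_peaks[r_peaks >= window[1] & r_peaks < window[2]]
    sbp <- sbp_from_pat(pat_series(beat_series(inw, "ECG"), feet), cal)
  }
  if (ir_ok && !is.null(frames$ppg_red) &&
      window_usable(frames$ppg_red, window)) {
    spo2 <- spo2_from_ppg(frames$ppg_red, frames$ppg_ir, window, cal)
  }
  if (!is.null(frames$resp)) {
    rw <- c(window[2] - rr_window_ms, window[2])
    rw[1] <- max(rw[1], frames$resp$start_time)
    if (diff(rw) >= 30000 && window_usable(frames$resp, rw)) {
      rr <- rr_from_resp(frames$resp, rw)
    }
  }
  if (!is.null(frames$acc) && window_usable(frames$acc, window) &&
      diff(window) >= 2000) {
    ap <- activity_and_posture(frames$acc, window)
    mpa <- ap$mpa; pos <- ap$body_position
  }
  vital_snapshot(soldier_id, window[2], rr = rr, hr = hr, sbp = sbp,
                 spo2 = spo2, mpa = mpa, body_position = pos)
}
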