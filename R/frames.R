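BIOSIGNAL_CHANNELS <- c("ECG", "PPG_RED", "PPG_IR", "RESP", "ACC3")

#' A sampled biosignal segment
#'
#' One uniformly sampled segment of a single wearable channel. ECG, PPG
#' (red and infrared), respiration and 3-axis acceleration are supported;
#' acceleration samples are an n x 3 matrix in g-units, all other channels a
#' numeric vector. Missing samples (sensor dropout) are `NA`.
#'
#' @param channel One of `"ECG"`, `"PPG_RED"`, `"PPG_IR"`, `"RESP"`, `"ACC3"`.
#' @param sampling_rate Hz, > 0.
#' @param start_time Segment start, ms UTC.
#' @param samples Numeric vector (ACC3: n x 3 matrix).
#' @return An object of class `biosignal_frame`.
#' @export
biosignal_frame <- function(channel, sampling_rate, start_time, samples) {
  channel <- match.arg(channel, BIOSIGNAL_CHANNELS)
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    abort("sampling_rate must be > 0", "fieldtriage_input_error")
  }
  if (channel == "ACC3") {
    samples <- as.matrix(samples)
    if (ncol(samples) != 3 || nrow(samples) == 0) {
      abort("ACC3 samples must be a non-empty n x 3 matrix",
            "fieldtriage_input_error")
    }
  } else {
    samples <- as.numeric(samples)
    if (length(samples) == 0) {
      abort("samples must be non-empty", "fieldtriage_input_error")
    }
  }
  if (any(is.infinite(samples))) {
    abort("samples must be finite or NA", "fieldtriage_input_error")
  }
  structure(list(channel = channel, sampling_rate = as.numeric(sampling_rate),
                 start_time = as.numeric(start_time), samples = samples),
            class = "biosignal_frame")
}

frame_n <- function(frame) {
  if (frame$channel == "ACC3") nrow(frame$samples) else length(frame$samples)
}

#' @export
print.biosignal_frame <- function(x, ...) {
  n <- frame_n(x)
  cat(sprintf("<biosignal_frame> %s: %d samples @ %g Hz (%.1f s from %.0f ms)\n",
              x$channel, n, x$sampling_rate, n / x$sampling_rate, x$start_time))
  invisible(x)
}

# sample times in ms
frame_times <- function(frame) {
  frame$start_time + (seq_len(frame_n(frame)) - 1) * 1000 / frame$sampling_rate
}

# index range of a half-open window [t0, t1) in ms; NULL if empty
frame_window_idx <- function(frame, window) {
  t <- frame_times(frame)
  idx <- which(t >= window[1] & t < window[2])
  if (length(idx) == 0) NULL else idx
}

# TRUE when the window holds enough usable (non-NA) samples to analyse
window_usable <- function(frame, window, min_fraction = 0.8) {
  idx <- frame_window_idx(frame, window)
  if (is.null(idx)) return(FALSE)
  x <- if (frame$channel == "ACC3") frame$samples[idx, , drop = FALSE]
       else frame$samples[idx]
  mean(!is.na(x)) >= min_fraction
}

#' Per-soldier sensor calibration
#'
#' Coefficients tying the optically derived quantities to blood pressure and
#' oxygen saturation: cuffless systolic pressure from pulse arrival time via
#' the linear model SBP = a * PAT + b (a < 0: a longer arrival time means a
#' lower pressure), and saturation from the dual-wavelength ratio of ratios
#' via SpO2 = c0 - c1 * R.
#'
#' @param soldier_id Identifier.
#' @param a Slope, mmHg per ms; must be negative. Default -0.4.
#' @param b Intercept, mmHg. Default 220.
#' @param c0,c1 Saturation curve coefficients; `c1 > 0`. Defaults 110 and 25.
#' @return An object of class `calibration_record`.
#' @export
calibration_record <- function(soldier_id, a = -0.4, b = 220,
                               c0 = 110, c1 = 25) {
  if (!is_scalar_number(a) || a >= 0) {
    abort("SBP slope a must be negative (longer PAT -> lower SBP)",
          "fieldtriage_config_error")
  }
  if (!is_scalar_number(c1) || c1 <= 0) {
    abort("SpO2 coefficient c1 must be positive", "fieldtriage_config_error")
  }
  structure(list(soldier_id = soldier_id, a = a, b = b, c0 = c0, c1 = c1),
            class = "calibration_record")
}

#' Write / read a biosignal frame as CSV with a JSON sidecar header
#'
#' The on-disk format is a plain CSV of `time_ms,value` (ACC3:
#' `time_ms,x,y,z`) next to a `<path>.json` header holding channel,
#' sampling rate and start time.
#'
#' @param frame A [biosignal_frame()].
#' @param path CSV path; the header goes to `paste0(path, ".json")`.
#' @return `write_frame_csv` the path invisibly; `read_frame_csv` the frame.
#' @export
write_frame_csv <- function(frame, path) {
  t <- frame_times(frame)
  df <- if (frame$channel == "ACC3") {
    data.frame(time_ms = t, x = frame$samples[, 1], y = frame$samples[, 2],
               z = frame$samples[, 3])
  } else {
    data.frame(time_ms = t, value = frame$samples)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  header <- list(channel = frame$channel, sampling_rate = frame$sampling_rate,
                 start_time = frame$start_time)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  samples <- if (header$channel == "ACC3") as.matrix(df[, c("x", "y", "z")])
             else df$value
  biosignal_frame(header$channel, header$sampling_rate, header$start_time,
                  samples)
}
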