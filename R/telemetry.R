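MESSAGE_TYPES <- c("vitals", "biosignal_chunk", "triage", "request", "ack")

# CRC-16/CCITT-FALSE: poly 0x1021, init 0xFFFF, no reflection, xorout 0.
# Table-driven, computed once at load.
crc16_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    crc <- bitwShiftL(i, 8)
    for (j in 1:8) {
      crc <- if (bitwAnd(crc, 0x8000L) != 0L) {
        bitwXor(bitwShiftL(crc, 1), 0x1021L)
      } else {
        bitwShiftL(crc, 1)
      }
      crc <- bitwAnd(crc, 0xFFFFL)
    }
    tab[i + 1] <- crc
  }
  tab
})

#' CRC-16/CCITT-FALSE checksum
#' @param bytes Raw vector.
#' @return Integer in \[0, 65535\].
#' @export
crc16 <- function(bytes) {
  crc <- 0xFFFFL
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(bitwShiftR(crc, 8), b), 0xFFL)
    crc <- bitwAnd(bitwXor(bitwShiftL(crc, 8), crc16_table[idx + 1]), 0xFFFFL)
  }
  crc
}

int_to_bytes <- function(x, n) {
  as.raw(rev(vapply(seq_len(n) - 1L,
                    function(i) bitwAnd(bitwShiftR(as.integer(x), 8L * i), 0xFFL),
                    integer(1))))
}

bytes_to_int <- function(b) {
  out <- 0
  for (x in as.integer(b)) out <- out * 256 + x
  out
}

SYNC_MARKER <- as.raw(c(0xAA, 0x55))
MDTP_VERSION <- 1L

#' Telemetry message
#'
#' A single unit of the sensor-hub-to-terminal protocol: typed, sequenced
#' per soldier (16-bit wrapping counter) and carrying an arbitrary payload
#' (structured payloads are serialised as JSON bytes).
#'
#' @param type One of `"vitals"`, `"biosignal_chunk"`, `"triage"`,
#'   `"request"`, `"ack"`.
#' @param soldier_id Identifier (<= 255 bytes UTF-8).
#' @param seq Sequence number in \[0, 65535\].
#' @param payload Raw vector, character string, or a list (JSON-encoded).
#' @return An `mdtp_message`.
#' @export
mdtp_message <- function(type, soldier_id, seq, payload = raw(0)) {
  type <- match.arg(type, MESSAGE_TYPES)
  if (seq < 0 || seq > 65535) {
    abort("sequence number must fit 16 bits", "fieldtriage_framing_error")
  }
  if (is.list(payload)) {
    payload <- charToRaw(as.character(
      jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")))
  } else if (is.character(payload)) {
    payload <- charToRaw(payload)
  }
  if (length(payload) > 65535) {
    abort("payload exceeds 65535 bytes", "fieldtriage_framing_error")
  }
  structure(list(type = type, soldier_id = as.character(soldier_id),
                 seq = as.integer(seq), payload = payload),
            class = "mdtp_message")
}

#' Encode / decode a framed telemetry message
#'
#' Wire format: sync `0xAA 0x55`, version, message type, 16-bit sequence
#' number, length-prefixed soldier id, 16-bit payload length, payload, and a
#' CRC-16/CCITT-FALSE over everything after the sync marker. All integers
#' big-endian. `decode_frame(encode_frame(m))` is the identity; truncation
#' raises a framing error and any corruption a CRC integrity error.
#'
#' @param message An [mdtp_message()].
#' @return `encode_frame`: a raw vector. `decode_frame`: the message.
#' @export
encode_frame <- function(message) {
  stopifnot(inherits(message, "mdtp_message"))
  id <- charToRaw(message$soldier_id)
  if (length(id) > 255) {
    abort("soldier id exceeds 255 bytes", "fieldtriage_framing_error")
  }
  body <- c(as.raw(MDTP_VERSION),
            as.raw(match(message$type, MESSAGE_TYPES)),
            int_to_bytes(message$seq, 2),
            as.raw(length(id)), id,
            int_to_bytes(length(message$payload), 2),
            message$payload)
  c(SYNC_MARKER, body, int_to_bytes(crc16(body), 2))
}

#' @rdname encode_frame
#' @param bytes Raw vector holding exactly one encoded frame.
#' @export
decode_frame <- function(bytes) {
  if (length(bytes) < 11) {
    abort("buffer too short for a frame", "fieldtriage_framing_error")
  }
  if (!identical(bytes[1:2], SYNC_MARKER)) {
    abort("missing sync marker", "fieldtriage_framing_error")
  }
  id_len <- as.integer(bytes[7])
  pl_off <- 8 + id_len
  if (length(bytes) < pl_off + 1) {
    abort("truncated frame header", "fieldtriage_framing_error")
  }
  pl_len <- bytes_to_int(bytes[pl_off:(pl_off + 1)])
  total <- pl_off + 1 + pl_len + 2
  if (length(bytes) != total) {
    abort("frame length does not match payload length field",
          "fieldtriage_framing_error")
  }
  body <- bytes[3:(total - 2)]
  if (crc16(body) != bytes_to_int(bytes[(total - 1):total])) {
    abort("CRC mismatch: frame corrupted", "fieldtriage_integrity_error")
  }
  type_code <- as.integer(bytes[4])
  if (type_code < 1 || type_code > length(MESSAGE_TYPES)) {
    abort("unknown message type", "fieldtriage_framing_error")
  }
  payload <- if (pl_len > 0) bytes[(pl_off + 2):(pl_off + 1 + pl_len)] else raw(0)
  mdtp_message(MESSAGE_TYPES[type_code],
               rawToChar(bytes[8:(7 + id_len)]),
               bytes_to_int(bytes[5:6]),
               payload)
}

#' Decode a JSON payload back into a list
#' @param message An [mdtp_message()] whose payload holds JSON bytes.
#' @return The decoded list.
#' @export
payload_as_list <- function(message) {
  jsonlite::fromJSON(rawToChar(message$payload), simplifyVector = TRUE)
}

snapshot_payload <- function(snap) {
  list(soldier_id = snap$soldier_id, timestamp = snap$timestamp,
       rr = snap$rr, hr = snap$hr, sbp = snap$sbp, spo2 = snap$spo2,
       mpa = snap$mpa, body_position = snap$body_position)
}

#' Periodic snapshot streaming with a loss model
#'
#' Emits one framed vitals message per reporting period from a generated
#' stream (or a pre-computed snapshot list), then drops frames according to
#' a seeded Bernoulli loss model — the in-process stand-in for battlefield
#' link loss and jamming.
#'
#' @param stream A [generate_scenario()] result, or a list of
#'   [vital_snapshot()]s.
#' @param period_s Reporting period in seconds (> 0).
#' @param loss_prob Probability each frame is lost in transit.
#' @param loss_seed Seed for the loss pattern.
#' @return List with `sent` (all encoded frames, raw vectors), `received`
#'   (surviving frames), `period_s` and the send timestamps.
#' @export
stream_snapshots <- function(stream, period_s = 10, loss_prob = 0,
                             loss_seed = 1) {
  if (period_s <= 0) abort("period must be > 0", "fieldtriage_validation_error")
  snaps <- if (inherits(stream, "generated_stream")) {
    stream_to_snapshots(stream, period_s = period_s)
  } else {
    stream
  }
  frames <- mapply(function(s, i) {
    encode_frame(mdtp_message("vitals", s$soldier_id, (i - 1) %% 65536,
                              snapshot_payload(s)))
  }, snaps, seq_along(snaps), SIMPLIFY = FALSE)
  set.seed(loss_seed)
  lost <- stats::runif(length(frames)) < loss_prob
  list(sent = frames, received = frames[!lost], period_s = period_s,
       timestamps = vapply(snaps, `[[`, numeric(1), "timestamp"))
}

#' Receiver-side silence watchdog
#'
#' Decodes received frames and reconstructs the soldier's status timeline.
#' If no frame arrives for more than `timeout_periods` reporting periods —
#' link loss, jamming, sensor destruction — the receiver tags the soldier
#' black (needs on-scene confirmation), exactly as when the heart-rate
#' signal is absent.
#'
#' @param received List of encoded frames (raw vectors).
#' @param horizon_ms Time (ms) up to which silence is evaluated.
#' @param period_s Nominal reporting period (s).
#' @param timeout_periods Missed periods tolerated before black (default 3).
#' @param profile [reference_profile()] used to re-triage decoded snapshots.
#' @return List with `snapshots`, `decisions` (one per received frame) and
#'   `silence_decision` (`NULL`, or the black [triage_decision()] raised at
#'   `horizon_ms`).
#' @export
receive_stream <- function(received, horizon_ms, period_s = 10,
                           timeout_periods = 3,
                           profile = default_reference_profile()) {
  msgs <- lapply(received, decode_frame)
  snaps <- lapply(msgs, function(m) {
    p <- payload_as_list(m)
    vital_snapshot(p$soldier_id, p$timestamp,
                   rr = p$rr %||% NA, hr = p$hr %||% NA, sbp = p$sbp %||% NA,
                   spo2 = p$spo2 %||% NA, mpa = p$mpa %||% NA,
                   body_position = p$body_position %||% NA)
  })
  decisions <- lapply(snaps, function(s) {
    prof <- profile; prof$soldier_id <- s$soldier_id
    triage(s, prof)
  })
  last_seen <- if (length(snaps)) max(vapply(snaps, `[[`, numeric(1),
                                             "timestamp")) else -Inf
  silence <- NULL
  if (horizon_ms - last_seen > timeout_periods * period_s * 1000) {
    sid <- if (length(snaps)) snaps[[length(snaps)]]$soldier_id else "unknown"
    silence <- triage_decision(sid, horizon_ms, "black",
                               needs_confirmation = TRUE)
  }
  list(snapshots = snaps, decisions = decisions, silence_decision = silence)
}
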