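#' Write a recording to EDF
#'
#' Minimal European Data Format writer for synthetic PSG: all channels share
#' one sampling rate, samples are scaled to 16-bit integers over the
#' per-channel physical range, data records are one second long, physical
#' units are microvolts. Sufficient for round-tripping the recordings this
#' package generates; no annotations (EDF+) are written.
#'
#' @param rec a [psg_recording()].
#' @param path output file path.
#' @param patient,recording_id header identification strings.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "synthetic") {
  stopifnot(inherits(rec, "psg_recording"))
  rate <- rec$rate
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate")
  ns <- length(rec$signals)
  spr <- as.integer(rate)                 # samples per record (1 s records)
  n_rec <- floor(rec$n_samples / spr)
  if (n_rec < 1) stop("recording shorter than one data record")
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  phys_min <- vapply(rec$signals, function(x) floor(min(x, -1)), numeric(1))
  phys_max <- vapply(rec$signals, function(x) ceiling(max(x, 1)), numeric(1))
  hdr <- paste0(
    pad("0", 8), pad(patient, 80), pad(recording_id, 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + 256 * ns, 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste0(vapply(vals, pad, "", w = w),
                                              collapse = ""), con, eos = NULL)
  field(names(rec$signals), 16)                      # label
  field(rep("", ns), 80)                             # transducer
  field(rep("uV", ns), 8)                            # physical dimension
  field(phys_min, 8)
  field(phys_max, 8)
  field(rep(-32768, ns), 8)                          # digital min
  field(rep(32767, ns), 8)                           # digital max
  field(rep("", ns), 80)                             # prefiltering
  field(rep(spr, ns), 8)                             # samples per record
  field(rep("", ns), 32)                             # reserved
  gain <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    s0 <- (r - 1L) * spr
    for (k in seq_len(ns)) {
      x <- rec$signals[[k]][(s0 + 1):(s0 + spr)]
      d <- round((x - phys_min[k]) / gain[k]) - 32768
      writeBin(as.integer(pmax(-32768, pmin(32767, d))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return a [psg_recording()] in physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8)                        # version
  readChar(con, 160)                      # patient + recording id
  readChar(con, 16)                       # dates
  readChar(con, 8)                        # header bytes
  readChar(con, 44)                       # reserved
  n_rec <- as.integer(readChar(con, 8))
  dur <- as.numeric(readChar(con, 8))
  ns <- as.integer(readChar(con, 4))
  grab <- function(w) vapply(seq_len(ns), function(i) trimws(readChar(con, w)), "")
  labels <- grab(16)
  grab(80); grab(8)
  phys_min <- as.numeric(grab(8))
  phys_max <- as.numeric(grab(8))
  dig_min <- as.numeric(grab(8))
  dig_max <- as.numeric(grab(8))
  grab(80)
  spr <- as.integer(grab(8))
  grab(32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- lapply(seq_len(ns), function(k) numeric(n_rec * spr[k]))
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[k], size = 2, endian = "little",
                   signed = TRUE)
      sig[[k]][((r - 1) * spr[k] + 1):(r * spr[k])] <-
        (d - dig_min[k]) * gain[k] + phys_min[k]
    }
  }
  names(sig) <- labels
  psg_recording(sig, rate = spr[1] / dur)
}
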