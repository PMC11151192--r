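#' Multichannel PSG recording container
#'
#' A light container for a polysomnography recording: a named list of equal
#' length numeric channel vectors (physical units microvolts) and a sampling
#' rate.
#'
#' @param signals named list of numeric vectors, one per channel.
#' @param rate sampling rate in Hz.
#' @return object of class `psg_recording`.
#' @export
psg_recording <- function(signals, rate) {
  stopifnot(is.list(signals), length(signals) > 0L,
            !is.null(names(signals)), rate > 0)
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1L) stop("all channels must have the same length")
  structure(list(signals = signals, rate = rate, n_samples = n),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", length(x$signals), " channel(s) x ",
      x$n_samples, " samples @ ", x$rate, " Hz (",
      round(x$n_samples / x$rate / 60, 1), " min)\n", sep = "")
  cat("channels:", paste(names(x$signals), collapse = ", "), "\n")
  invisible(x)
}

#' Design a zero-phase FIR filter kernel
#'
#' Returns an odd-length linear-phase FIR kernel. `"hamming"` designs a
#' Hamming windowed sinc whose -6 dB points sit at the band edges;
#' `"remez"` designs an equiripple (Parks-McClellan / Chebyshev) filter with
#' the band edges at the passband corners. The kernel length follows from
#' the transition bandwidth (`3.3 * rate / trans` taps for the Hamming
#' window).
#'
#' @param rate sampling rate in Hz.
#' @param lo,hi band edges in Hz; use `lo = 0` for a low-pass and
#'   `hi = Inf`/`NULL` for a high-pass.
#' @param trans transition bandwidth in Hz.
#' @param type `"hamming"` or `"remez"`.
#' @param ripple passband/stopband ripple for the equiripple design.
#' @param max_taps upper bound on the kernel length.
#' @return numeric kernel (odd length, symmetric).
#' @export
design_fir <- function(rate, lo, hi, trans = 0.2,
                       type = c("hamming", "remez"), ripple = 0.01,
                       max_taps = 2^15) {
  type <- match.arg(type)
  nyq <- rate / 2
  if (is.null(hi)) hi <- Inf
  if (lo < 0 || (is.finite(hi) && hi >= nyq) || (is.finite(hi) && lo >= hi))
    stop("band edges must satisfy 0 <= lo < hi < Nyquist")
  n <- ceiling(3.3 * rate / trans)
  n <- min(n, max_taps)
  if (n %% 2 == 1) n <- n + 1  # even order -> odd length
  if (type == "hamming") {
    if (lo <= 0) {
      h <- signal::fir1(n, hi / nyq, type = "low")
    } else if (!is.finite(hi)) {
      h <- signal::fir1(n, lo / nyq, type = "high")
    } else {
      h <- signal::fir1(n, c(lo, hi) / nyq, type = "pass")
    }
  } else {
    # equiripple; band edges widened by half the transition width so that the
    # passband corners sit at lo/hi
    n <- min(n, 1000L)
    if (n %% 2 == 1) n <- n + 1
    f <- c(0, max(lo - trans, 0.01), lo, hi, min(hi + trans, nyq - 0.01), nyq) / nyq
    a <- c(0, 0, 1, 1, 0, 0)
    h <- tryCatch(signal::remez(n, f, a),
                  error = function(e) {
                    # fall back to the windowed-sinc design if the exchange
                    # algorithm fails to converge at this order
                    signal::fir1(n, c(lo, hi) / nyq, type = "pass")
                  })
  }
  as.numeric(h)
}

#' Apply a linear-phase FIR filter with zero group delay
#'
#' Single forward pass with a symmetric odd-length kernel, delay-compensated
#' (centred convolution with reflection padding), so the output has zero
#' phase shift and the magnitude response of the kernel itself.
#'
#' @param x numeric signal.
#' @param h odd-length symmetric FIR kernel from [design_fir()].
#' @return filtered signal, same length as `x`.
#' @export
fir_zerophase <- function(x, h) {
  fft_filter_same(x, h)
}

#' Broadband band-pass filtering of EEG
#'
#' Zero-phase Hamming windowed-sinc FIR band-pass with -6 dB points at the
#' band edges (default 0.2-35 Hz) and transition bands of `trans` Hz, so the
#' stop edges sit at `lo - trans/2` and `hi + trans/2`.
#'
#' @param x numeric signal (microvolts).
#' @param rate sampling rate in Hz; must exceed `2 * hi`.
#' @param lo,hi -6 dB band edges in Hz.
#' @param trans transition bandwidth in Hz.
#' @return filtered signal.
#' @export
bandpass_eeg <- function(x, rate, lo = 0.2, hi = 35, trans = 0.2) {
  if (rate <= 2 * hi) stop("sampling rate must exceed twice the upper edge")
  fir_zerophase(x, design_fir(rate, lo, hi, trans = trans))
}

#' Low-pass filtering of EEG
#'
#' Zero-phase FIR low-pass (default cutoff 3.5 Hz) used ahead of
#' slow-oscillation detection.
#'
#' @inheritParams bandpass_eeg
#' @param hi cutoff (-6 dB) in Hz.
#' @export
lowpass_eeg <- function(x, rate, hi = 3.5, trans = 1) {
  fir_zerophase(x, design_fir(rate, 0, hi, trans = trans))
}

#' Re-reference EEG channels to the mastoid average
#'
#' Subtracts the average of the two mastoid channels from every EEG channel;
#' the mastoid channels themselves are left untouched.
#'
#' @param rec a [psg_recording()].
#' @param mastoids names of the two mastoid channels.
#' @return re-referenced `psg_recording`.
#' @export
rereference_mastoids <- function(rec, mastoids = c("A1", "A2")) {
  stopifnot(inherits(rec, "psg_recording"))
  if (!all(mastoids %in% names(rec$signals)))
    stop("mastoid channel(s) missing: ",
         paste(setdiff(mastoids, names(rec$signals)), collapse = ", "))
  ref <- (rec$signals[[mastoids[1]]] + rec$signals[[mastoids[2]]]) / 2
  for (ch in setdiff(names(rec$signals), mastoids)) {
    rec$signals[[ch]] <- rec$signals[[ch]] - ref
  }
  rec
}

#' Select clean stage epochs for one target channel
#'
#' Keeps the epochs of the requested stage whose overlap with artifact
#' annotations is at most `max_artifact_s` seconds (the threshold is
#' exclusive: exactly 8 s is kept) and whose target-channel impedance does
#' not exceed `max_impedance_kohm`. Epochs that are not fully covered by the
#' recording are dropped. Exclusion reasons are logged.
#'
#' @param hyp a [hypnogram()] aligned with the recording.
#' @param stage target stage label.
#' @param channel target channel name (impedance is looked up per channel).
#' @param rate sampling rate in Hz.
#' @param n_samples recording length in samples (defaults to the full
#'   hypnogram span).
#' @param impedance optional data frame with columns `channel` and `kohm`
#'   (one per-recording value per channel).
#' @param max_artifact_s maximal tolerated artifact overlap per epoch.
#' @param max_impedance_kohm maximal tolerated contact impedance.
#' @return object of class `epoch_set`: the kept epoch indices (1-based),
#'   stage, channel, timing fields and an `exclusions` data frame.
#' @export
select_clean_epochs <- function(hyp, stage, channel, rate,
                                n_samples = NULL, impedance = NULL,
                                max_artifact_s = 8,
                                max_impedance_kohm = 30) {
  stopifnot(inherits(hyp, "hypnogram"))
  el <- hyp$epoch_length
  if (is.null(n_samples)) n_samples <- length(hyp$stages) * el * rate
  idx <- which(hyp$stages == stage)
  excl <- data.frame(epoch = integer(0), reason = character(0))
  drop <- function(epochs, reason) {
    if (length(epochs) > 0)
      excl <<- rbind(excl, data.frame(epoch = epochs, reason = reason))
  }
  # channel impedance applies to the whole recording
  if (!is.null(impedance)) {
    z <- impedance$kohm[match(channel, impedance$channel)]
    if (!is.na(z) && z > max_impedance_kohm) {
      drop(idx, sprintf("impedance %.1f kOhm > %g", z, max_impedance_kohm))
      idx <- integer(0)
    }
  }
  if (length(idx) > 0) {
    full <- idx * el * rate <= n_samples
    drop(idx[!full], "epoch extends beyond recording")
    idx <- idx[full]
  }
  if (length(idx) > 0 && nrow(hyp$artifacts) > 0) {
    ov <- vapply(idx, function(e)
      interval_overlap((e - 1) * el, e * el,
                       hyp$artifacts$onset_s, hyp$artifacts$duration_s),
      numeric(1))
    bad <- ov > max_artifact_s
    drop(idx[bad], sprintf("artifact overlap > %g s", max_artifact_s))
    idx <- idx[!bad]
  }
  structure(list(stage = stage, channel = channel, epochs = idx,
                 epoch_length = el, rate = rate,
                 n_kept = length(idx), exclusions = excl),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> stage ", x$stage, ", channel ", x$channel, ": ",
      x$n_kept, " epochs kept, ", nrow(x$exclusions), " excluded\n", sep = "")
  invisible(x)
}

#' Sample index mask of an epoch set
#'
#' Logical vector over the recording marking samples that belong to the kept
#' epochs.
#'
#' @param es an `epoch_set`.
#' @param n_samples recording length in samples.
#' @return logical vector of length `n_samples`.
#' @export
epoch_mask <- function(es, n_samples) {
  spe <- es$epoch_length * es$rate
  m <- logical(n_samples)
  for (e in es$epochs) {
    m[((e - 1) * spe + 1):min(e * spe, n_samples)] <- TRUE
  }
  m
}

#' Extract epoch slices as a samples-by-epochs matrix
#'
#' @param x numeric channel vector.
#' @param es an `epoch_set`.
#' @return matrix with one column per kept epoch.
#' @export
epoch_matrix <- function(x, es) {
  spe <- as.integer(es$epoch_length * es$rate)
  cols <- lapply(es$epochs, function(e) x[((e - 1) * spe + 1):(e * spe)])
  do.call(cbind, cols)
}
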