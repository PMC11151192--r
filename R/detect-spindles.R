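#' Individual sigma peak frequency
#'
#' Finds the participant's fast-spindle frequency as the highest-frequency
#' qualifying local maximum of the detrended power spectral density curve
#' within the sigma range (default 9-16 Hz). The curve is detrended by
#' subtracting a least-squares line over the sigma range; local maxima must
#' exceed a prominence threshold (height above the higher of the two
#' flanking minima) expressed as a fraction of the detrended curve's range.
#' When two peaks qualify, the higher-frequency one is selected.
#'
#' @param freq,psd the PSD curve (must cover the sigma range).
#' @param range sigma range in Hz.
#' @param prominence_frac minimal prominence as a fraction of the detrended
#'   range.
#' @return object of class `sigma_peak`: `peak_hz` and the detection band
#'   `band_hz` (peak +/- 2 Hz, clipped to positive frequencies).
#' @export
individual_sigma_peak <- function(freq, psd, range = c(9, 16),
                                  prominence_frac = 0.1) {
  sel <- freq >= range[1] & freq <= range[2]
  if (sum(sel) < 5) stop("PSD curve must cover the sigma range")
  f <- freq[sel]; p <- psd[sel]
  d <- stats::residuals(stats::lm(p ~ f))
  n <- length(d)
  locmax <- which(diff(sign(diff(d))) == -2) + 1L
  if (length(locmax) == 0)
    stop_no_peak()
  prom <- vapply(locmax, function(i) {
    left <- if (i > 1) min(d[1:i]) else d[i]
    right <- if (i < n) min(d[i:n]) else d[i]
    d[i] - max(left, right)
  }, numeric(1))
  keep <- locmax[prom >= prominence_frac * diff(range(d))]
  if (length(keep) == 0) stop_no_peak()
  peak <- f[max(keep)]  # highest-frequency qualifying peak
  structure(list(peak_hz = peak,
                 band_hz = c(max(peak - 2, 0.1), peak + 2)),
            class = "sigma_peak")
}

stop_no_peak <- function() {
  stop(structure(class = c("somnaffect_no_sigma_peak", "error", "condition"),
                 list(message = paste0(
                   "no qualifying sigma peak; consider falling back to the ",
                   "cohort mean fast-spindle frequency (13.47 Hz)"),
                   call = NULL)))
}

#' Fall back to the cohort mean sigma peak
#'
#' Convenience wrapper around [individual_sigma_peak()] that substitutes
#' the cohort mean fast-spindle frequency (13.47 Hz) when no individual
#' peak qualifies.
#'
#' @inheritParams individual_sigma_peak
#' @param fallback_hz frequency used when no peak is found.
#' @export
sigma_peak_or_default <- function(freq, psd, range = c(9, 16),
                                  fallback_hz = 13.47) {
  tryCatch(individual_sigma_peak(freq, psd, range),
           somnaffect_no_sigma_peak = function(e)
             structure(list(peak_hz = fallback_hz,
                            band_hz = c(fallback_hz - 2, fallback_hz + 2)),
                       class = "sigma_peak"))
}

# runs of TRUE in a logical vector as (start, end) sample indices
logical_runs <- function(m) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect fast sleep spindles
#'
#' Amplitude-threshold detection on the sigma-band-filtered signal,
#' restricted to the clean epochs of one stage and channel. The signal is
#' band-pass filtered to the individual detection band (peak +/- 2 Hz,
#' equiripple FIR), rectified and smoothed with a 100-ms moving average.
#' With M the mean of this envelope over all analyzed epochs: an event is a
#' contiguous segment with envelope >= 2M whose peak reaches >= 5M and which
#' extends at least 250 ms on both sides of the peak; segments closer than
#' 250 ms are merged before the length test; events longer than 3 s are
#' rejected, and events overlapping artifact annotations are discarded.
#' Thresholds are relative to the channel's own amplitude, so detections
#' are invariant to rescaling the signal.
#'
#' @param x channel signal (microvolts, full recording timeline).
#' @param es an `epoch_set` of clean epochs for one stage/channel.
#' @param band a `sigma_peak` (or 2-vector of band edges in Hz).
#' @param artifacts data frame of artifact intervals (`onset_s`,
#'   `duration_s`) whose overlap discards events.
#' @param smooth_ms envelope moving-average length (ms).
#' @param peak_mult,dwell_mult peak and dwell threshold multipliers of M.
#' @param dwell_s minimal extent on each side of the peak (s).
#' @param max_dur_s maximal event duration (s).
#' @param filter_type FIR design passed to [design_fir()].
#' @return data frame of events: `onset_s`, `duration_s`, `peak_time_s`,
#'   `peak_uv` (envelope peak), `stage`, `channel`.
#' @export
detect_spindles <- function(x, es, band, artifacts = NULL,
                            smooth_ms = 100, peak_mult = 5, dwell_mult = 2,
                            dwell_s = 0.25, max_dur_s = 3.0,
                            filter_type = "remez") {
  rate <- es$rate
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_time_s = numeric(0), peak_uv = numeric(0),
                      stage = character(0), channel = character(0))
  if (length(es$epochs) == 0) return(empty)
  edges <- if (inherits(band, "sigma_peak")) band$band_hz else band
  h <- design_fir(rate, edges[1], edges[2], trans = 1, type = filter_type)
  k <- max(1L, round(smooth_ms / 1000 * rate))
  # filter within contiguous runs of kept epochs (cheap on long nights;
  # the epoch mask would break candidate segments at run edges anyway)
  runs <- epoch_runs(es$epochs)
  spe <- as.integer(es$epoch_length * rate)
  env <- numeric(length(x))
  for (r in seq_len(nrow(runs))) {
    i0 <- (runs[r, 1] - 1L) * spe + 1L
    i1 <- min(runs[r, 2] * spe, length(x))
    env[i0:i1] <- running_mean(abs(fir_zerophase(x[i0:i1], h)), k)
  }
  mask <- epoch_mask(es, length(x))
  M <- mean(env[mask])
  if (!is.finite(M) || M <= 0) return(empty)
  events <- scan_envelope_events(env, mask, rate, M,
                                 peak_mult, dwell_mult, dwell_s, max_dur_s)
  if (nrow(events) == 0) return(empty)
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    keep <- vapply(seq_len(nrow(events)), function(i)
      interval_overlap(events$onset_s[i],
                       events$onset_s[i] + events$duration_s[i],
                       artifacts$onset_s, artifacts$duration_s) == 0,
      logical(1))
    events <- events[keep, , drop = FALSE]
  }
  if (nrow(events) == 0) return(empty)
  events$stage <- es$stage
  events$channel <- es$channel
  rownames(events) <- NULL
  events
}

# sigma-band rectified + smoothed amplitude envelope over a whole signal
spindle_envelope <- function(x, rate, edges, smooth_ms = 100,
                             filter_type = "remez") {
  h <- design_fir(rate, edges[1], edges[2], trans = 1, type = filter_type)
  k <- max(1L, round(smooth_ms / 1000 * rate))
  running_mean(abs(fir_zerophase(x, h)), k)
}

# core threshold scan shared with nothing else; operates on the envelope
scan_envelope_events <- function(env, mask, rate, M, peak_mult, dwell_mult,
                                 dwell_s, max_dur_s) {
  above <- env >= dwell_mult * M & mask
  runs <- logical_runs(above)
  out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                    peak_time_s = numeric(0), peak_uv = numeric(0))
  if (nrow(runs) == 0) return(out)
  # merge candidate runs separated by less than the dwell requirement
  gap <- round(dwell_s * rate)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs[i, "start"] - merged[nrow(merged), "end"] - 1L < gap) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  need <- round(dwell_s * rate)
  for (i in seq_len(nrow(merged))) {
    s <- merged[i, "start"]; e <- merged[i, "end"]
    seg <- env[s:e]
    pk <- which.max(seg)
    if (seg[pk] < peak_mult * M) next
    if (pk - 1L < need || (e - s + 1L) - pk < need) next
    dur <- (e - s + 1L) / rate
    if (dur > max_dur_s) next
    out <- rbind(out, data.frame(onset_s = (s - 1) / rate,
                                 duration_s = dur,
                                 peak_time_s = (s - 1 + pk - 1) / rate,
                                 peak_uv = seg[pk]))
  }
  out
}

#' Spindle density
#'
#' Events per minute of the analyzed stage.
#'
#' @param events event data frame (or an event count).
#' @param stage_minutes minutes spent in the stage (> 0).
#' @return events/min.
#' @export
spindle_density <- function(events, stage_minutes) {
  if (stage_minutes <= 0) stop("stage duration must be positive")
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / stage_minutes
}
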