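#' Detect slow oscillations
#'
#' Zero-crossing detection on the low-pass (3.5 Hz) filtered signal,
#' restricted to the clean epochs of one stage/channel. Candidate cycles are
#' the segments between consecutive positive-to-negative zero-crossings with
#' length 0.8-5 s (0.2-1.25 Hz) lying inside kept epochs; cycles
#' overlapping artifact annotations are discarded before thresholding. Over
#' the candidate set, the mean negative peak and mean positive-to-negative
#' (peak-to-peak) amplitude difference are computed per channel and stage; a
#' cycle is a slow oscillation when its negative peak is lower than 0.9
#' times the mean negative peak and its amplitude difference exceeds 0.9
#' times the mean difference. Thresholds are relative, so detections are
#' invariant to rescaling the signal.
#'
#' @param x channel signal (microvolts, full recording timeline).
#' @param es an `epoch_set` of clean epochs for one stage/channel.
#' @param artifacts data frame of artifact intervals (`onset_s`,
#'   `duration_s`).
#' @param lowpass_hz low-pass cutoff (Hz).
#' @param cycle_range admissible zero-crossing interval (s).
#' @param neg_mult,p2p_mult threshold multipliers of the candidate means.
#' @return data frame of events: `start_s`, `end_s` (half-open cycle
#'   interval), `neg_peak_uv`, `neg_peak_time_s`, `pos_peak_uv`,
#'   `pos_peak_time_s`, `p2p_uv`, `stage`, `channel`.
#' @export
detect_slow_oscillations <- function(x, es, artifacts = NULL,
                                     lowpass_hz = 3.5,
                                     cycle_range = c(0.8, 5),
                                     neg_mult = 0.9, p2p_mult = 0.9) {
  rate <- es$rate
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      neg_peak_uv = numeric(0), neg_peak_time_s = numeric(0),
                      pos_peak_uv = numeric(0), pos_peak_time_s = numeric(0),
                      p2p_uv = numeric(0), stage = character(0),
                      channel = character(0))
  if (length(es$epochs) == 0) return(empty)
  h <- design_fir(rate, 0, lowpass_hz, trans = 1)
  mask <- epoch_mask(es, length(x))
  runs <- epoch_runs(es$epochs)
  spe <- as.integer(es$epoch_length * rate)
  cand <- list()
  for (r in seq_len(nrow(runs))) {
    r0 <- (runs[r, 1] - 1L) * spe + 1L
    r1 <- min(runs[r, 2] * spe, length(x))
    # filter within the contiguous run of kept epochs
    xf <- fir_zerophase(x[r0:r1], h)
    # positive-to-negative zero-crossings: sign goes + -> <= 0
    pn <- which(xf[-length(xf)] > 0 & xf[-1] <= 0)
    if (length(pn) < 2) next
    for (i in seq_len(length(pn) - 1L)) {
      s <- pn[i] + 1L; e <- pn[i + 1L]
      len <- (e - s + 1L) / rate
      if (len < cycle_range[1] || len > cycle_range[2]) next
      if (!all(mask[(r0 - 1L) + (s:e)])) next
      seg <- xf[s:e]
      ineg <- which.min(seg); ipos <- which.max(seg)
      if (seg[ineg] >= 0 || seg[ipos] <= 0) next
      start_s <- (r0 - 1L + s - 1L) / rate
      end_s <- (r0 - 1L + e) / rate
      if (!is.null(artifacts) && nrow(artifacts) > 0 &&
          interval_overlap(start_s, end_s, artifacts$onset_s,
                           artifacts$duration_s) > 0) next
      cand[[length(cand) + 1L]] <- data.frame(
        start_s = start_s, end_s = end_s,
        neg_peak_uv = seg[ineg],
        neg_peak_time_s = start_s + (ineg - 1) / rate,
        pos_peak_uv = seg[ipos],
        pos_peak_time_s = start_s + (ipos - 1) / rate,
        p2p_uv = seg[ipos] - seg[ineg])
    }
  }
  if (length(cand) == 0) return(empty)
  cc <- do.call(rbind, cand)
  mean_neg <- mean(cc$neg_peak_uv)
  mean_p2p <- mean(cc$p2p_uv)
  keep <- cc$neg_peak_uv < neg_mult * mean_neg & cc$p2p_uv > p2p_mult * mean_p2p
  out <- cc[keep, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$stage <- es$stage
  out$channel <- es$channel
  rownames(out) <- NULL
  out
}
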