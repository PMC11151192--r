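#' Identify SO-coupled spindles
#'
#' A spindle is coupled when its amplitude peak time lies inside some
#' slow-oscillation cycle interval `[start_s, end_s)` (half-open: a peak
#' exactly at a cycle start is coupled, exactly at its end is not).
#'
#' @param spindles spindle events from [detect_spindles()] (needs
#'   `peak_time_s`).
#' @param sos slow-oscillation events from [detect_slow_oscillations()]
#'   (needs `start_s`, `end_s`), from the same channel/stage.
#' @return the coupled subset of `spindles`, with a `so_index` column
#'   giving the row of the enclosing cycle.
#' @export
couple_events <- function(spindles, sos) {
  if (nrow(spindles) == 0 || is.null(sos) || nrow(sos) == 0) {
    out <- spindles[integer(0), , drop = FALSE]
    out$so_index <- integer(0)
    return(out)
  }
  hit <- vapply(spindles$peak_time_s, function(t) {
    i <- which(sos$start_s <= t & t < sos$end_s)
    if (length(i) == 0) NA_integer_ else i[1]
  }, integer(1))
  out <- spindles[!is.na(hit), , drop = FALSE]
  out$so_index <- hit[!is.na(hit)]
  rownames(out) <- NULL
  out
}

#' Slow-oscillation phase at spindle peaks
#'
#' Band-pass filters the signal to the slow-oscillation band (0.2-1.25 Hz),
#' takes the Hilbert analytic representation, and samples the instantaneous
#' phase at each spindle peak time. Phase convention: 0 rad at the filtered
#' wave's positive peak, +/-pi at the trough, increasing with time (a peak a
#' quarter cycle after the wave's maximum has phase +pi/2).
#'
#' @param x channel signal covering all peak times.
#' @param rate sampling rate in Hz.
#' @param peak_times spindle peak times in seconds.
#' @param band slow-oscillation band edges in Hz.
#' @return phases in (-pi, pi], one per peak.
#' @export
so_phase_at_peaks <- function(x, rate, peak_times, band = c(0.2, 1.25)) {
  if (length(peak_times) == 0) return(numeric(0))
  idx <- round(peak_times * rate) + 1L
  if (any(idx < 1 | idx > length(x)))
    stop("spindle peak time outside the signal")
  xf <- fir_zerophase(x, design_fir(rate, band[1], band[2], trans = 0.2))
  ph <- Arg(analytic_signal(xf))
  wrap_pi(ph[idx])
}

#' Circular coupling summary
#'
#' Circular mean phase (argument of the mean resultant vector), resultant
#' vector length (its modulus) and the number of optimally coupled (OC)
#' spindles: coupled spindles whose phase lies within 0.5 rad (inclusive,
#' shorter-arc distance) of the individual mean phase. With no coupled
#' spindles the counts are zero and the mean phase/RVL are flagged missing
#' rather than raising an error, so cohort tables stay rectangular.
#'
#' @param phases phases of the coupled spindles, radians in (-pi, pi].
#' @param n_spindles total spindle count (>= number of phases).
#' @param oc_window OC half-window in radians.
#' @return one-row data frame: `n_spindles`, `n_coupled`, `mean_phase_rad`,
#'   `rvl`, `n_oc`.
#' @export
coupling_summary <- function(phases, n_spindles, oc_window = 0.5) {
  n_coupled <- length(phases)
  if (n_spindles < n_coupled) stop("n_spindles must be >= length(phases)")
  if (n_coupled == 0) {
    return(data.frame(n_spindles = n_spindles, n_coupled = 0L,
                      mean_phase_rad = NA_real_, rvl = NA_real_, n_oc = 0L))
  }
  mu <- circ_mean(phases)
  data.frame(n_spindles = n_spindles, n_coupled = n_coupled,
             mean_phase_rad = mu, rvl = circ_rvl(phases),
             n_oc = sum(circ_dist(phases, mu) <= oc_window))
}

#' Average per-channel coupling summaries across central electrodes
#'
#' Resultant vector length and OC-spindle counts are computed per channel
#' and then averaged across the central electrodes (not pooled at the phase
#' level). Counts are averaged as numbers; the mean phase is combined
#' circularly, weighted by each channel's resultant vector.
#'
#' @param summaries list (or rbind-ed data frame) of per-channel
#'   [coupling_summary()] rows.
#' @return one-row data frame on the same columns.
#' @export
average_channel_summaries <- function(summaries) {
  df <- if (is.data.frame(summaries)) summaries else do.call(rbind, summaries)
  ok <- !is.na(df$rvl)
  mean_phase <- if (any(ok))
    wrap_pi(Arg(sum(df$rvl[ok] * exp(1i * df$mean_phase_rad[ok])))) else NA_real_
  data.frame(n_spindles = mean(df$n_spindles),
             n_coupled = mean(df$n_coupled),
             mean_phase_rad = mean_phase,
             rvl = if (any(ok)) mean(df$rvl[ok]) else NA_real_,
             n_oc = mean(df$n_oc))
}
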