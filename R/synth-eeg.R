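#' Ground-truth parameters for synthetic EEG
#'
#' Defaults emulate the oscillatory content the detection pipeline targets:
#' a 1/f colored-noise background; slow oscillations planted in SWS (and
#' sparsely in N2) as single 0.2-1.25 Hz cycles with ~150 uV peak-to-peak
#' amplitude; sigma-band spindle bursts in N2/SWS at a participant-specific
#' center frequency drawn from the fast-spindle population distribution
#' (mean 13.47 Hz, SD 0.56 Hz), a fraction of them phase-locked to planted
#' slow oscillations through a von Mises phase distribution; and a
#' multiplicative theta-band (4-8 Hz) power gain in REM epochs.
#'
#' @param background_sd broadband background amplitude (uV, SD).
#' @param spectral_exponent exponent of the 1/f^a background.
#' @param so_rate_sws,so_rate_n2 planted slow oscillations per minute.
#' @param so_p2p_uv,so_p2p_sd slow-oscillation peak-to-peak amplitude (uV).
#' @param so_cycle_range cycle length range (s), inside the 0.8-5 s band.
#' @param spindle_rate_n2,spindle_rate_sws planted spindles per minute.
#' @param spindle_amp_uv spindle burst peak amplitude (uV). The default
#'   (40 uV over a 15-uV background) puts the burst's rectified envelope
#'   well above five times the mean rectified sigma-band amplitude, the
#'   detection threshold, so planted events are recoverable.
#' @param spindle_dur_range burst duration range (s).
#' @param center_freq_mean,center_freq_sd population distribution of the
#'   individual fast-spindle peak frequency (Hz).
#' @param coupled_frac_sws,coupled_frac_n2 fraction of planted spindles
#'   whose peak is locked into a planted slow-oscillation cycle.
#' @param coupling_mu,coupling_kappa von Mises parameters of the planted
#'   slow-oscillation phase at coupled spindle peaks (0 = up state).
#' @param theta_gain REM theta power gain (>= 1; 1 = no elevation).
#' @param sws_delta_gain optional SWS delta-band (0.5-2 Hz) background
#'   power gain (>= 1). At the default (1) the planted slow-oscillation
#'   cycles are the SWS slow-wave activity and the ground-truth ledger is
#'   exhaustive; raising it adds unlabelled background delta waves, some of
#'   which legitimately satisfy the detector's relative thresholds.
#' @return list of class `eeg_truth_params`.
#' @export
eeg_truth_params <- function(background_sd = 15,
                             spectral_exponent = 1,
                             so_rate_sws = 6, so_rate_n2 = 0.5,
                             so_p2p_uv = 150, so_p2p_sd = 8,
                             so_cycle_range = c(1.0, 1.6),
                             spindle_rate_n2 = 5, spindle_rate_sws = 4,
                             spindle_amp_uv = 40,
                             spindle_dur_range = c(0.7, 1.3),
                             center_freq_mean = 13.47, center_freq_sd = 0.56,
                             coupled_frac_sws = 0.22, coupled_frac_n2 = 0.15,
                             coupling_mu = 0, coupling_kappa = 5,
                             theta_gain = 1.4, sws_delta_gain = 1) {
  stopifnot(background_sd > 0, theta_gain >= 1, sws_delta_gain >= 1)
  structure(as.list(environment()), class = "eeg_truth_params")
}

# colored noise of length n with PSD ~ 1/f^a over [lo, rate/2] Hz, scaled
# to sd `sd`; band-limited below `lo` to mirror the 0.2 Hz high-pass floor
# of preprocessed sleep EEG, and synthesized at a 5-smooth FFT length
colored_noise <- function(n, exponent, sd, rate = 256, lo = 0.2) {
  if (n < 4) return(stats::rnorm(n, 0, sd))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  k <- floor(m / 2)
  freq <- c(0, seq_len(k), rev(seq_len(ceiling(m / 2) - 1L))) * rate / m
  amp <- ifelse(freq >= lo, 1 / pmax(freq, 1e-9)^(exponent / 2), 0)
  x <- Re(stats::fft(W * amp, inverse = TRUE))[seq_len(n)] / m
  x * sd / stats::sd(x)
}

# unit colored noise restricted to a frequency band (used to add REM theta)
band_noise <- function(n, rate, band, exponent) {
  if (n < 8) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  k <- floor(m / 2)
  freq <- c(0, seq_len(k), rev(seq_len(ceiling(m / 2) - 1L))) * rate / m
  amp <- ifelse(freq >= band[1] & freq <= band[2],
                1 / pmax(freq, 1e-6)^(exponent / 2), 0)
  Re(stats::fft(W * amp, inverse = TRUE))[seq_len(n)] / m
}

# contiguous runs of sorted epoch indices, as (first, last) rows
epoch_runs <- function(epochs) {
  if (length(epochs) == 0) return(matrix(integer(0), ncol = 2))
  brk <- which(diff(epochs) > 1L)
  cbind(first = epochs[c(1L, brk + 1L)], last = epochs[c(brk, length(epochs))])
}

# single slow-oscillation cycle starting at a positive-to-negative
# zero-crossing (trough first, then the up-state peak)
so_waveform <- function(len_s, p2p, rate) {
  t <- seq(0, len_s, by = 1 / rate)
  -(p2p / 2) * sin(2 * pi * t / len_s)
}

# Gaussian-windowed sigma burst with its envelope peak at the center
spindle_waveform <- function(dur_s, freq, amp, rate, phase = 0) {
  t <- seq(-dur_s / 2, dur_s / 2, by = 1 / rate)
  amp * exp(-t^2 / (2 * (dur_s / 4)^2)) * cos(2 * pi * freq * t + phase)
}

#' Synthesize multichannel EEG for a hypnogram
#'
#' Builds a stage-conditioned synthetic EEG recording: colored-noise
#' background on every channel, slow oscillations planted in SWS (sparsely
#' in N2), spindle bursts planted in N2/SWS (a configurable fraction locked
#' to planted slow-oscillation cycles at a von Mises phase), and a theta
#' power gain in REM epochs. Oscillatory events are added identically to all
#' EEG channels; the mastoids carry low-amplitude noise. Returns the
#' recording and the exact planted-event ledger (ground truth).
#'
#' Planted events always lie fully inside epochs of their nominal stage.
#' The slow-oscillation phase convention is 0 at the filtered wave's
#' positive peak and +/-pi at the trough, matching the coupling module.
#'
#' @param hyp a [hypnogram()].
#' @param params an [eeg_truth_params()] list.
#' @param channels channels to synthesize.
#' @param rate sampling rate in Hz.
#' @param stages optional stage subset: when given, background noise is
#'   synthesized only over epochs of these stages (other samples stay
#'   zero), which keeps stage-restricted analyses cheap on long nights.
#' @param seed optional integer seed.
#' @return list with `recording` (a [psg_recording()]) and `truth` (list
#'   with `spindles`, `slow_oscillations` data frames, `center_freq`,
#'   `theta_gain`).
#' @export
synthesize_eeg <- function(hyp, params = eeg_truth_params(),
                           channels = c("F3", "F4", "C3", "C4", "O1", "O2",
                                        "A1", "A2"),
                           rate = 256, stages = NULL, seed = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (length(hyp$stages) == 0) stop("empty hypnogram")
  if (!is.null(seed)) set.seed(seed)
  el <- hyp$epoch_length
  spe <- as.integer(el * rate)
  n <- length(hyp$stages) * spe
  eeg_ch <- setdiff(channels, c("A1", "A2"))
  epoch_start <- function(e) (e - 1) * spe  # 0-based sample offset

  cf <- stats::rnorm(1, params$center_freq_mean, params$center_freq_sd)
  cf <- min(max(cf, 11), 15.5)

  # --- event placement (shared across channels) -------------------------
  sws_epochs <- which(hyp$stages == "SWS")
  n2_epochs <- which(hyp$stages == "N2")
  rem_epochs <- which(hyp$stages == "REM")

  place_sos <- function(epochs, rate_min) {
    out <- list()
    for (e in epochs) {
      k <- stats::rpois(1, rate_min * el / 60)
      if (k == 0) next
      t0 <- (e - 1) * el
      # sequential placement with margins; skip what does not fit
      cursor <- t0 + stats::runif(1, 0.2, 1.5)
      for (j in seq_len(k)) {
        len <- stats::runif(1, params$so_cycle_range[1], params$so_cycle_range[2])
        if (cursor + len > t0 + el - 0.2) break
        p2p <- stats::rnorm(1, params$so_p2p_uv, params$so_p2p_sd)
        out[[length(out) + 1L]] <- data.frame(
          stage = hyp$stages[e], epoch = e, start_s = cursor,
          end_s = cursor + len, cycle_s = len, p2p_uv = p2p)
        cursor <- cursor + len + stats::runif(1, 0.5, 2.0)
      }
    }
    if (length(out) == 0) return(NULL)
    do.call(rbind, out)
  }
  sos <- rbind(place_sos(sws_epochs, params$so_rate_sws),
               place_sos(n2_epochs, params$so_rate_n2))

  place_spindles <- function(epochs, rate_min, coupled_frac, stage) {
    out <- list()
    stage_sos <- if (!is.null(sos)) sos[sos$stage == stage, ] else NULL
    for (e in epochs) {
      k <- stats::rpois(1, rate_min * el / 60)
      if (k == 0) next
      t0 <- (e - 1) * el
      so_here <- if (!is.null(stage_sos)) stage_sos[stage_sos$epoch == e, ] else NULL
      taken <- numeric(0)
      for (j in seq_len(k)) {
        dur <- stats::runif(1, params$spindle_dur_range[1],
                            params$spindle_dur_range[2])
        coupled <- !is.null(so_here) && nrow(so_here) > 0 &&
          stats::runif(1) < coupled_frac
        if (coupled) {
          row <- so_here[sample(nrow(so_here), 1), ]
          phi <- rvonmises(1, params$coupling_mu, params$coupling_kappa)
          # phase theta(t) = 2*pi*t/L + pi/2 for the planted -sin cycle
          tpk <- row$start_s + (wrap_pi(phi - pi / 2) %% (2 * pi)) /
            (2 * pi) * row$cycle_s
        } else {
          phi <- NA_real_
          tpk <- t0 + stats::runif(1, dur / 2 + 0.1, el - dur / 2 - 0.1)
        }
        # keep the burst inside its stage epoch and away from other bursts
        if (tpk - dur / 2 < t0 + 0.05 || tpk + dur / 2 > t0 + el - 0.05) next
        if (any(abs(taken - tpk) < dur + 0.3)) next
        taken <- c(taken, tpk)
        out[[length(out) + 1L]] <- data.frame(
          stage = stage, epoch = e, peak_time_s = tpk,
          onset_s = tpk - dur / 2, duration_s = dur,
          freq_hz = cf, amp_uv = params$spindle_amp_uv,
          coupled = coupled, so_phase = phi)
      }
    }
    if (length(out) == 0) return(NULL)
    do.call(rbind, out)
  }
  spindles <- rbind(
    place_spindles(n2_epochs, params$spindle_rate_n2,
                   params$coupled_frac_n2, "N2"),
    place_spindles(sws_epochs, params$spindle_rate_sws,
                   params$coupled_frac_sws, "SWS"))

  # --- event waveform template (identical on all EEG channels) ----------
  events <- numeric(n)
  if (!is.null(sos)) {
    for (i in seq_len(nrow(sos))) {
      w <- so_waveform(sos$cycle_s[i], sos$p2p_uv[i], rate)
      s0 <- round(sos$start_s[i] * rate)
      idx <- s0 + seq_along(w)
      idx <- idx[idx >= 1 & idx <= n]
      events[idx] <- events[idx] + w[seq_along(idx)]
    }
  }
  if (!is.null(spindles)) {
    for (i in seq_len(nrow(spindles))) {
      w <- spindle_waveform(spindles$duration_s[i], spindles$freq_hz[i],
                            spindles$amp_uv[i], rate)
      s0 <- round((spindles$peak_time_s[i] - spindles$duration_s[i] / 2) * rate)
      idx <- s0 + seq_along(w)
      idx <- idx[idx >= 1 & idx <= n]
      events[idx] <- events[idx] + w[seq_along(idx)]
    }
  }

  # stage-run layout for background and band components
  bg_epochs <- if (is.null(stages)) seq_along(hyp$stages) else
    which(hyp$stages %in% stages)
  bg_runs <- epoch_runs(bg_epochs)
  rem_runs <- epoch_runs(intersect(rem_epochs, bg_epochs))
  sws_runs <- epoch_runs(intersect(sws_epochs, bg_epochs))

  # additive band-limited component over stage runs, with per-run unit SD
  band_component <- function(runs, band, sd_target) {
    out <- numeric(n)
    for (r in seq_len(nrow(runs))) {
      i0 <- (runs[r, 1] - 1L) * spe + 1L
      i1 <- runs[r, 2] * spe
      y <- band_noise(i1 - i0 + 1L, rate, band, params$spectral_exponent)
      out[i0:i1] <- y / stats::sd(y) * sd_target
    }
    out
  }

  signals <- list()
  for (ch in channels) {
    if (ch %in% c("A1", "A2")) {
      signals[[ch]] <- stats::rnorm(n, 0, 2)
      next
    }
    x <- numeric(n)
    for (r in seq_len(nrow(bg_runs))) {
      i0 <- (bg_runs[r, 1] - 1L) * spe + 1L
      i1 <- bg_runs[r, 2] * spe
      x[i0:i1] <- colored_noise(i1 - i0 + 1L, params$spectral_exponent,
                                params$background_sd, rate = rate)
    }
    if (params$theta_gain > 1 && nrow(rem_runs) > 0) {
      # independent theta-band noise, scaled so REM theta power is
      # theta_gain times the background's own theta power
      x <- x + band_component(
        rem_runs, c(4, 8),
        sqrt(params$theta_gain - 1) * params$background_sd *
          theta_band_fraction(params$spectral_exponent, rate))
    }
    if (params$sws_delta_gain > 1 && nrow(sws_runs) > 0) {
      # slow-wave activity: 0.5-2 Hz elevation in SWS
      x <- x + band_component(
        sws_runs, c(0.5, 2),
        sqrt(params$sws_delta_gain - 1) * params$background_sd *
          band_sd_fraction(params$spectral_exponent, rate, 0.5, 2))
    }
    signals[[ch]] <- x + events
  }

  truth <- list(
    spindles = if (is.null(spindles)) data.frame() else
      data.frame(channel = "all", spindles, row.names = NULL),
    slow_oscillations = if (is.null(sos)) data.frame() else
      data.frame(channel = "all", sos, row.names = NULL),
    center_freq = cf, theta_gain = params$theta_gain)
  list(recording = psg_recording(signals, rate), truth = truth)
}

# fraction of the background SD carried by a frequency band for a 1/f^a
# spectrum band-limited to [0.2, rate/2]
band_sd_fraction <- function(exponent, rate, a, b, lo = 0.2) {
  hi <- rate / 2
  band_power <- function(p, q) {
    if (abs(exponent - 1) < 1e-9) log(q / p)
    else (q^(1 - exponent) - p^(1 - exponent)) / (1 - exponent)
  }
  sqrt(band_power(a, b) / band_power(lo, hi))
}

theta_band_fraction <- function(exponent, rate, lo = 0.2) {
  band_sd_fraction(exponent, rate, 4, 8, lo)
}

#' Write ground-truth event tables as CSV
#'
#' @param truth the `truth` element returned by [synthesize_eeg()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$spindles, file.path(dir, "truth_spindles.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$slow_oscillations,
                   file.path(dir, "truth_slow_oscillations.csv"),
                   row.names = FALSE)
  invisible(dir)
}
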