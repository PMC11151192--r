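#' Welch power spectral density
#'
#' Mean modified periodogram over Hamming-windowed segments of `nfft`
#' samples with the given overlap. Segments are demeaned before windowing.
#' Returns a one-sided density normalized so that summing
#' `psd * df` recovers the signal power (Parseval).
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param nfft segment length in samples (default 1024: 4 s at 256 Hz,
#'   0.25 Hz resolution).
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, rate, nfft = 1024, overlap = 0.5) {
  n <- length(x)
  if (n < nfft) stop("signal shorter than one Welch segment")
  step <- max(1L, round(nfft * (1 - overlap)))
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nfft) / (nfft - 1))
  u <- sum(w^2)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nfft - 1L)]
    (seg - mean(seg)) * w
  }, numeric(nfft))
  S <- Mod(stats::mvfft(segs))^2
  k <- floor(nfft / 2)
  psd <- rowMeans(S)[1:(k + 1L)] / (u * rate)
  psd[2:k] <- 2 * psd[2:k]  # one-sided
  list(freq = (0:k) * rate / nfft, psd = psd)
}

#' One-hertz PSD bins used by the energy pipeline
#'
#' Averages native Welch bins into 30 one-hertz bins covering (0, 30] Hz;
#' bin `j` covers frequencies `(j-1, j]`, so boundary frequencies belong to
#' the lower bin, and the DC component is excluded.
#'
#' @param freq,psd a Welch PSD as returned by [welch_psd()].
#' @return named numeric vector of 30 bin values.
#' @export
one_hz_bins <- function(freq, psd) {
  bins <- numeric(30)
  for (j in 1:30) {
    sel <- freq > (j - 1) & freq <= j
    bins[j] <- mean(psd[sel])
  }
  names(bins) <- paste0("bin", 1:30)
  bins
}

#' Per-epoch 1-Hz PSD bin table
#'
#' Welch PSD of every kept epoch (1024-sample windows, 50% overlap)
#' averaged into 1-Hz bins over 0-30 Hz and further averaged across the
#' given channels (frontal F3/F4 by default).
#'
#' @param rec a [psg_recording()].
#' @param es an `epoch_set` (the channel field is ignored; `channels` below
#'   is used).
#' @param channels channels to average.
#' @param nfft Welch segment length.
#' @return matrix (epochs x 30 bins), rownames the epoch indices.
#' @export
epoch_psd <- function(rec, es, channels = c("F3", "F4"), nfft = 1024) {
  stopifnot(inherits(rec, "psg_recording"))
  missing_ch <- setdiff(channels, names(rec$signals))
  if (length(missing_ch) > 0)
    stop("channel(s) not in recording: ", paste(missing_ch, collapse = ", "))
  spe <- as.integer(es$epoch_length * es$rate)
  if (spe < nfft) stop("epoch shorter than the Welch window")
  out <- matrix(0, nrow = length(es$epochs), ncol = 30,
                dimnames = list(es$epochs, paste0("bin", 1:30)))
  for (ch in channels) {
    x <- rec$signals[[ch]]
    for (i in seq_along(es$epochs)) {
      e <- es$epochs[i]
      seg <- x[((e - 1) * spe + 1):(e * spe)]
      W <- welch_psd(seg, es$rate, nfft = nfft)
      out[i, ] <- out[i, ] + one_hz_bins(W$freq, W$psd)
    }
  }
  out / length(channels)
}

#' Frequency bands of the energy measure
#'
#' Six canonical bands over the 1-Hz bins, boundary bins assigned to the
#' lower band: SO-delta (<= 4 Hz), theta (4-8], alpha (8-12], sigma
#' (12-16], beta1 (16-22], beta2 (22-30].
#' @keywords internal
ENERGY_BANDS <- list(so_delta = 1:4, theta = 5:8, alpha = 9:12,
                     sigma = 13:16, beta1 = 17:22, beta2 = 23:30)

#' Accumulated PSD energy per participant
#'
#' The stage-specific energy measure: every (epoch, bin) PSD value of the
#' cohort is z-scored against the mean and SD pooled over all bins, epochs
#' and participants of that stage, linearly shifted into the positive range
#' (minimum value 1), and summed over each participant's epochs, giving an
#' accumulated (duration-weighted) spectral energy per 1-Hz bin.
#'
#' @param bin_tables named list, one per participant, of per-epoch bin
#'   matrices from [epoch_psd()].
#' @param log_transform log10-transform the bin values before z-scoring
#'   (spectral power is approximately log-normal; default TRUE).
#' @return matrix (participants x 30 bins) of accumulated energy.
#' @export
accumulate_energy <- function(bin_tables, log_transform = TRUE) {
  stopifnot(length(bin_tables) >= 1)
  if (is.null(names(bin_tables)))
    names(bin_tables) <- paste0("p", seq_along(bin_tables))
  all_vals <- unlist(bin_tables, use.names = FALSE)
  if (log_transform) all_vals <- log10(pmax(all_vals, 1e-12))
  mu <- mean(all_vals); sdv <- stats::sd(all_vals)
  if (!is.finite(sdv)) stop("degenerate input: non-finite bin values")
  if (sdv == 0) {
    # constant input: all z-scores are 0 by convention, so every shifted
    # value is 1 and the energy reduces to the epoch count
    warning("pooled SD of bin values is zero; energies equal epoch counts")
    sdv <- 1
  }
  shift <- 1 - (min(all_vals) - mu) / sdv  # global minimum maps to 1
  out <- t(vapply(bin_tables, function(m) {
    v <- if (log_transform) log10(pmax(m, 1e-12)) else m
    z <- (v - mu) / sdv + shift
    colSums(z)
  }, numeric(30)))
  colnames(out) <- paste0("bin", 1:30)
  out
}

#' Band means of (adjusted) bin energies
#'
#' @param energy participants x 30 bin matrix.
#' @return participants x 6 band matrix (band value = mean of its bins).
#' @export
band_energy <- function(energy) {
  out <- vapply(ENERGY_BANDS, function(b)
    rowMeans(energy[, b, drop = FALSE]), numeric(nrow(energy)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(ENERGY_BANDS)))
  out
}

#' Residualize energy sums for amplitude confounds
#'
#' Two-stage adjustment for amplitude variation due to variable conductance
#' (skull/skin properties): (1) the participant's mean PSD over 0-30 Hz is
#' regressed on the suppression-condition indicator and the stage duration,
#' keeping the residual R (mean PSD purged of design effects); (2) each
#' bin-wise energy sum is regressed on R and replaced by its residual.
#' Adjusted values are centered residuals (cohort mean ~ 0) and are
#' uncorrelated with R by construction.
#'
#' @param energy participants x 30 bin matrix from [accumulate_energy()].
#' @param mean_psd per-participant mean PSD across 0-30 Hz.
#' @param condition per-participant condition factor/character.
#' @param stage_duration per-participant stage minutes.
#' @return list with `bins` (adjusted participants x 30 matrix), `bands`
#'   (participants x 6), and `amplitude_residual` (R).
#' @export
residualize_energy <- function(energy, mean_psd, condition, stage_duration) {
  n <- nrow(energy)
  if (n < 3) stop("cohort size must be at least 3")
  stopifnot(length(mean_psd) == n, length(condition) == n,
            length(stage_duration) == n)
  d <- data.frame(mp = mean_psd, cond = factor(condition),
                  dur = stage_duration)
  f1 <- stats::lm(mp ~ cond + dur, data = d)
  if (any(is.na(stats::coef(f1))))
    stop("collinear design in the amplitude model")
  R <- stats::residuals(f1)
  adj <- apply(energy, 2, function(y) stats::residuals(stats::lm(y ~ R)))
  list(bins = adj, bands = band_energy(adj), amplitude_residual = R)
}
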