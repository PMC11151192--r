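#' Cohort specification for the synthetic-data module
#'
#' Bundles the fixed design constants of a simulated suppression cohort:
#' group size, sleep opportunity (default 480 min, i.e. a 11 P.M.-7 A.M.
#' window), EEG and electrodermal sampling rates and the global seed from
#' which all per-participant substreams are derived.
#'
#' @param n_per_condition participants per suppression condition (>= 1).
#' @param sleep_opportunity_min sleep opportunity in minutes.
#' @param eeg_rate EEG sampling rate in Hz.
#' @param eda_rate skin-conductance sampling rate in Hz.
#' @param seed integer global seed; identical specs with identical seeds
#'   produce bit-identical cohorts.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_condition = 15, sleep_opportunity_min = 480,
                        eeg_rate = 256, eda_rate = 500, seed = 1L) {
  stopifnot(n_per_condition >= 1, sleep_opportunity_min > 0,
            eeg_rate > 0, eda_rate > 0)
  structure(list(n_per_condition = as.integer(n_per_condition),
                 sleep_opportunity_min = sleep_opportunity_min,
                 eeg_rate = eeg_rate, eda_rate = eda_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

CONDITIONS <- c("REMS_SUPPR", "SWS_SUPPR")

# Default stage dynamics of the simulated sleeper, at 30-s epoch resolution.
# Dwell times are geometric (mean in epochs); on leaving a stage the next
# stage is drawn from the corresponding kernel row. Values were chosen so
# that the two suppressed conditions land near the published group means for
# stage durations, forced-awakening counts and fragmentation (see the
# methods vignette).
hypnogram_params <- function(dwell = c(W = 7, N1 = 2, N2 = 10, SWS = 25, REM = 28),
                             suppression_dwell = 7,
                             rebound_prob = 0.55,
                             rebound_window = 14,
                             rebound_dwell_factor = 0.3,
                             arousals_per_hour = 8,
                             artifacts_per_hour = 6) {
  kernel <- rbind(
    W   = c(W = 0,    N1 = 0.85, N2 = 0.15, SWS = 0,    REM = 0),
    N1  = c(W = 0.15, N1 = 0,    N2 = 0.85, SWS = 0,    REM = 0),
    N2  = c(W = 0.40, N1 = 0.26, N2 = 0,    SWS = 0.19, REM = 0.15),
    SWS = c(W = 0.15, N1 = 0,    N2 = 0.85, SWS = 0,    REM = 0),
    REM = c(W = 0.40, N1 = 0.30, N2 = 0.30, SWS = 0,    REM = 0))
  list(dwell = dwell, kernel = kernel,
       suppression_dwell = suppression_dwell,
       rebound_prob = rebound_prob, rebound_window = rebound_window,
       rebound_dwell_factor = rebound_dwell_factor,
       arousals_per_hour = arousals_per_hour,
       artifacts_per_hour = artifacts_per_hour)
}

# awakening intensity steps 1-4 (marimba, name, sit up, math problems);
# probabilities reproduce the published mean strengths (1.9 / 1.6)
awakening_intensity_probs <- function(condition) {
  if (condition == "REMS_SUPPR") c(0.45, 0.30, 0.15, 0.10)
  else c(0.55, 0.30, 0.12, 0.03)
}

#' Generate one suppression-night hypnogram
#'
#' Simulates a night of sleep under selective stage suppression as a
#' discrete-time Markov chain over W/N1/N2/SWS/REM at 30-s resolution. On
#' entering the suppressed stage the dwell is cut short (geometric, mean
#' `suppression_dwell` epochs, default 8 = 4 min) by a forced awakening,
#' logged with a progressive intensity step. After a forced awakening the
#' sleeper transiently rebounds toward the suppressed stage (probability
#' `rebound_prob` within `rebound_window` epochs), which fragments the
#' suppressed stage's episodes the way repeated awakenings do. Brief
#' arousals and movement artifacts are annotated at constant hourly rates
#' during sleep.
#'
#' @param spec a [cohort_spec()].
#' @param condition `"REMS_SUPPR"` or `"SWS_SUPPR"`.
#' @param params dynamics parameters from `hypnogram_params()`.
#' @param seed optional integer; when given, the generator is deterministic.
#' @return list with elements `hypnogram` (a [hypnogram()] with arousal and
#'   artifact annotations) and `awakenings` (data frame: `epoch`, `time_s`,
#'   `stage_interrupted`, `intensity`).
#' @export
generate_hypnogram <- function(spec, condition = CONDITIONS,
                               params = hypnogram_params(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  suppressed <- if (condition == "REMS_SUPPR") "REM" else "SWS"
  n <- as.integer(spec$sleep_opportunity_min * 60 / 30)
  dwell <- params$dwell
  kernel <- params$kernel
  # precomputed cumulative kernels (plain + rebound-biased) and draws keep
  # the epoch loop cheap enough for many-cohort simulations
  cum_plain <- t(apply(kernel, 1, cumsum))
  kern_reb <- kernel
  for (st in c("N1", "N2")) {
    kern_reb[st, suppressed] <- kern_reb[st, suppressed] + 1.2
    kern_reb[st, ] <- kern_reb[st, ] / sum(kern_reb[st, ])
  }
  cum_reb <- t(apply(kern_reb, 1, cumsum))
  cum_int <- cumsum(awakening_intensity_probs(condition))
  u_stay <- stats::runif(n)
  u_next <- stats::runif(n)
  u_extra <- stats::runif(n)
  stages <- character(n)
  aw_epoch <- integer(0); aw_int <- integer(0)
  state <- "W"
  rebound <- 0L  # epochs of rebound bias remaining
  for (i in seq_len(n)) {
    stages[i] <- state
    d <- if (state == suppressed) params$suppression_dwell else dwell[[state]]
    # during the rebound window intermediate stages are passed through
    # quickly, so the sleeper re-enters the suppressed stage within minutes
    if (rebound > 0L && state != suppressed)
      d <- max(1.5, d * params$rebound_dwell_factor)
    if (u_stay[i] < 1 - 1 / d) {
      if (rebound > 0L) rebound <- rebound - 1L
      next
    }
    if (state == suppressed) {
      # forced awakening (progressive intensity) ends the bout
      aw_epoch <- c(aw_epoch, i)
      aw_int <- c(aw_int, findInterval(u_next[i], cum_int) + 1L)
      state <- "W"
      # homeostatic pressure: with probability rebound_prob the sleeper
      # drifts back toward the suppressed stage within minutes
      rebound <- if (u_extra[i] < params$rebound_prob)
        params$rebound_window else 0L
      next
    }
    cum <- if (rebound > 0L && (state == "N1" || state == "N2"))
      cum_reb[state, ] else cum_plain[state, ]
    state <- STAGES[findInterval(u_next[i], cum) + 1L]
    if (rebound > 0L) rebound <- rebound - 1L
    if (state == suppressed) rebound <- 0L
  }
  awakenings <- data.frame(epoch = aw_epoch, time_s = aw_epoch * 30,
                           stage_interrupted =
                             rep(suppressed, length(aw_epoch)),
                           intensity = aw_int)
  # brief arousals / movement artifacts during sleep epochs
  ann <- function(rate_per_hour, dur_range, label) {
    sleep_idx <- which(stages != "W")
    k <- stats::rpois(1, rate_per_hour * length(sleep_idx) * 30 / 3600)
    k <- min(k, length(sleep_idx))
    if (k == 0) return(NULL)
    ep <- sample(sleep_idx, k)
    dur <- stats::runif(k, dur_range[1], dur_range[2])
    on <- (ep - 1) * 30 + stats::runif(k, 0, pmax(30 - dur, 0.1))
    data.frame(onset_s = on, duration_s = pmin(dur, 30), label = label)
  }
  hyp <- hypnogram(stages,
                   arousals = ann(params$arousals_per_hour, c(3, 12), "arousal"),
                   artifacts = ann(params$artifacts_per_hour, c(2, 12), "artifact"))
  list(hypnogram = hyp, awakenings = awakenings)
}
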