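#' Skin-conductance trace container
#'
#' Tonic skin conductance (microsiemens) sampled at a fixed rate with the
#' session event markers needed by the SCR computation: baseline start,
#' playback start and playback end (seconds from trace start).
#'
#' @param samples numeric vector, microsiemens; must be finite.
#' @param rate sampling rate in Hz.
#' @param markers named numeric vector or list with `baseline_start`,
#'   `playback_start`, `playback_end`.
#' @return object of class `scl_trace`.
#' @export
scl_trace <- function(samples, rate, markers) {
  markers <- as.list(markers)
  stopifnot(all(c("baseline_start", "playback_start", "playback_end") %in%
                  names(markers)),
            rate > 0, all(is.finite(samples)))
  if (!(markers$baseline_start <= markers$playback_start &&
        markers$playback_start < markers$playback_end))
    stop("markers must be ordered: baseline_start <= playback_start < playback_end")
  structure(list(samples = samples, rate = rate,
                 markers = markers[c("baseline_start", "playback_start",
                                     "playback_end")]),
            class = "scl_trace")
}

#' Default SCL generator parameters
#'
#' The playback elevation is multiplicative (tonic skin conductance is a
#' ratio-scaled measure). Default day multipliers are back-computed from the
#' session SCR statistic (`scr = sqrt(100 * playback / baseline)`) so that
#' cohort day means land near 13.75 (Day 1), 15.54 (Day 2) and 12.73
#' (Day 5), with the Day-1-to-Day-2 elevation differing by condition: a
#' 20.1% overnight SCR increase when SWS was suppressed (REM intact) and
#' 6.1% when REM was suppressed.
#'
#' @param tonic_uS tonic baseline level in microsiemens (> 0).
#' @param scr_day1,scr_day5 target SCR statistic on Days 1 and 5.
#' @param overnight_change_pct named vector of the Day-1-to-Day-2 percent
#'   SCR change per condition.
#' @param noise_sd measurement noise SD (uS).
#' @param drift_sd SD of the smoothed random-walk drift (uS).
#' @param baseline_s,playback_s,recovery_s segment durations (s).
#' @return list of class `scl_params`.
#' @export
scl_params <- function(tonic_uS = 5,
                       scr_day1 = 13.75, scr_day5 = 12.73,
                       overnight_change_pct = c(REMS_SUPPR = 6.1,
                                                SWS_SUPPR = 20.1),
                       noise_sd = 0.05, drift_sd = 0.2,
                       baseline_s = 300, playback_s = 90, recovery_s = 300) {
  stopifnot(tonic_uS > 0)
  as.list(environment())
}

# playback/baseline multiplier that yields a given SCR statistic
scr_to_multiplier <- function(scr) (scr / 10)^2

#' Synthesize one session's SCL trace
#'
#' A 5-min baseline at the tonic level, a ~1.5-min playback segment at a
#' multiplicatively elevated level and a 5-min recovery, plus smooth drift
#' and measurement noise. The playback multiplier defaults to the value
#' implied by the condition x day SCR targets of [scl_params()]; it can be
#' overridden (e.g. by the cohort generator) via `multiplier`.
#'
#' @param condition `"REMS_SUPPR"` or `"SWS_SUPPR"`.
#' @param day measurement day: 1, 2 or 5.
#' @param params an [scl_params()] list.
#' @param multiplier optional explicit playback/baseline multiplier.
#' @param rate sampling rate in Hz.
#' @param seed optional integer seed.
#' @return an [scl_trace()].
#' @export
synthesize_scl <- function(condition = CONDITIONS, day = c(1, 2, 5),
                           params = scl_params(), multiplier = NULL,
                           rate = 500, seed = NULL) {
  condition <- match.arg(condition)
  day <- as.numeric(day)[1]
  if (!day %in% c(1, 2, 5)) stop("day must be 1, 2 or 5")
  if (params$tonic_uS <= 0) stop("tonic level must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(multiplier)) {
    scr1 <- params$scr_day1
    scr <- switch(as.character(day),
                  "1" = scr1,
                  "2" = scr1 * (1 + params$overnight_change_pct[[condition]] / 100),
                  "5" = params$scr_day5)
    multiplier <- scr_to_multiplier(scr)
  }
  n_b <- round(params$baseline_s * rate)
  n_p <- round(params$playback_s * rate)
  n_r <- round(params$recovery_s * rate)
  n <- n_b + n_p + n_r
  level <- c(rep(params$tonic_uS, n_b),
             rep(params$tonic_uS * multiplier, n_p),
             params$tonic_uS * (1 + (multiplier - 1) *
                                  exp(-seq_len(n_r) / (30 * rate))))
  drift <- 0
  if (params$drift_sd > 0) {
    # smooth tonic drift: heavily low-passed random walk
    step <- stats::rnorm(ceiling(n / rate), 0, params$drift_sd / sqrt(n / rate))
    drift <- stats::approx(seq_along(step) * rate, cumsum(step),
                           xout = seq_len(n), rule = 2)$y
  }
  noise <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else 0
  samples <- pmax(level + drift + noise, 0.01)
  scl_trace(samples, rate,
            markers = list(baseline_start = 0,
                           playback_start = params$baseline_s,
                           playback_end = params$baseline_s + params$playback_s))
}

#' Write / read an SCL trace as CSV
#'
#' The trace itself is `time_s,microsiemens`; markers are a separate
#' `event,onset_s` CSV.
#'
#' @param trace an [scl_trace()].
#' @param path trace CSV path.
#' @param marker_path marker CSV path.
#' @rdname scl-io
#' @export
write_scl_csv <- function(trace, path, marker_path) {
  n <- length(trace$samples)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / trace$rate,
                              microsiemens = trace$samples),
                   path, row.names = FALSE)
  utils::write.csv(data.frame(event = names(trace$markers),
                              onset_s = unlist(trace$markers)),
                   marker_path, row.names = FALSE)
  invisible(path)
}

#' @rdname scl-io
#' @export
read_scl_csv <- function(path, marker_path) {
  df <- utils::read.csv(path)
  mk <- utils::read.csv(marker_path)
  rate <- 1 / stats::median(diff(df$time_s))
  scl_trace(df$microsiemens, rate = round(rate, 6),
            markers = as.list(stats::setNames(mk$onset_s, mk$event)))
}

#' Behavioral generator parameters
#'
#' Day means default to the published-scale trajectories the package's
#' synthetic cohorts are calibrated to: a subjective-embarrassment composite
#' decreasing over sessions (Day 1 mean 1.83 on the 0-4 scale), with a sex
#' difference on Days 2 and 5, and cued metaphor recall percentages with a
#' persistent sex gap (e.g. Day 1: 68.8% vs 53.0%).
#'
#' @param emb_means named list of per-day two-level vectors `c(F, M)` of the
#'   embarrassment composite.
#' @param emb_sd between-participant SD of the composite.
#' @param emb_item_sd within-composite item scatter.
#' @param recall_means named list of per-day `c(F, M)` recall percentages.
#' @param recall_sd between-participant recall SD (percent points).
#' @return list of class `behavior_params`.
#' @export
behavior_params <- function(emb_means = list(`1` = c(F = 1.83, M = 1.83),
                                             `2` = c(F = 1.37, M = 0.64),
                                             `5` = c(F = 1.13, M = 0.46)),
                            emb_sd = 0.8, emb_item_sd = 0.3,
                            recall_means = list(`1` = c(F = 68.8, M = 53.0),
                                                `2` = c(F = 68.1, M = 47.1),
                                                `5` = c(F = 65.5, M = 41.5)),
                            recall_sd = 15) {
  as.list(environment())
}

#' Generate per-day behavioral measures for one participant
#'
#' Draws the two embarrassment items (0-4 scale; their mean is the
#' composite) and the cued-recall percentage for Days 1, 2 and 5, around the
#' configured day x sex means with participant-level correlated deviations.
#' All values are clipped to their legal ranges.
#'
#' @param condition suppression condition label (carried through).
#' @param sex `"F"` or `"M"`.
#' @param params a [behavior_params()] list.
#' @param noise_sd multiplier on all random scatter (0 gives the configured
#'   means exactly).
#' @param seed optional integer seed.
#' @return data frame with one row per day: `day`, `emb_item1`, `emb_item2`,
#'   `embarrassment`, `recall_pct`.
#' @export
generate_behavioral <- function(condition = CONDITIONS, sex = c("F", "M"),
                                params = behavior_params(), noise_sd = 1,
                                seed = NULL) {
  condition <- match.arg(condition)
  sex <- match.arg(sex)
  if (!is.null(seed)) set.seed(seed)
  days <- c(1, 2, 5)
  # participant-level stable deviations
  re_emb <- stats::rnorm(1, 0, params$emb_sd * 0.7) * noise_sd
  re_rec <- stats::rnorm(1, 0, params$recall_sd * 0.8) * noise_sd
  out <- lapply(days, function(d) {
    mu_e <- params$emb_means[[as.character(d)]][[sex]] + re_emb +
      stats::rnorm(1, 0, params$emb_sd * 0.5) * noise_sd
    i1 <- min(max(mu_e + stats::rnorm(1, 0, params$emb_item_sd) * noise_sd, 0), 4)
    i2 <- min(max(mu_e + stats::rnorm(1, 0, params$emb_item_sd) * noise_sd, 0), 4)
    mu_r <- params$recall_means[[as.character(d)]][[sex]] + re_rec +
      stats::rnorm(1, 0, params$recall_sd * 0.5) * noise_sd
    data.frame(condition = condition, sex = sex, day = d,
               emb_item1 = i1, emb_item2 = i2,
               embarrassment = (i1 + i2) / 2,
               recall_pct = min(max(mu_r, 0), 100))
  })
  do.call(rbind, out)
}
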