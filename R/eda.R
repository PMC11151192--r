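#' Baseline skin-conductance level
#'
#' Mean of the trace over `[baseline_start + 120 s, playback_start - 20 s)`:
#' the average settles after 2 min of quiet sitting and ends 20 s before the
#' playback starts.
#'
#' @param trace an [scl_trace()].
#' @return baseline SCL in microsiemens.
#' @export
baseline_scl <- function(trace) {
  stopifnot(inherits(trace, "scl_trace"))
  a <- trace$markers$baseline_start + 120
  b <- trace$markers$playback_start - 20
  if (b <= a) stop("baseline window is empty (need >= 160 s before playback)")
  i0 <- floor(a * trace$rate) + 1L
  i1 <- ceiling(b * trace$rate)
  m <- mean(trace$samples[i0:min(i1, length(trace$samples))])
  if (!is.finite(m) || m <= 0) stop("nonpositive baseline SCL")
  m
}

#' Playback skin-conductance level
#'
#' Mean of the trace over the playback interval
#' `[playback_start, playback_end)`.
#'
#' @param trace an [scl_trace()].
#' @return playback SCL in microsiemens.
#' @export
playback_scl <- function(trace) {
  stopifnot(inherits(trace, "scl_trace"))
  a <- trace$markers$playback_start
  b <- trace$markers$playback_end
  i0 <- floor(a * trace$rate) + 1L
  i1 <- ceiling(b * trace$rate)
  if (i1 <= i0) stop("empty playback interval")
  mean(trace$samples[i0:min(i1, length(trace$samples))])
}

#' Session skin-conductance response statistic
#'
#' The SCR statistic per session: the playback/baseline SCL ratio on a
#' percent scale, square-root transformed (`scr0 = sqrt(100 * playback /
#' baseline)`, so playback equal to baseline gives 10), then controlled for
#' baseline SCL by per-day OLS residualization across the cohort with the
#' day grand mean added back. The percent scale is adopted so values land
#' on the magnitude of the published day means (12.7-15.5); the square root
#' corrects the ratio's skewness. Both the raw (`scr0`) and the
#' baseline-controlled (`scr`) statistic are returned.
#'
#' @param sessions data frame with columns `participant`, `day`,
#'   `baseline_uS`, `playback_uS` (one row per session).
#' @param control how to control for baseline SCL: `"residualize"` (per-day
#'   OLS, default) or `"none"` (leave to a downstream model covariate).
#' @return `sessions` with added columns `scr0` and `scr`.
#' @export
compute_scr <- function(sessions, control = c("residualize", "none")) {
  control <- match.arg(control)
  stopifnot(all(c("participant", "day", "baseline_uS", "playback_uS") %in%
                  names(sessions)))
  if (any(sessions$baseline_uS <= 0)) stop("baseline SCL must be positive")
  sessions$scr0 <- sqrt(100 * sessions$playback_uS / sessions$baseline_uS)
  sessions$scr <- sessions$scr0
  if (control == "residualize") {
    for (d in unique(sessions$day)) {
      i <- sessions$day == d
      if (sum(i) >= 3 && stats::sd(sessions$baseline_uS[i]) > 0) {
        f <- stats::lm(scr0 ~ baseline_uS, data = sessions[i, ])
        sessions$scr[i] <- stats::residuals(f) + mean(sessions$scr0[i])
      }
    }
  }
  sessions
}

#' SCR statistics for a cohort of synthesized traces
#'
#' Convenience wrapper: applies [baseline_scl()] and [playback_scl()] to a
#' list of traces and computes the cohort SCR table.
#'
#' @param traces named list of lists of [scl_trace()] objects,
#'   `traces[[participant]][[as.character(day)]]`.
#' @inheritParams compute_scr
#' @return SCR table as from [compute_scr()].
#' @export
scr_from_traces <- function(traces, control = "residualize") {
  rows <- list()
  for (p in names(traces)) {
    for (d in names(traces[[p]])) {
      tr <- traces[[p]][[d]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, day = as.numeric(d),
        baseline_uS = baseline_scl(tr), playback_uS = playback_scl(tr))
    }
  }
  compute_scr(do.call(rbind, rows), control = control)
}
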