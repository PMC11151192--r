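#' Sleep stage labels
#'
#' The closed set of stage labels used throughout the package.
#' @keywords internal
STAGES <- c("W", "N1", "N2", "SWS", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is the sequence of fixed-length (by default 30 s) sleep-stage
#' labels scored for one recording, together with optional arousal and
#' artifact annotations (intervals in seconds from recording start).
#'
#' @param stages character vector of stage labels, each one of
#'   `"W"`, `"N1"`, `"N2"`, `"SWS"`, `"REM"`.
#' @param epoch_length epoch duration in seconds (default 30).
#' @param arousals,artifacts data frames with numeric columns `onset_s` and
#'   `duration_s` (and optionally `label`); intervals must lie within the
#'   recording.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length = 30, arousals = NULL,
                      artifacts = NULL) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad) > 0L)
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(epoch_length) || epoch_length <= 0)
    stop("epoch_length must be positive")
  total <- length(stages) * epoch_length
  check_ann <- function(ann, what) {
    if (is.null(ann)) {
      return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                        label = character(0)))
    }
    ann <- as.data.frame(ann)
    stopifnot(all(c("onset_s", "duration_s") %in% names(ann)))
    if (!"label" %in% names(ann)) ann$label <- what
    if (nrow(ann) > 0 &&
        (any(ann$onset_s < 0) || any(ann$onset_s + ann$duration_s > total) ||
         any(ann$duration_s <= 0)))
      stop(what, " annotations must be positive-length intervals inside the recording")
    ann[c("onset_s", "duration_s", "label")]
  }
  structure(list(stages = stages, epoch_length = epoch_length,
                 arousals = check_ann(arousals, "arousal"),
                 artifacts = check_ann(artifacts, "artifact")),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x$stages), " epochs x ", x$epoch_length,
      " s (", length(x$stages) * x$epoch_length / 60, " min)\n", sep = "")
  print(table(factor(x$stages, levels = STAGES)))
  invisible(x)
}

#' Number of epochs in a hypnogram
#' @param hyp a [hypnogram()].
#' @return integer epoch count.
#' @export
n_epochs <- function(hyp) length(hyp$stages)

#' Write / read the hypnogram TSV dialect
#'
#' The on-disk dialect is a two-column tab-separated table
#' `epoch_index<TAB>stage` (0-based epoch index, stages W/N1/N2/SWS/REM).
#' Annotations travel separately as CSV with columns
#' `onset_s,duration_s,label`.
#'
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @rdname hypnogram-io
#' @export
write_hypnogram_tsv <- function(hyp, path) {
  df <- data.frame(epoch_index = seq_along(hyp$stages) - 1L,
                   stage = hyp$stages)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param epoch_length epoch duration in seconds for the read hypnogram.
#' @rdname hypnogram-io
#' @export
read_hypnogram_tsv <- function(path, epoch_length = 30) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[order(df$epoch_index), ]
  hypnogram(df$stage, epoch_length = epoch_length)
}

#' @param annotations data frame with `onset_s`, `duration_s`, `label`.
#' @rdname hypnogram-io
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname hypnogram-io
#' @export
read_annotations_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Stage durations, total sleep time and WASO
#'
#' Per-stage minutes are epoch counts times the epoch length; total sleep
#' time (TST) is the sum of N1, N2, SWS and REM minutes; wake after sleep
#' onset (WASO) is wake time occurring after the first sleep epoch.
#'
#' @param hyp a [hypnogram()].
#' @return a one-row data frame with columns `W`, `N1`, `N2`, `SWS`, `REM`
#'   (minutes), `TST` and `WASO`.
#' @export
stage_durations <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  epm <- hyp$epoch_length / 60
  counts <- table(factor(hyp$stages, levels = STAGES))
  mins <- as.numeric(counts) * epm
  names(mins) <- STAGES
  first_sleep <- match(TRUE, hyp$stages != "W")
  waso <- if (is.na(first_sleep)) 0 else
    sum(hyp$stages[seq.int(first_sleep, length(hyp$stages))] == "W") * epm
  out <- as.data.frame(as.list(mins))
  out$TST <- sum(mins[c("N1", "N2", "SWS", "REM")])
  out$WASO <- waso
  out
}

#' Segment a hypnogram into stage episodes
#'
#' A REM episode starts at a REM epoch and ends at the first run of at least
#' `term_epochs` (default 8, i.e. 4 min) consecutive epochs that are neither
#' REM nor interrupted by REM, or at the end of the recording. An SWS episode
#' starts at an SWS epoch and ends at the first REM epoch or the first run of
#' at least `term_epochs` consecutive W/N1/N2 epochs. Interior gaps shorter
#' than the terminating run remain inside the episode. Episode boundaries are
#' half-open `[start, end)` seconds from recording start, with `end` the end
#' of the last target-stage epoch of the episode.
#'
#' @param hyp a [hypnogram()].
#' @param stage `"REM"` or `"SWS"`.
#' @param term_epochs length of the terminating run, in epochs.
#' @return data frame with columns `stage`, `start_s`, `end_s`,
#'   `first_epoch`, `last_epoch` (1-based epoch indices of the first/last
#'   target-stage epoch).
#' @export
segment_episodes <- function(hyp, stage = c("REM", "SWS"), term_epochs = 8L) {
  stopifnot(inherits(hyp, "hypnogram"))
  stage <- match.arg(stage)
  s <- hyp$stages
  n <- length(s)
  el <- hyp$epoch_length
  # an epoch terminates an episode when it belongs to a long-enough run of
  # terminator labels (REM: any non-REM; SWS: W/N1/N2), or (SWS) is REM
  is_target <- s == stage
  terminator <- if (stage == "REM") !is_target else s %in% c("W", "N1", "N2")
  hard_stop <- if (stage == "SWS") s == "REM" else rep(FALSE, n)

  # run lengths of terminator epochs
  r <- rle(terminator)
  run_len <- rep(r$lengths, r$lengths)
  long_run <- terminator & run_len >= term_epochs

  out <- list()
  i <- 1L
  while (i <= n) {
    if (!is_target[i]) { i <- i + 1L; next }
    j <- i
    last_target <- i
    while (j <= n) {
      if (hard_stop[j] || long_run[j]) break
      if (is_target[j]) last_target <- j
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      stage = stage,
      start_s = (i - 1L) * el,
      end_s = last_target * el,
      first_epoch = i, last_epoch = last_target)
    i <- j
    # skip to after the terminating run / hard stop
    while (i <= n && !is_target[i]) i <- i + 1L
  }
  if (length(out) == 0L)
    return(data.frame(stage = character(0), start_s = numeric(0),
                      end_s = numeric(0), first_epoch = integer(0),
                      last_epoch = integer(0)))
  do.call(rbind, out)
}

# total length of the intersection of [a0,a1) with a set of intervals,
# counting every instant at most once
interval_overlap <- function(a0, a1, onsets, durs) {
  if (length(onsets) == 0L) return(0)
  lo <- pmax(a0, onsets)
  hi <- pmin(a1, onsets + durs)
  sum(pmax(0, hi - lo))
}

#' Stage fragmentation percentage
#'
#' Fragmentation of a stage is the time inside that stage's episodes spent
#' either in another stage (wake or other sleep) or in annotated arousals
#' that overlap epochs of the target stage, divided by the total minutes of
#' the target stage over the night, times 100. Any instant is counted once,
#' so interior wake that also carries an arousal annotation is not counted
#' twice. The value can exceed 100 because the denominator is stage time,
#' not episode time.
#'
#' @inheritParams segment_episodes
#' @return fragmentation in percent.
#' @export
fragmentation_pct <- function(hyp, stage = c("REM", "SWS"), term_epochs = 8L) {
  stopifnot(inherits(hyp, "hypnogram"))
  stage <- match.arg(stage)
  el <- hyp$epoch_length
  stage_min <- sum(hyp$stages == stage) * el / 60
  if (stage_min <= 0)
    stop("fragmentation undefined: no ", stage, " in the hypnogram")
  eps <- segment_episodes(hyp, stage, term_epochs)
  frag_s <- 0
  for (k in seq_len(nrow(eps))) {
    idx <- seq.int(eps$first_epoch[k], eps$last_epoch[k])
    other <- idx[hyp$stages[idx] != stage]
    frag_s <- frag_s + length(other) * el
    # arousal time overlapping target-stage epochs inside the episode
    tgt <- idx[hyp$stages[idx] == stage]
    for (e in tgt) {
      frag_s <- frag_s + interval_overlap((e - 1) * el, e * el,
                                          hyp$arousals$onset_s,
                                          hyp$arousals$duration_s)
    }
  }
  100 * (frag_s / 60) / stage_min
}

#' Table-style sleep summary for one night
#'
#' Combines [stage_durations()] with REM/SWS fragmentation into a one-row
#' summary of the night's architecture.
#'
#' @param hyp a [hypnogram()].
#' @return one-row data frame.
#' @export
sleep_summary <- function(hyp) {
  d <- stage_durations(hyp)
  d$REM_fragmentation_pct <-
    if (d$REM > 0) fragmentation_pct(hyp, "REM") else NA_real_
  d$SWS_fragmentation_pct <-
    if (d$SWS > 0) fragmentation_pct(hyp, "SWS") else NA_real_
  d
}

#' Percentage reduction between two group-mean stage durations
#'
#' Utility for stage-duration contrasts between suppression conditions:
#' the relative reduction, in percent, of the suppressed group's mean stage
#' duration versus the other group's.
#'
#' @param suppressed_min,intact_min group-mean minutes of the stage in the
#'   suppressed and intact condition.
#' @return `100 * (1 - suppressed_min / intact_min)`.
#' @export
stage_reduction_pct <- function(suppressed_min, intact_min) {
  if (intact_min <= 0) stop("intact duration must be positive")
  100 * (1 - suppressed_min / intact_min)
}
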