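# Independent brute-force oracles used to cross-check the fast
# implementations on small inputs.

# sample-by-sample spindle scan: same rules as the detector, written as a
# naive state machine over the envelope
brute_force_spindles <- function(env, mask, rate, M, peak_mult = 5,
                                 dwell_mult = 2, dwell_s = 0.25,
                                 max_dur_s = 3.0) {
  above <- env >= dwell_mult * M & mask
  # collect maximal runs by walking the samples
  segs <- list()
  i <- 1L
  n <- length(env)
  while (i <= n) {
    if (!above[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && above[j + 1L]) j <- j + 1L
    segs[[length(segs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  # merge runs closer than the dwell requirement
  gap <- round(dwell_s * rate)
  merged <- list()
  for (sg in segs) {
    if (length(merged) > 0 &&
        sg[1] - merged[[length(merged)]][2] - 1L < gap) {
      merged[[length(merged)]][2] <- sg[2]
    } else merged[[length(merged) + 1L]] <- sg
  }
  out <- NULL
  need <- round(dwell_s * rate)
  for (sg in merged) {
    seg <- env[sg[1]:sg[2]]
    pk <- which.max(seg)
    if (seg[pk] < peak_mult * M) next
    if (pk - 1L < need || length(seg) - pk < need) next
    if (length(seg) / rate > max_dur_s) next
    out <- rbind(out, data.frame(onset_s = (sg[1] - 1) / rate,
                                 duration_s = length(seg) / rate,
                                 peak_time_s = (sg[1] - 1 + pk - 1) / rate,
                                 peak_uv = seg[pk]))
  }
  if (is.null(out))
    out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_time_s = numeric(0), peak_uv = numeric(0))
  out
}

# direct unit-vector summation for circular statistics
brute_force_circ <- function(phases) {
  sx <- sum(cos(phases)); sy <- sum(sin(phases))
  list(mean = atan2(sy, sx), rvl = sqrt(sx^2 + sy^2) / length(phases))
}

# epoch_set over all epochs of a stage with no exclusions
all_stage_epochs <- function(hyp, stage, channel = "C3", rate = 256) {
  select_clean_epochs(hyp, stage, channel, rate = rate)
}

# constant-stage hypnogram of n epochs
flat_hypnogram <- function(stage, n) hypnogram(rep(stage, n))
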