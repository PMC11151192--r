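#' Effect-model constants of the synthetic cohort
#'
#' The condition x day structure of the simulated skin-conductance response
#' is driven by a latent "theta drive" (REM minutes times the participant's
#' REM theta gain): the overnight (Day 1 to Day 2) percent SCR change is a
#' linear function of the standardized drive plus noise, calibrated so the
#' condition means land near the published 20.1% (SWS suppressed, REM
#' intact) versus 6.1% (REM suppressed), and so the drive-change correlation
#' is strongly positive. The drive standardization constants (`drive_mu`,
#' `drive_sd`) are the generator's own stationary values under default
#' dynamics. Day-2-to-Day-5 changes are condition-mean draws.
#'
#' @param drive_mu,drive_sd standardization constants of the latent drive.
#' @param change_intercept,change_slope overnight percent change as a
#'   function of standardized drive.
#' @param change_sd residual SD of the overnight change (percent points).
#' @param day25_change_mean named per-condition mean Day-2-to-Day-5 percent
#'   change.
#' @param day25_change_sd its SD.
#' @param scr_day1_mean,scr_day1_sd Day-1 SCR statistic distribution.
#' @param theta_gain_meanlog,theta_gain_sdlog log-normal REM theta gain.
#' @param energy_intercept,energy_slope,energy_noise_sd mapping from latent
#'   drive to the measured REM theta energy scale (used at measures level;
#'   calibrated to the published group means 104.5 / 219.4).
#' @param tonic_meanlog,tonic_sdlog log-normal tonic SCL level (uS).
#' @param baseline_tst_mean,baseline_tst_sd baseline-night sleep duration
#'   (minutes).
#' @return list of class `cohort_effects`.
#' @export
cohort_effects <- function(drive_mu = 84, drive_sd = 48,
                           change_intercept = 13.1, change_slope = 11.3,
                           change_sd = 8,
                           day25_change_mean = c(REMS_SUPPR = -15.9,
                                                 SWS_SUPPR = -20.5),
                           day25_change_sd = 10.75,
                           scr_day1_mean = 13.75, scr_day1_sd = 2.0,
                           theta_gain_meanlog = log(1.4) - 0.5 * 0.25^2,
                           theta_gain_sdlog = 0.25,
                           energy_intercept = 0.4, energy_slope = 1.92,
                           energy_noise_sd = 30,
                           tonic_meanlog = log(5), tonic_sdlog = 0.3,
                           baseline_tst_mean = 429, baseline_tst_sd = 33) {
  as.list(environment())
}

#' Simulate a suppression cohort with known ground truth
#'
#' Generates a full two-condition cohort: per participant a suppression
#' hypnogram with forced-awakening log, a REM theta gain, skin-conductance
#' session targets for Days 1/2/5 driven by the latent theta drive, and
#' behavioral trajectories. Two fidelity levels are provided:
#'
#' * `"measures"` (default): the per-session measures (SCR statistic,
#'   embarrassment, recall, REM theta energy) are drawn directly from the
#'   calibrated effect model. This level is cheap enough for the
#'   many-seed direction and type-I simulations of the inference stage.
#' * `"signals"`: skin-conductance traces (500 Hz) and frontal EEG
#'   (256 Hz) are synthesized per participant, and the SCR / spectral
#'   pipelines are run on the raw signals to produce the measures. This
#'   level exercises the signal path end to end and is used at small scale.
#'
#' @param spec a [cohort_spec()].
#' @param level `"measures"` or `"signals"`.
#' @param effects a [cohort_effects()] list.
#' @param hyp_params hypnogram dynamics from `hypnogram_params()`.
#' @param eeg_params an [eeg_truth_params()] list (signals level; the
#'   participant theta gain overrides its `theta_gain`).
#' @param scl_par an [scl_params()] list (signals level).
#' @param beh_params a [behavior_params()] list.
#' @return list with `measures` (long session table: one row per
#'   participant x day), `participants` (per-participant table incl. ground
#'   truth), and at signals level `raw` (per-participant recordings,
#'   traces, truth ledgers).
#' @export
simulate_cohort <- function(spec, level = c("measures", "signals"),
                            effects = cohort_effects(),
                            hyp_params = hypnogram_params(),
                            eeg_params = eeg_truth_params(),
                            scl_par = scl_params(),
                            beh_params = behavior_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  level <- match.arg(level)
  n <- spec$n_per_condition
  conditions <- rep(CONDITIONS, each = n)
  sexes <- unlist(lapply(CONDITIONS, function(cc)
    rep(c("F", "M"), length.out = n)))
  npart <- 2L * n
  ids <- sprintf("p%03d", seq_len(npart))

  participants <- list()
  measures <- list()
  raw <- if (level == "signals") list() else NULL
  days <- c(1, 2, 5)

  for (i in seq_len(npart)) {
    cond <- conditions[i]
    res <- with_substream(spec$seed, i, salt = 11L, {
      g <- generate_hypnogram(spec, cond, params = hyp_params)
      sd_tab <- stage_durations(g$hypnogram)
      gain <- stats::rlnorm(1, effects$theta_gain_meanlog,
                            effects$theta_gain_sdlog)
      if (gain < 1) gain <- 1
      drive <- sd_tab$REM * gain
      z <- (drive - effects$drive_mu) / effects$drive_sd
      d12 <- effects$change_intercept + effects$change_slope * z +
        stats::rnorm(1, 0, effects$change_sd)
      d25 <- effects$day25_change_mean[[cond]] +
        stats::rnorm(1, 0, effects$day25_change_sd)
      scr1 <- stats::rnorm(1, effects$scr_day1_mean, effects$scr_day1_sd)
      scr_t <- c(scr1, scr1 * (1 + d12 / 100),
                 scr1 * (1 + d12 / 100) * (1 + d25 / 100))
      tonic <- stats::rlnorm(1, effects$tonic_meanlog, effects$tonic_sdlog)
      beh <- generate_behavioral(cond, sexes[i], params = beh_params)
      energy_meas <- effects$energy_intercept + effects$energy_slope * drive +
        stats::rnorm(1, 0, effects$energy_noise_sd)
      list(g = g, sd_tab = sd_tab, gain = gain, drive = drive,
           scr_t = scr_t, tonic = tonic, beh = beh,
           energy_meas = energy_meas,
           btst = stats::rnorm(1, effects$baseline_tst_mean,
                               effects$baseline_tst_sd))
    })
    part <- data.frame(
      participant = ids[i], condition = cond, sex = sexes[i],
      rem_min = res$sd_tab$REM, sws_min = res$sd_tab$SWS,
      n2_min = res$sd_tab$N2, tst_min = res$sd_tab$TST,
      waso_min = res$sd_tab$WASO,
      awakenings_n = nrow(res$g$awakenings),
      awakening_strength = if (nrow(res$g$awakenings) > 0)
        mean(res$g$awakenings$intensity) else NA_real_,
      baseline_tst_min = res$btst,
      theta_gain = res$gain, theta_drive = res$drive,
      rem_theta_energy = res$energy_meas)
    scr0 <- res$scr_t
    if (level == "signals") {
      traces <- list()
      for (k in seq_along(days)) {
        traces[[as.character(days[k])]] <- with_substream(
          spec$seed, i, salt = 20L + k,
          synthesize_scl(cond, days[k],
                         params = utils::modifyList(scl_par,
                                                    list(tonic_uS = res$tonic)),
                         multiplier = scr_to_multiplier(res$scr_t[k]),
                         rate = spec$eda_rate))
      }
      ep <- utils::modifyList(eeg_params, list(theta_gain = res$gain))
      eeg <- with_substream(spec$seed, i, salt = 31L,
                            synthesize_eeg(res$g$hypnogram, params = ep,
                                           channels = c("F3", "F4"),
                                           rate = spec$eeg_rate))
      raw[[ids[i]]] <- list(hypnogram = res$g$hypnogram,
                            awakenings = res$g$awakenings,
                            traces = traces, eeg = eeg)
    } else {
      # measures level: SCR values carry small measurement noise around the
      # session targets (what the trace pipeline would recover)
      scr0 <- with_substream(spec$seed, i, salt = 41L,
                             res$scr_t + stats::rnorm(3, 0, 0.1))
    }
    m <- data.frame(participant = ids[i], condition = cond, sex = sexes[i],
                    day = days, scr0 = scr0,
                    embarrassment = res$beh$embarrassment,
                    recall_pct = res$beh$recall_pct)
    participants[[i]] <- part
    measures[[i]] <- m
  }
  participants <- do.call(rbind, participants)
  measures <- do.call(rbind, measures)

  if (level == "signals") {
    # run the electrodermal pipeline on the synthesized traces
    traces <- lapply(raw, `[[`, "traces")
    scr_tab <- scr_from_traces(traces)
    measures$scr0 <- scr_tab$scr0[match(
      paste(measures$participant, measures$day),
      paste(scr_tab$participant, scr_tab$day))]
    measures$scr <- scr_tab$scr[match(
      paste(measures$participant, measures$day),
      paste(scr_tab$participant, scr_tab$day))]
    # run the spectral pipeline: REM theta energy from frontal EEG
    bins <- list()
    for (p in ids) {
      es <- select_clean_epochs(raw[[p]]$hypnogram, "REM", "F3",
                                rate = spec$eeg_rate)
      bins[[p]] <- epoch_psd(raw[[p]]$eeg$recording, es)
    }
    energy <- accumulate_energy(bins)
    mean_psd <- vapply(bins, function(m) mean(m), numeric(1))
    adj <- residualize_energy(energy, mean_psd, participants$condition,
                              participants$rem_min)
    participants$rem_theta_energy_raw <- band_energy(energy)[, "theta"]
    participants$rem_theta_energy <- band_energy(energy)[, "theta"]
    participants$rem_theta_energy_adj <- adj$bands[, "theta"]
  } else {
    measures$scr <- measures$scr0
  }
  measures <- merge(measures,
                    participants[c("participant", "awakenings_n",
                                   "baseline_tst_min", "rem_theta_energy")],
                    by = "participant", sort = FALSE)
  measures <- measures[order(measures$participant, measures$day), ]
  rownames(measures) <- NULL
  list(measures = measures, participants = participants, raw = raw)
}
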