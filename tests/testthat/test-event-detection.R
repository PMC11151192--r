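make_sigma_curve <- function(bumps, heights = 1) {
  f <- seq(8, 17, by = 0.1)
  p <- 10 / f  # 1/f background
  for (i in seq_along(bumps))
    p <- p + heights[min(i, length(heights))] *
      exp(-(f - bumps[i])^2 / (2 * 0.3^2))
  list(freq = f, psd = p)
}

test_that("individual sigma peak follows the higher-frequency rule", {
  cv <- make_sigma_curve(13.0)
  pk <- individual_sigma_peak(cv$freq, cv$psd)
  expect_lt(abs(pk$peak_hz - 13.0), 0.11)
  expect_equal(pk$band_hz, c(pk$peak_hz - 2, pk$peak_hz + 2))

  # two equal bumps: the higher-frequency one wins
  cv2 <- make_sigma_curve(c(11.2, 13.6), c(1, 1))
  expect_lt(abs(individual_sigma_peak(cv2$freq, cv2$psd)$peak_hz - 13.6), 0.11)

  # monotone curve with no bump signals the no-peak condition, and the
  # fallback substitutes the cohort mean
  f <- seq(8, 17, by = 0.1)
  expect_error(individual_sigma_peak(f, 10 / f),
               class = "somnaffect_no_sigma_peak")
  expect_equal(sigma_peak_or_default(f, 10 / f)$peak_hz, 13.47)
})

test_that("spindle detection finds a planted burst and applies the rules", {
  rate <- 256
  hyp <- flat_hypnogram("N2", 2)
  es <- all_stage_epochs(hyp, "N2")
  n <- 2 * 30 * rate
  band <- c(11.5, 15.5)

  # all-zeros signal: no events, no division problems
  expect_equal(nrow(detect_spindles(numeric(n), es, band)), 0)

  # background noise with one planted 13.5 Hz burst at 6x the background
  # rectified mean -> exactly one event containing the planted peak
  set.seed(8)
  bg <- as.numeric(stats::filter(rnorm(n, 0, 4), rep(1, 4), sides = 2))
  bg[is.na(bg)] <- 0
  env0 <- somnaffect:::spindle_envelope(bg, rate, band)
  t <- seq(-0.5, 0.5, by = 1 / rate)
  burst_amp <- 6 * mean(env0) / 0.64  # envelope ~ 0.64 x sinusoid peak
  burst <- burst_amp * exp(-t^2 / (2 * 0.25^2)) * cos(2 * pi * 13.5 * t)
  x <- bg
  peak_at <- 30 * rate
  x[peak_at + seq_along(t) - round(length(t) / 2)] <-
    x[peak_at + seq_along(t) - round(length(t) / 2)] + burst
  ev <- detect_spindles(x, es, band)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$peak_time_s, peak_at / rate - 0.1)
  expect_lt(ev$peak_time_s, peak_at / rate + 0.1)
  expect_gte(ev$duration_s, 0.5)
  expect_lte(ev$duration_s, 3.0)

  # the same burst stretched beyond 3 s above the dwell threshold is
  # rejected by the length cutoff
  tl <- seq(-1.9, 1.9, by = 1 / rate)
  long_burst <- burst_amp * cos(2 * pi * 13.5 * tl)  # no taper: stays high
  x2 <- bg
  x2[peak_at + seq_along(tl) - round(length(tl) / 2)] <-
    x2[peak_at + seq_along(tl) - round(length(tl) / 2)] + long_burst
  expect_equal(nrow(detect_spindles(x2, es, band)), 0)

  # artifact overlap discards the event
  ev3 <- detect_spindles(x, es, band,
                         artifacts = data.frame(onset_s = peak_at / rate - 1,
                                                duration_s = 2))
  expect_equal(nrow(ev3), 0)

  # thresholds are signal-relative: rescaling changes nothing
  ev4 <- detect_spindles(x * 7.3, es, band)
  expect_equal(ev4$onset_s, ev$onset_s)
  expect_equal(ev4$duration_s, ev$duration_s)
})

test_that("brute-force scan reproduces spindle detection exactly", {
  rate <- 256
  hyp <- flat_hypnogram("N2", 2)  # 60-s signal
  es <- all_stage_epochs(hyp, "N2")
  band <- c(11.5, 15.5)
  set.seed(14)
  for (r in 1:5) {
    x <- 10 * rnorm(2 * 30 * rate)
    # plant a few random bursts of varying strength so some pass, some fail
    t <- seq(-0.5, 0.5, by = 1 / rate)
    for (k in 1:6) {
      amp <- runif(1, 5, 60)
      at <- sample(seq(rate, 2 * 30 * rate - rate), 1)
      idx <- at + seq_along(t) - round(length(t) / 2)
      x[idx] <- x[idx] + amp * exp(-t^2 / (2 * 0.22^2)) *
        cos(2 * pi * 13.5 * t)
    }
    ev <- detect_spindles(x, es, band)
    env <- somnaffect:::spindle_envelope(x, rate, band)
    mask <- epoch_mask(es, length(x))
    oracle <- brute_force_spindles(env, mask, rate, mean(env[mask]))
    expect_equal(nrow(ev), nrow(oracle))
    expect_equal(ev$onset_s, oracle$onset_s)
    expect_equal(ev$duration_s, oracle$duration_s)
    expect_equal(ev$peak_time_s, oracle$peak_time_s)
  }
})

test_that("spindle density is count over stage minutes", {
  expect_equal(spindle_density(data.frame()[0, ], 30), 0)
  # Table-1 scale: 120 events in 30 min of SWS is a density of 4/min
  expect_equal(spindle_density(120, 30), 4)
  expect_equal(spindle_density(240, 60), 4)
  expect_error(spindle_density(10, 0), "positive")
})

test_that("slow-oscillation detection implements the cycle rules", {
  rate <- 256
  hyp <- flat_hypnogram("SWS", 2)
  es <- all_stage_epochs(hyp, "SWS")
  n <- 2 * 30 * rate
  tt <- seq(0, by = 1 / rate, length.out = n)

  # all-zeros: empty
  expect_equal(nrow(detect_slow_oscillations(numeric(n), es)), 0)

  # pure 0.75 Hz sinusoid: every interior cycle qualifies (each cycle
  # equals the mean, and 0.9 x a negative mean is above the peak)
  x <- -100 * sin(2 * pi * 0.75 * tt)
  so <- detect_slow_oscillations(x, es)
  n_cycles <- floor(60 * 0.75) - 1
  expect_gte(nrow(so), n_cycles - 2)
  expect_true(all(so$neg_peak_uv < 0 & so$pos_peak_uv > 0))
  expect_true(all(so$end_s - so$start_s >= 0.8 & so$end_s - so$start_s <= 5))

  # pure 3 Hz sinusoid: 0.33-s cycles fall below the 0.8-s minimum
  x3 <- -100 * sin(2 * pi * 3 * tt)
  expect_equal(nrow(detect_slow_oscillations(x3, es)), 0)

  # relative thresholds: rescaling changes nothing
  so2 <- detect_slow_oscillations(x * 0.05, es)
  expect_equal(so2$start_s, so$start_s)
})

test_that("detected events are disjoint in time per channel and stage", {
  spec <- cohort_spec(seed = 3)
  g <- generate_hypnogram(spec, "SWS_SUPPR", seed = 12)
  syn <- synthesize_eeg(g$hypnogram, channels = "C3",
                        stages = c("N2", "SWS"), seed = 13)
  es <- select_clean_epochs(g$hypnogram, "N2", "C3", rate = 256,
                            n_samples = syn$recording$n_samples)
  ev <- detect_spindles(syn$recording$signals$C3, es,
                        structure(list(band_hz = syn$truth$center_freq +
                                         c(-2, 2)), class = "sigma_peak"),
                        artifacts = g$hypnogram$artifacts)
  ev <- ev[order(ev$onset_s), ]
  expect_true(all(diff(ev$onset_s) >=
                    ev$duration_s[-nrow(ev)] - 1e-9))
  so <- detect_slow_oscillations(syn$recording$signals$C3, es,
                                 artifacts = g$hypnogram$artifacts)
  so <- so[order(so$start_s), ]
  expect_true(all(so$start_s[-1] >= so$end_s[-nrow(so)] - 1e-9))
})
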