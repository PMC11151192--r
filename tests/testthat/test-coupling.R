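test_that("coupling uses half-open cycle intervals", {
  sp <- data.frame(peak_time_s = c(1.0, 2.2, 3.0, 5.0))
  so <- data.frame(start_s = c(1.0, 2.1), end_s = c(2.0, 3.0))
  out <- couple_events(sp, so)
  # peak exactly at a cycle start is coupled; exactly at its end is not
  expect_equal(out$peak_time_s, c(1.0, 2.2))
  expect_equal(out$so_index, c(1, 2))
  # no slow oscillations -> nothing coupled
  expect_equal(nrow(couple_events(sp, so[0, ])), 0)
  # a peak 0.1 s inside a 1.2-s cycle is coupled
  out2 <- couple_events(data.frame(peak_time_s = 10.1),
                        data.frame(start_s = 10, end_s = 11.2))
  expect_equal(nrow(out2), 1)
})

test_that("Hilbert phase convention anchors zero at the positive peak", {
  rate <- 100
  tt <- seq(0, 60, by = 1 / rate)
  x <- cos(2 * pi * 0.5 * tt)  # maxima at t = 0, 2, 4, ...
  # peak at the cosine maximum -> phase 0
  ph <- so_phase_at_peaks(x, rate, peak_times = c(10, 20, 30))
  expect_true(all(abs(ph) < 0.05))
  # at the minimum -> +/- pi
  ph2 <- so_phase_at_peaks(x, rate, peak_times = c(11, 21))
  expect_true(all(abs(abs(ph2) - pi) < 0.05))
  # a quarter cycle after the maximum -> +pi/2 (phase increases with time)
  ph3 <- so_phase_at_peaks(x, rate, peak_times = c(10.5, 20.5))
  expect_true(all(abs(ph3 - pi / 2) < 0.05))
  expect_error(so_phase_at_peaks(x, rate, peak_times = 1000), "outside")
})

test_that("coupling summary matches closed-form circular statistics", {
  # degenerate concentration
  s <- coupling_summary(rep(1.2, 7), n_spindles = 10)
  expect_equal(s$mean_phase_rad, 1.2)
  expect_equal(s$rvl, 1.0)
  expect_equal(s$n_oc, 7)

  # two vectors at +/-0.4 around 0: RVL = cos(0.4), both within the window
  s2 <- coupling_summary(c(0.4, -0.4), n_spindles = 2)
  expect_equal(s2$rvl, cos(0.4), tolerance = 1e-12)
  expect_equal(abs(s2$mean_phase_rad), 0, tolerance = 1e-12)
  expect_equal(s2$n_oc, 2)

  # uniform phases: RVL near the Rayleigh null expectation sqrt(pi/4)/sqrt(n)
  set.seed(9)
  u <- runif(10000, -pi, pi)
  s3 <- coupling_summary(u, n_spindles = 10000)
  expect_lt(s3$rvl, 0.03)

  # empty input: zero counts and flagged mean, not an error
  s4 <- coupling_summary(numeric(0), n_spindles = 5)
  expect_equal(s4$n_coupled, 0)
  expect_true(is.na(s4$mean_phase_rad))
  expect_error(coupling_summary(c(1, 2), 1), "n_spindles")
})

test_that("RVL and mean phase equal direct vector summation to 1e-12", {
  set.seed(4)
  for (r in 1:10) {
    ph <- runif(sample(5:500, 1), -pi, pi)
    bf <- brute_force_circ(ph)
    expect_equal(circ_mean(ph), bf$mean, tolerance = 1e-12)
    expect_equal(circ_rvl(ph), bf$rvl, tolerance = 1e-12)
  }
})

test_that("phase statistics are rotation-equivariant", {
  set.seed(6)
  ph <- rvonmises(150, mu = -1.1, kappa = 3)
  base <- coupling_summary(ph, 150)
  for (shift in c(0.7, 2.9, -2.2)) {
    s <- coupling_summary(somnaffect:::wrap_pi(ph + shift), 150)
    expect_equal(s$rvl, base$rvl, tolerance = 1e-12)
    expect_equal(s$n_oc, base$n_oc)
    expect_lt(circ_dist(s$mean_phase_rad, base$mean_phase_rad + shift), 1e-9)
  }
})

test_that("planted von Mises coupling is recovered through the summary", {
  set.seed(18)
  for (mu in c(0, 1.4, -2.0)) {
    ph <- rvonmises(200, mu = mu, kappa = 5)
    s <- coupling_summary(ph, 200)
    expect_lt(circ_dist(s$mean_phase_rad, mu), 0.15)
    expect_lt(abs(s$rvl - vonmises_rvl(5)), 0.05)
  }
})

test_that("channel averaging combines summaries, not pooled phases", {
  a <- coupling_summary(rvonmises(80, 0.5, 4), 100)
  b <- coupling_summary(rvonmises(60, 0.7, 4), 90)
  avg <- average_channel_summaries(rbind(a, b))
  expect_equal(avg$rvl, (a$rvl + b$rvl) / 2)
  expect_equal(avg$n_oc, (a$n_oc + b$n_oc) / 2)
  expect_equal(avg$n_spindles, 95)
})

test_that("end-to-end: planted coupled spindles recover the locking phase", {
  # one long SWS block with dense, strongly coupled spindles
  hyp <- flat_hypnogram("SWS", 40)
  par <- eeg_truth_params(so_rate_sws = 8, spindle_rate_sws = 8,
                          coupled_frac_sws = 0.9, coupling_mu = 0.3,
                          coupling_kappa = 8)
  syn <- synthesize_eeg(hyp, par, channels = "C3", seed = 44)
  x <- syn$recording$signals$C3
  es <- all_stage_epochs(hyp, "SWS")
  band <- structure(list(band_hz = syn$truth$center_freq + c(-2, 2)),
                    class = "sigma_peak")
  sp <- detect_spindles(x, es, band)
  so <- detect_slow_oscillations(x, es)
  coup <- couple_events(sp, so)
  expect_gt(nrow(coup), 50)
  ph <- so_phase_at_peaks(x, 256, coup$peak_time_s)
  s <- coupling_summary(ph, nrow(sp))
  # the measured locking phase approximates the planted von Mises mean
  expect_lt(circ_dist(s$mean_phase_rad, 0.3), 0.25)
  expect_gt(s$rvl, 0.5)
  expect_lte(s$n_oc, s$n_coupled)
})
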