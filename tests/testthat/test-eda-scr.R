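flat_trace <- function(level, rate = 100, baseline_s = 300, playback_s = 90,
                       recovery_s = 60) {
  n <- (baseline_s + playback_s + recovery_s) * rate
  scl_trace(rep(level, n), rate,
            markers = list(baseline_start = 0, playback_start = baseline_s,
                           playback_end = baseline_s + playback_s))
}

test_that("baseline window is [start + 120 s, playback - 20 s)", {
  tr <- flat_trace(5)
  expect_equal(baseline_scl(tr), 5)

  # 2 uS before 120 s, 6 uS after: the early segment is excluded
  x <- rep(2, 450 * 100)
  x[(120 * 100 + 1):length(x)] <- 6
  tr2 <- scl_trace(x, 100, list(baseline_start = 0, playback_start = 300,
                                playback_end = 390))
  expect_equal(baseline_scl(tr2), 6)

  # additive shift of the whole trace shifts the baseline equally
  tr3 <- scl_trace(tr2$samples + 1, 100, tr2$markers)
  expect_equal(baseline_scl(tr3), baseline_scl(tr2) + 1)

  # too-short baseline window is an error
  short <- scl_trace(rep(5, 200 * 100), 100,
                     list(baseline_start = 0, playback_start = 130,
                          playback_end = 190))
  expect_error(baseline_scl(short), "160 s")
})

test_that("playback SCL is the mean over the playback interval", {
  expect_equal(playback_scl(flat_trace(8)), 8)
  # half 6, half 10 during playback -> 8
  x <- rep(5, 450 * 100)
  x[(300 * 100 + 1):(345 * 100)] <- 6
  x[(345 * 100 + 1):(390 * 100)] <- 10
  tr <- scl_trace(x, 100, list(baseline_start = 0, playback_start = 300,
                               playback_end = 390))
  expect_equal(playback_scl(tr), 8)
  # resampling the trace leaves the means (nearly) unchanged
  x2 <- x[seq(1, length(x), by = 4)]  # 25 Hz
  tr2 <- scl_trace(x2, 25, tr$markers)
  expect_equal(playback_scl(tr2), 8, tolerance = 1e-3)
})

test_that("SCR statistic is the square-root percent ratio", {
  sess <- data.frame(participant = sprintf("p%d", 1:6), day = 1,
                     baseline_uS = c(5, 5, 4, 6, 5, 3),
                     playback_uS = c(5, 5, 4, 6, 5, 3))
  out <- compute_scr(sess)
  # playback = baseline -> sqrt(100) = 10
  expect_true(all(out$scr0 == 10))
  # playback = 4 x baseline -> 20
  sess2 <- within(sess, playback_uS <- 4 * baseline_uS)
  expect_true(all(compute_scr(sess2)$scr0 == 20))
  expect_error(compute_scr(within(sess, baseline_uS <- 0)), "positive")
})

test_that("baseline control is a per-day residualization", {
  set.seed(41)
  n <- 30
  sess <- data.frame(participant = sprintf("p%02d", 1:n), day = 1,
                     baseline_uS = runif(n, 3, 8))
  # construct scr0 uncorrelated with baseline: controlled equals scr0 up to
  # centering noise of the regression
  sess$playback_uS <- sess$baseline_uS * rnorm(n, 2, 0.2)^2 / 1
  out <- compute_scr(sess)
  fit <- lm(scr0 ~ baseline_uS, data = out)
  manual <- residuals(fit) + mean(out$scr0)
  expect_equal(out$scr, manual, ignore_attr = TRUE)
  # with control = "none" the raw statistic is carried through
  expect_equal(compute_scr(sess, control = "none")$scr, out$scr0)
})

test_that("scr0 is scale-invariant and monotone in playback level", {
  tr <- flat_trace(5)
  s1 <- sqrt(100 * playback_scl(tr) / baseline_scl(tr))
  tr2 <- scl_trace(tr$samples * 3.7, tr$rate, tr$markers)
  s2 <- sqrt(100 * playback_scl(tr2) / baseline_scl(tr2))
  expect_equal(s1, s2)
})

test_that("synthesized SCL traces obey the multiplier contract", {
  par0 <- scl_params(noise_sd = 0, drift_sd = 0)
  # multiplier 1: playback mean equals baseline mean exactly
  tr <- synthesize_scl("SWS_SUPPR", 1, par0, multiplier = 1, rate = 100)
  expect_equal(playback_scl(tr), baseline_scl(tr))
  # multiplier 4: playback mean is 4 x baseline mean
  tr4 <- synthesize_scl("SWS_SUPPR", 1, par0, multiplier = 4, rate = 100)
  expect_equal(playback_scl(tr4), 4 * baseline_scl(tr4))
  expect_error(synthesize_scl("SWS_SUPPR", 3), "day")
  expect_error(synthesize_scl("SWS_SUPPR", 1, scl_params(tonic_uS = -1)),
               "tonic")
})

test_that("default SWS_SUPPR traces reproduce the 20.1% overnight rise", {
  changes <- sapply(1:60, function(i) {
    t1 <- synthesize_scl("SWS_SUPPR", 1, rate = 250, seed = i)
    t2 <- synthesize_scl("SWS_SUPPR", 2, rate = 250, seed = 5000 + i)
    s1 <- sqrt(100 * playback_scl(t1) / baseline_scl(t1))
    s2 <- sqrt(100 * playback_scl(t2) / baseline_scl(t2))
    100 * (s2 - s1) / s1
  })
  expect_lt(abs(mean(changes) - 20.1), 2)
})

test_that("SCL trace and marker CSVs round-trip", {
  tr <- synthesize_scl("REMS_SUPPR", 1, scl_params(baseline_s = 170,
                                                   recovery_s = 10),
                       rate = 50, seed = 2)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_scl_csv(tr, p1, p2)
  tr2 <- read_scl_csv(p1, p2)
  expect_equal(tr2$rate, 50)
  expect_equal(tr2$markers$playback_start, tr$markers$playback_start)
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-6)
})
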