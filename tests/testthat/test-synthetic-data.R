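spec <- cohort_spec(seed = 101)

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_per_condition = 0), "n_per_condition")
  expect_error(cohort_spec(eeg_rate = -1))
  expect_s3_class(spec, "cohort_spec")
})

test_that("hypnogram generator covers the sleep opportunity deterministically", {
  g <- generate_hypnogram(spec, "REMS_SUPPR", seed = 4)
  # 480 min / 30 s = 960 epochs
  expect_length(g$hypnogram$stages, 960)
  # identical seed -> identical stage sequence and awakening log
  g2 <- generate_hypnogram(spec, "REMS_SUPPR", seed = 4)
  expect_identical(g$hypnogram$stages, g2$hypnogram$stages)
  expect_identical(g$awakenings, g2$awakenings)
  # awakenings interrupt the suppressed stage only
  expect_true(all(g$awakenings$stage_interrupted == "REM"))
  expect_true(all(g$awakenings$intensity %in% 1:4))
  expect_error(generate_hypnogram(spec, "NO_SUPPR"), "arg")
})

test_that("suppressed REM lasts about half of the intact condition's", {
  rem <- sapply(1:60, function(r)
    stage_durations(generate_hypnogram(spec, "REMS_SUPPR",
                                       seed = r)$hypnogram)$REM)
  rem_i <- sapply(1:60, function(r)
    stage_durations(generate_hypnogram(spec, "SWS_SUPPR",
                                       seed = 1000 + r)$hypnogram)$REM)
  ratio <- mean(rem) / mean(rem_i)
  expect_gt(ratio, 0.42)
  expect_lt(ratio, 0.62)
})

test_that("suppression fragments the suppressed stage (Table-1 direction)", {
  frag <- function(cond, stage, seeds) {
    mean(sapply(seeds, function(r) {
      h <- generate_hypnogram(spec, cond, seed = r)$hypnogram
      if (sum(h$stages == stage) == 0) return(NA)
      fragmentation_pct(h, stage)
    }), na.rm = TRUE)
  }
  expect_gt(frag("REMS_SUPPR", "REM", 1:15), frag("SWS_SUPPR", "REM", 1:15))
  expect_gt(frag("SWS_SUPPR", "SWS", 1:15), frag("REMS_SUPPR", "SWS", 1:15))
})

test_that("planted events lie inside epochs of their nominal stage", {
  g <- generate_hypnogram(spec, "SWS_SUPPR", seed = 9)
  syn <- synthesize_eeg(g$hypnogram, channels = "C3", seed = 10)
  tr <- syn$truth
  stage_of <- function(t) g$hypnogram$stages[floor(t / 30) + 1]
  sp <- tr$spindles
  expect_gt(nrow(sp), 0)
  expect_true(all(stage_of(sp$onset_s) == sp$stage))
  expect_true(all(stage_of(sp$onset_s + sp$duration_s - 1e-9) == sp$stage))
  so <- tr$slow_oscillations
  expect_gt(nrow(so), 0)
  expect_true(all(stage_of(so$start_s) == so$stage))
  expect_true(all(stage_of(so$end_s - 1e-9) == so$stage))
  # planted coupling phases are proper angles
  ph <- sp$so_phase[sp$coupled]
  expect_true(all(ph > -pi & ph <= pi))
  expect_error(synthesize_eeg(hypnogram(character(0))), "epoch")
})

test_that("identity configuration yields pure 1/f noise", {
  hyp <- flat_hypnogram("N2", 20)
  par0 <- eeg_truth_params(theta_gain = 1, sws_delta_gain = 1,
                           so_rate_sws = 0, so_rate_n2 = 0,
                           spindle_rate_n2 = 0, spindle_rate_sws = 0)
  syn <- synthesize_eeg(hyp, par0, channels = "C3", seed = 2)
  expect_equal(nrow(syn$truth$spindles), 0)
  expect_equal(nrow(syn$truth$slow_oscillations), 0)
  # Welch log-log slope matches the configured exponent (1/f)
  W <- welch_psd(syn$recording$signals$C3, 256)
  sel <- W$freq >= 1 & W$freq <= 30
  slope <- coef(lm(log10(W$psd[sel]) ~ log10(W$freq[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.15)
})

test_that("theta gain strictly raises REM theta Welch power", {
  hyp <- flat_hypnogram("REM", 10)
  pow <- sapply(c(1, 1.6, 2.4), function(g) {
    syn <- synthesize_eeg(hyp, eeg_truth_params(theta_gain = g),
                          channels = "C3", seed = 5)
    W <- welch_psd(syn$recording$signals$C3, 256)
    mean(W$psd[W$freq > 4 & W$freq <= 8])
  })
  expect_true(all(diff(pow) > 0))
  # gain ~ measured power ratio (multiplicative theta elevation)
  expect_lt(abs(pow[3] / pow[1] - 2.4), 0.5)
})

test_that("von Mises sampler hits its mean and concentration", {
  set.seed(33)
  ph <- rvonmises(200, mu = 0, kappa = 5)
  expect_lt(abs(circ_mean(ph)), 0.15)
  expect_lt(abs(circ_rvl(ph) - vonmises_rvl(5)), 0.05)
  # kappa = 0 is the uniform circle
  u <- rvonmises(4000, 0, 0)
  expect_lt(circ_rvl(u), 0.05)
  expect_error(rvonmises(5, 0, -1), "kappa")
})

test_that("cohort simulation is bit-identical under one seed", {
  sp <- cohort_spec(n_per_condition = 3, seed = 77)
  a <- simulate_cohort(sp)
  b <- simulate_cohort(sp)
  expect_identical(a$measures, b$measures)
  expect_identical(a$participants, b$participants)
  # different seed -> different cohort
  c3 <- simulate_cohort(cohort_spec(n_per_condition = 3, seed = 78))
  expect_false(identical(a$measures$scr0, c3$measures$scr0))
  # long format: one row per participant x day
  expect_equal(nrow(a$measures), 3 * 2 * 3)
})

test_that("EDF round-trips a synthetic recording at 16-bit precision", {
  hyp <- flat_hypnogram("N2", 2)
  syn <- synthesize_eeg(hyp, channels = c("C3", "A1", "A2"), seed = 3)
  path <- tempfile(fileext = ".edf")
  write_edf(syn$recording, path)
  rec2 <- read_edf(path)
  expect_identical(names(rec2$signals), c("C3", "A1", "A2"))
  expect_equal(rec2$rate, 256)
  rng <- diff(range(syn$recording$signals$C3))
  expect_lt(max(abs(rec2$signals$C3 - syn$recording$signals$C3)),
            rng / 65535 * 2)
})
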