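test_that("outlier rule is a conjunction on static/change, OR on residual", {
  base <- rep(c(-1, 1), 5)
  # deviant in both static and change: flagged
  r <- flag_outliers(c(base, 10), c(base, 9))
  expect_true(r$flag[11])
  expect_equal(sum(r$flag), 1)
  expect_match(r$log$reason, "static\\+change")

  # deviant in static only: not flagged
  r2 <- flag_outliers(c(base, 10), c(base, 0), residual = c(base, 0.5))
  expect_false(any(r2$flag))

  # large residual alone flags
  r3 <- flag_outliers(c(base, 0), c(base, 0), residual = c(base, 12))
  expect_true(r3$flag[11])
  expect_equal(r3$log$reason, "residual")

  expect_error(flag_outliers(rep(1, 10), rep(0, 10)), "zero variance")
  expect_error(flag_outliers(1:2, 1:2), "at least 3")
})

cohort <- simulate_cohort(cohort_spec(n_per_condition = 15, seed = 404))

test_that("the mixed model reports F tests, AICc and the structure label", {
  f <- fit_lmm(cohort$measures, "scr", "condition")
  expect_s3_class(f, "somnaffect_lmm")
  expect_true(all(c("condition", "day_f", "condition:day_f") %in%
                    f$anova$term))
  expect_true(all(f$anova$df2 > 0))
  expect_true(all(f$anova$p >= 0 & f$anova$p <= 1))
  expect_true(is.finite(f$aicc))
  expect_true(f$converged)

  fc <- fit_lmm(cohort$measures, "scr", "condition", structure = "CSH")
  expect_equal(fc$structure_fitted, "CSH")
  fu <- fit_lmm(cohort$measures, "scr", "condition", structure = "FA1")
  expect_equal(fu$structure_fitted, "general symmetric")
  expect_true(is.finite(fc$aicc) && is.finite(fu$aicc))

  # covariates enter additively
  fcov <- fit_lmm(cohort$measures, "scr", "condition",
                  covariates = "awakenings_n")
  expect_true("awakenings_n" %in% fcov$anova$term)

  # a single extracted term
  tm <- lmm_term(f, "condition:day_f")
  expect_equal(tm$df1, 2)
  expect_error(lmm_term(f, "nonsense"), "not in model")
})

test_that("missing sessions are tolerated without listwise deletion", {
  d <- cohort$measures
  d$scr[d$participant == "p001" & d$day == 2] <- NA
  d <- d[!(d$participant == "p002" & d$day == 5), ]
  f <- fit_lmm(d, "scr", "condition")
  expect_true(is.finite(lmm_term(f, "condition:day_f")$p))
  # participants with partial data still contribute
  expect_true("p001" %in% rownames(lme4::ranef(f$fit)$participant))
})

test_that("a planted condition-by-time effect is detected at scale", {
  big <- simulate_cohort(cohort_spec(n_per_condition = 60, seed = 7))
  f <- fit_lmm(big$measures, "scr", "condition")
  expect_lt(lmm_term(f, "condition:day_f")$p, 0.01)
  # and the direction matches: larger overnight change with suppressed SWS
  wide <- reshape(big$measures[c("participant", "condition", "day", "scr")],
                  idvar = c("participant", "condition"), timevar = "day",
                  direction = "wide")
  ch <- wide$scr.2 - wide$scr.1
  expect_gt(mean(ch[wide$condition == "SWS_SUPPR"]),
            mean(ch[wide$condition == "REMS_SUPPR"]))
})

test_that("AICc prefers the true covariance structure in most fits", {
  # data generated under compound symmetry (random intercept + iid noise)
  set.seed(88)
  wins <- 0
  nsim <- 30
  for (s in 1:nsim) {
    n <- 40
    b <- rnorm(n, 0, 2)
    d <- expand.grid(participant = sprintf("p%02d", 1:n), day = c(1, 2, 5))
    d$condition <- rep(rep(CONDITIONS, each = n / 2), 3)
    d$y <- 10 + b[as.integer(factor(d$participant))] + rnorm(nrow(d))
    fc <- fit_lmm(d, "y", "condition", structure = "CSH")
    fu <- fit_lmm(d, "y", "condition", structure = "UN")
    if (fc$aicc < fu$aicc) wins <- wins + 1
  }
  expect_gt(wins / nsim, 0.5)
})

test_that("planted-effect power materially exceeds the nominal level", {
  # paper-sized cohorts at default (planted) effects
  rej <- 0
  nsim <- 40
  for (s in 1:nsim) {
    co <- simulate_cohort(cohort_spec(n_per_condition = 15, seed = 9000 + s))
    f <- fit_lmm(co$measures, "scr", "condition")
    if (lmm_term(f, "condition:day_f")$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / nsim, 0.3)
})

test_that("Bonferroni families multiply and cap p-values", {
  expect_equal(bonferroni_family(0.01, 6), 0.06)
  expect_equal(bonferroni_family(0.5, 3), 1)
  p <- c(0.001, 0.02, 0.3)
  adj <- bonferroni_family(p, 6)
  expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in raw p
  expect_error(bonferroni_family(c(0.1, 0.2), 1), "family size")
})

test_that("follow-up families compute the declared contrasts", {
  d <- cohort$measures
  ft <- followups(d, "scr", "paired_days")
  expect_equal(nrow(ft), 3)
  expect_true(all(ft$p_bonf >= ft$p_raw))
  fr <- followups(d, "scr", "condition_regression", change = c(1, 2),
                  family_m = 2)
  expect_equal(nrow(fr), 1)
  fc <- followups(d, "scr", "correlation", feature = "rem_theta_energy",
                  change = c(1, 2), family_m = 6)
  expect_true(abs(fc$estimate) <= 1)
  expect_equal(fc$p_bonf, min(1, fc$p_raw * 6))
})

test_that("nonparametric equivalents handle their degenerate cases", {
  d <- cohort$measures
  # identical group distributions: Mann-Whitney p = 1 under tie handling
  d0 <- d
  idx <- ave(seq_len(nrow(d0)), d0$condition, d0$day, FUN = seq_along)
  d0$scr <- idx * d0$day  # same change-score set in both conditions
  mw <- nonparametric_followups(d0, "scr", "mann_whitney")
  expect_equal(mw$p_raw, 1, tolerance = 1e-6)
  # identical repeated columns: Friedman statistic 0
  d1c <- d
  d1c$scr <- as.numeric(factor(d1c$participant))  # constant across days
  fr <- nonparametric_followups(d1c, "scr", "friedman")
  expect_equal(unname(fr$statistic), 0)
  # perfectly monotone pairs: Spearman rho = 1
  d1 <- d
  d1$rem_theta_energy <- as.numeric(factor(d1$participant))
  d1$scr <- ave(d1$rem_theta_energy, d1$day) + d1$rem_theta_energy + d1$day
  sp <- nonparametric_followups(d1, "scr", "spearman",
                                feature = "rem_theta_energy", on = "static")
  expect_equal(unname(sp$statistic), 1)
  # real data: all three run and adjust within their families
  for (ty in c("friedman", "mann_whitney")) {
    out <- nonparametric_followups(d, "scr", ty, family_m = 3)
    expect_true(out$p_bonf <= 1 && out$p_bonf >= out$p_raw)
  }
})
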