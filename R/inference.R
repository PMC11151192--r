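#' Flag outlying observations
#'
#' An observation is flagged when it deviates at least `threshold` (default
#' 2.5) sample SDs from the sample mean **both** in its static variable
#' (e.g. Day-1 SCR) and in its change score (e.g. the Day-1-to-Day-2
#' change), **or** in its fitted-versus-residual value. Flags are logged
#' with reasons; zero-variance inputs are an error.
#'
#' @param static,change numeric vectors of the same length.
#' @param residual optional residual vector (model fit diagnostics).
#' @param threshold SD multiplier.
#' @return list with `flag` (logical) and `log` (data frame of flagged
#'   indices with reasons and z-scores).
#' @export
flag_outliers <- function(static, change, residual = NULL, threshold = 2.5) {
  if (length(static) < 3) stop("need at least 3 observations")
  zs <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero variance in outlier screen")
    (x - mean(x, na.rm = TRUE)) / s
  }
  z_st <- zs(static)
  z_ch <- zs(change)
  both <- abs(z_st) >= threshold & abs(z_ch) >= threshold
  both[is.na(both)] <- FALSE
  flag <- both
  reason <- ifelse(both, "static+change", NA_character_)
  if (!is.null(residual)) {
    z_re <- zs(residual)
    res_flag <- abs(z_re) >= threshold
    res_flag[is.na(res_flag)] <- FALSE
    reason[res_flag & !flag] <- "residual"
    reason[res_flag & both] <- "static+change,residual"
    flag <- flag | res_flag
  }
  idx <- which(flag)
  list(flag = flag,
       log = data.frame(index = idx, reason = reason[idx],
                        z_static = round(z_st[idx], 2),
                        z_change = round(z_ch[idx], 2)))
}

#' Fit the repeated-measures linear mixed model
#'
#' REML linear mixed model for one session-level outcome with a random
#' participant intercept, the day factor as the repeated measure, and a
#' choice of residual covariance structure over the three measurement
#' days:
#'
#' * `"RI"`: random intercept with homoscedastic residuals, fitted with
#'   `lmerTest`; F tests use Satterthwaite denominator degrees of freedom
#'   (type III, sum contrasts).
#' * `"CSH"`: heterogeneous compound symmetry (common correlation,
#'   day-specific variances), fitted with `nlme`.
#' * `"FA1"`/`"UN"`: a general symmetric (unstructured) residual
#'   covariance over the three days, fitted with `nlme`. With three
#'   repeated measures the first-order factor-analytic structure has the
#'   same parameter count as the unstructured matrix, which is fitted as
#'   its explicit parameterization; the requested label is recorded.
#'
#' The `nlme` fits report marginal (type III style) F tests with
#' containment degrees of freedom. AICc is reported for covariance
#' structure comparison. Missing/excluded sessions are simply absent rows
#' (no listwise deletion).
#'
#' @param data long session table (one row per participant x day) with at
#'   least `participant`, `day` and the outcome.
#' @param outcome outcome column name.
#' @param predictors right-hand-side terms crossed with `day_f` (the day
#'   factor), e.g. `"condition"` for the condition-by-time model or an
#'   energy column for the energy-by-time models.
#' @param covariates optional additive covariate column names.
#' @param structure residual covariance structure label.
#' @return list of class `somnaffect_lmm`: `fit`, `anova` (term table with
#'   F, df, p), `structure`, `structure_fitted`, `aicc`, `converged`.
#' @export
fit_lmm <- function(data, outcome, predictors = "condition",
                    covariates = NULL,
                    structure = c("RI", "CSH", "FA1", "UN")) {
  structure <- match.arg(structure)
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if (length(unique(data$day)) < 2)
    stop("outcome must be present on at least two days")
  data$day_f <- factor(data$day)
  data$participant <- factor(data$participant)
  for (p in predictors)
    if (is.character(data[[p]])) data[[p]] <- factor(data[[p]])
  rhs <- paste(c(sprintf("%s * day_f", predictors), covariates),
               collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  if (structure == "RI") {
    f2 <- stats::update(form, . ~ . + (1 | participant))
    fit <- lmerTest::lmer(f2, data = data, REML = TRUE)
    an <- stats::anova(fit, type = 3)
    tab <- data.frame(term = rownames(an), F = an[["F value"]],
                      df1 = an[["NumDF"]], df2 = an[["DenDF"]],
                      p = an[["Pr(>F)"]], row.names = NULL)
    k <- length(lme4::fixef(fit)) + 2L  # + random intercept SD + residual SD
    ll <- as.numeric(stats::logLik(fit))
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
  } else {
    corr <- if (structure == "CSH")
      nlme::corCompSymm(form = ~ 1 | participant)
    else nlme::corSymm(form = ~ as.numeric(day_f) | participant)
    fit <- nlme::lme(form, random = ~ 1 | participant, data = data,
                     correlation = corr,
                     weights = nlme::varIdent(form = ~ 1 | day_f),
                     method = "REML",
                     control = nlme::lmeControl(opt = "optim",
                                                maxIter = 200,
                                                msMaxIter = 200,
                                                returnObject = TRUE))
    an <- stats::anova(fit, type = "marginal")
    an <- an[rownames(an) != "(Intercept)", , drop = FALSE]
    tab <- data.frame(term = rownames(an), F = an[["F-value"]],
                      df1 = an[["numDF"]], df2 = an[["denDF"]],
                      p = an[["p-value"]], row.names = NULL)
    npar_corr <- if (structure == "CSH") 1L else 3L
    k <- length(nlme::fixef(fit)) + 1L + npar_corr + 3L  # + var weights
    ll <- as.numeric(stats::logLik(fit))
    conv <- TRUE
  }
  structure(list(fit = fit, anova = tab, structure = structure,
                 structure_fitted = if (structure %in% c("FA1", "UN"))
                   "general symmetric" else structure,
                 aicc = aicc(ll, k, nrow(data)), converged = conv),
            class = "somnaffect_lmm")
}

#' @export
print.somnaffect_lmm <- function(x, ...) {
  cat("<somnaffect_lmm> structure ", x$structure,
      if (x$structure != x$structure_fitted)
        paste0(" (fitted as ", x$structure_fitted, ")"),
      ", AICc ", round(x$aicc, 2), "\n", sep = "")
  print(x$anova, digits = 4)
  invisible(x)
}

#' Extract one term's test from a fitted LMM
#'
#' @param model a `somnaffect_lmm`.
#' @param term term label (e.g. `"condition:day_f"`).
#' @return one-row data frame with `F`, `df1`, `df2`, `p`.
#' @export
lmm_term <- function(model, term) {
  i <- match(term, model$anova$term)
  if (is.na(i)) stop("term not in model: ", term)
  model$anova[i, c("F", "df1", "df2", "p")]
}

#' Bonferroni adjustment within a declared family
#'
#' @param p raw p-values.
#' @param m family size; must be at least `length(p)`.
#' @return p-values multiplied by `m`, capped at 1.
#' @export
bonferroni_family <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size smaller than the number of tests")
  pmin(1, p * m)
}

#' Follow-up contrasts for a significant LMM effect
#'
#' The three follow-up families used after a significant mixed-model
#' effect, each Bonferroni-corrected over its declared family size:
#' paired t tests between measurement days (`type = "paired_days"`),
#' between-condition linear regressions on static or change scores
#' (`type = "condition_regression"`), and Pearson correlations between a
#' sleep feature and a change score (`type = "correlation"`).
#'
#' @param data long session table.
#' @param outcome outcome column.
#' @param type contrast family.
#' @param days day pairs (list of 2-vectors) for `paired_days`.
#' @param feature feature column for `correlation`.
#' @param on `"static"` day values or `"change"` scores for the regression
#'   and correlation families, with `change = c(d1, d2)` day pair.
#' @param change day pair defining a change score.
#' @param family_m Bonferroni family size (defaults to the number of tests).
#' @return data frame of contrasts with statistics, raw and adjusted p.
#' @export
followups <- function(data, outcome,
                      type = c("paired_days", "condition_regression",
                               "correlation"),
                      days = list(c(1, 2), c(2, 5), c(1, 5)),
                      feature = NULL, on = c("change", "static"),
                      change = c(1, 2), family_m = NULL) {
  type <- match.arg(type)
  on <- match.arg(on)
  wide <- stats::reshape(
    data[c("participant", "condition", "day", outcome)],
    idvar = c("participant", "condition"), timevar = "day",
    direction = "wide")
  val <- function(d) wide[[paste0(outcome, ".", d)]]
  rows <- list()
  if (type == "paired_days") {
    for (pr in days) {
      tt <- stats::t.test(val(pr[2]), val(pr[1]), paired = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = sprintf("day%g-day%g", pr[2], pr[1]),
        estimate = unname(tt$estimate), t = unname(tt$statistic),
        df = unname(tt$parameter), p_raw = tt$p.value)
    }
  } else if (type == "condition_regression") {
    y <- if (on == "change") val(change[2]) - val(change[1]) else val(change[1])
    f <- stats::lm(y ~ wide$condition)
    s <- summary(f)
    rows[[1L]] <- data.frame(
      contrast = sprintf("condition on %s", if (on == "change")
        sprintf("day%g-day%g change", change[2], change[1]) else
          sprintf("day%g", change[1])),
      estimate = stats::coef(f)[2], t = s$coefficients[2, "t value"],
      df = f$df.residual, p_raw = s$coefficients[2, "Pr(>|t|)"])
  } else {
    stopifnot(!is.null(feature))
    fx <- data[[feature]][match(wide$participant, data$participant)]
    y <- if (on == "change") val(change[2]) - val(change[1]) else val(change[1])
    ct <- stats::cor.test(fx, y)
    rows[[1L]] <- data.frame(
      contrast = sprintf("%s ~ %s", feature, if (on == "change")
        sprintf("day%g-day%g change", change[2], change[1]) else
          sprintf("day%g", change[1])),
      estimate = unname(ct$estimate), t = unname(ct$statistic),
      df = unname(ct$parameter), p_raw = ct$p.value)
  }
  out <- do.call(rbind, rows)
  m <- if (is.null(family_m)) nrow(out) else family_m
  out$p_bonf <- bonferroni_family(out$p_raw, m)
  rownames(out) <- NULL
  out
}

#' Nonparametric equivalents of the follow-up tests
#'
#' Friedman test for repeated measures (whole sample or within condition),
#' Mann-Whitney U for between-condition comparisons of values or change
#' scores, and Spearman correlation for feature-change associations, with
#' the same Bonferroni family sizes as their parametric counterparts.
#'
#' @inheritParams followups
#' @param type test family.
#' @return data frame with statistics, raw and adjusted p.
#' @export
nonparametric_followups <- function(data, outcome,
                                    type = c("friedman", "mann_whitney",
                                             "spearman"),
                                    feature = NULL, on = c("change", "static"),
                                    change = c(1, 2), family_m = NULL) {
  type <- match.arg(type)
  on <- match.arg(on)
  wide <- stats::reshape(
    data[c("participant", "condition", "day", outcome)],
    idvar = c("participant", "condition"), timevar = "day",
    direction = "wide")
  cols <- grep(paste0("^", outcome, "\\."), names(wide), value = TRUE)
  val <- function(d) wide[[paste0(outcome, ".", d)]]
  if (type == "friedman") {
    m <- as.matrix(wide[cols])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
      # every row fully tied: no evidence of a column effect (the tie
      # correction of the test statistic is degenerate here)
      out <- data.frame(test = "friedman", statistic = 0,
                        df = ncol(m) - 1, p_raw = 1)
    } else {
      ft <- stats::friedman.test(m)
      out <- data.frame(test = "friedman", statistic = unname(ft$statistic),
                        df = unname(ft$parameter), p_raw = ft$p.value)
    }
  } else if (type == "mann_whitney") {
    y <- if (on == "change") val(change[2]) - val(change[1]) else val(change[1])
    g <- wide$condition
    wt <- stats::wilcox.test(y[g == CONDITIONS[1]], y[g == CONDITIONS[2]],
                             exact = FALSE)
    out <- data.frame(test = "mann_whitney", statistic = unname(wt$statistic),
                      df = NA_real_, p_raw = wt$p.value)
  } else {
    stopifnot(!is.null(feature))
    fx <- data[[feature]][match(wide$participant, data$participant)]
    y <- if (on == "change") val(change[2]) - val(change[1]) else val(change[1])
    ok <- stats::complete.cases(fx, y)
    st <- stats::cor.test(fx[ok], y[ok], method = "spearman", exact = FALSE)
    out <- data.frame(test = "spearman", statistic = unname(st$estimate),
                      df = NA_real_, p_raw = st$p.value)
  }
  m <- if (is.null(family_m)) nrow(out) else family_m
  out$p_bonf <- bonferroni_family(out$p_raw, m)
  out
}
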