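#' Power of a fixed-effects F test
#'
#' `P(F > F_crit)` under the noncentral F distribution with noncentrality
#' `lambda`; strictly increasing in `lambda` at fixed degrees of freedom
#' and alpha.
#'
#' @param lambda noncentrality parameter.
#' @param df1,df2 numerator/denominator degrees of freedom.
#' @param alpha significance level.
#' @return power in [0, 1].
#' @export
f_test_power <- function(lambda, df1, df2, alpha = 0.05) {
  stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda,
            lower.tail = FALSE)
}

# noncentrality lambda achieving the target power, by root finding; when
# the size of the test already exceeds the target (alpha >= power) the
# smallest detectable effect is zero
lambda_for_power <- function(df1, df2, alpha, power, tol = 1e-9) {
  if (f_test_power(1e-9, df1, df2, alpha) >= power) return(0)
  stats::uniroot(function(l) f_test_power(l, df1, df2, alpha) - power,
                 interval = c(1e-9, 1e4), tol = tol)$root
}

#' Minimum detectable effect size of a mixed ANOVA (sensitivity analysis)
#'
#' Inverts noncentral-F power for a g (between) x m (within) mixed-design
#' ANOVA to find the smallest Cohen's f detectable at the given alpha and
#' power. Degrees of freedom: within/interaction effects use
#' `df1 = (m - 1)` (interaction: `(g - 1)(m - 1)`) and
#' `df2 = (N - g)(m - 1)`; the between effect uses `df1 = g - 1`,
#' `df2 = N - g` (sphericity correction `eps = 1`).
#'
#' Two effect-size conventions are implemented:
#'
#' * `"spss"` (G*Power's "as in SPSS" option): the effect size is defined
#'   through the partial eta squared of the observed F, so the
#'   noncentrality is `lambda = f^2 * df2` (the error degrees of freedom).
#' * `"gpower"` (G*Power default): the repeated-measures correlation `rho`
#'   enters explicitly; `lambda = f^2 * N * m / (1 - rho)` for
#'   within/interaction effects and `lambda = f^2 * N * m / (1 + (m - 1)
#'   rho)` for the between effect.
#'
#' The two conventions answer the same question on different effect-size
#' scales, so both values are reported by the cohort-level sensitivity
#' summary.
#'
#' @param design `"interaction"`, `"within"` or `"between"`.
#' @param N total sample size.
#' @param groups number of between-subject groups (g).
#' @param measurements number of repeated measurements (m).
#' @param alpha significance level.
#' @param power target power.
#' @param convention effect-size convention (see above).
#' @param rho assumed repeated-measures correlation (gpower convention).
#' @param eps nonsphericity correction (1 = spherical).
#' @return minimum detectable Cohen's f.
#' @export
sensitivity_min_effect <- function(design = c("interaction", "within",
                                              "between"),
                                   N = 29, groups = 2, measurements = 3,
                                   alpha = 0.05, power = 0.8,
                                   convention = c("spss", "gpower"),
                                   rho = 0.5, eps = 1) {
  design <- match.arg(design)
  convention <- match.arg(convention)
  g <- groups; m <- measurements
  if (design == "between") {
    df1 <- g - 1
    df2 <- N - g
  } else {
    df1 <- if (design == "interaction") (g - 1) * (m - 1) * eps else (m - 1) * eps
    df2 <- (N - g) * (m - 1) * eps
  }
  lam <- lambda_for_power(df1, df2, alpha, power)
  mult <- if (convention == "spss") {
    df2
  } else if (design == "between") {
    N * m / (1 + (m - 1) * rho)
  } else {
    N * m * eps / (1 - rho)
  }
  sqrt(lam / mult)
}

#' Sensitivity summary for the study design
#'
#' Minimum detectable f for the interaction/within and between factors of
#' the 2 x 3 mixed design at the given N, under both implemented effect-size
#' conventions.
#'
#' @inheritParams sensitivity_min_effect
#' @return data frame with one row per design factor and convention.
#' @export
sensitivity_summary <- function(N = 29, alpha = 0.05, power = 0.8, rho = 0.5) {
  grid <- expand.grid(design = c("interaction", "between"),
                      convention = c("spss", "gpower"),
                      stringsAsFactors = FALSE)
  grid$min_f <- mapply(function(d, cv)
    sensitivity_min_effect(d, N = N, alpha = alpha, power = power,
                           convention = cv, rho = rho),
    grid$design, grid$convention)
  grid
}
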