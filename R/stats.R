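#' Covariate-adjusted group comparison by linear regression
#'
#' Fits `outcome ~ group + age + sex` by ordinary least squares on a
#' two-group subset (group coded 0 for the first group, 1 for the second;
#' sex coded male = 1, female = 0) and reports the group coefficient with
#' its t-test and the Cohen's f-squared attributable to the group term
#' (R-squared increment of the full over the covariates-only model).
#'
#' @param table a `cohort_table` (or any data.frame with the columns).
#' @param outcome name of the outcome column.
#' @param groups length-2 character vector; the first level is coded 0.
#' @param covariates covariate column names (default age and sex).
#' @return object of class `regression_result`: `estimate`, `se`, `t`,
#'   `p`, `f2`, `n`, plus the model description.
#' @export
fit_group_model <- function(table, outcome,
                            groups = c("control", "psychosis"),
                            covariates = c("age", "sex")) {
  if (!outcome %in% names(table))
    stop("data error: outcome column '", outcome, "' not found")
  sub <- table[table$group %in% groups, , drop = FALSE]
  if (any(tabulate(factor(sub$group, levels = groups), 2L) < 2L))
    stop("data error: need at least 2 subjects per group")
  y <- sub[[outcome]]
  if (any(!is.finite(y))) stop("data error: non-finite outcome values")
  X <- cbind(group = as.integer(sub$group == groups[2]))
  for (cv in covariates) {
    v <- sub[[cv]]
    if (is.null(v)) stop("data error: covariate '", cv, "' not found")
    if (!is.numeric(v)) v <- as.integer(v == "male")
    X <- cbind(X, v)
  }
  colnames(X) <- c("group", covariates)
  Xf <- cbind(`(Intercept)` = 1, X)
  if (qr(Xf)$rank < ncol(Xf))
    stop("collinearity error: design matrix is rank deficient")
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  est <- sm$coefficients["Xgroup", ]
  r2_full <- sm$r.squared
  Xr <- X[, covariates, drop = FALSE]
  r2_red <- if (ncol(Xr)) summary(stats::lm(y ~ Xr))$r.squared else 0
  structure(
    list(estimate = unname(est["Estimate"]), se = unname(est["Std. Error"]),
         t = unname(est["t value"]), p = unname(est["Pr(>|t|)"]),
         f2 = if (r2_full >= 1 - 1e-12) Inf else
           cohens_f2(r2_full, min(r2_red, r2_full)),
         r2_full = r2_full, r2_reduced = r2_red,
         n = nrow(sub), outcome = outcome, groups = groups,
         covariates = covariates),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "%s ~ group(%s vs %s) + %s  [n = %d]\n", x$outcome, x$groups[1],
    x$groups[2], paste(x$covariates, collapse = " + "), x$n))
  cat(sprintf("Estimate = %.4g, SE = %.3g, t = %.3g, p = %.3g, f2 = %.3g\n",
              x$estimate, x$se, x$t, x$p, x$f2))
  invisible(x)
}

#' Cohen's f-squared from R-squared increments
#'
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)`, the effect size of the
#' terms distinguishing the full from the reduced model.
#'
#' @param r2_full,r2_reduced coefficients of determination, with
#'   `0 <= r2_reduced <= r2_full < 1`.
#' @return f-squared (>= 0).
#' @export
cohens_f2 <- function(r2_full, r2_reduced) {
  if (!is.finite(r2_full) || !is.finite(r2_reduced) || r2_full >= 1 ||
      r2_full < 0 || r2_reduced < 0)
    stop("domain error: R-squared values must lie in [0, 1)")
  if (r2_reduced > r2_full)
    stop("negative-increment error: r2_reduced exceeds r2_full")
  (r2_full - r2_reduced) / (1 - r2_full)
}

#' Minimum detectable effect size for a regression term
#'
#' Smallest Cohen's f-squared at which the F-test of a model term attains
#' the requested power: the test statistic is noncentral F with
#' `df_test` numerator and `n_total - n_predictors - 1` denominator
#' degrees of freedom and noncentrality `f2 * n_total` (total-sample
#' convention; `ncp_convention = "df_error"` uses the error-df
#' convention instead). Solved by monotone root finding.
#'
#' @param n_total total sample size.
#' @param n_predictors number of predictors in the full model.
#' @param df_test numerator degrees of freedom of the tested term.
#' @param alpha significance level.
#' @param power requested power.
#' @param ncp_convention noncentrality convention (see above).
#' @return minimum detectable f-squared.
#' @export
min_detectable_f2 <- function(n_total, n_predictors, df_test = 1,
                              alpha = 0.05, power = 0.80,
                              ncp_convention = c("total_n", "df_error")) {
  ncp_convention <- match.arg(ncp_convention)
  df2 <- n_total - n_predictors - 1
  if (df2 <= 0)
    stop("domain error: n_total must exceed n_predictors + 1")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("domain error: alpha and power must lie in (0, 1)")
  nc_scale <- if (ncp_convention == "total_n") n_total else df2
  crit <- stats::qf(1 - alpha, df_test, df2)
  pw <- function(f2) 1 - stats::pf(crit, df_test, df2, ncp = f2 * nc_scale)
  if (pw(1e4) < power)
    stop("domain error: requested power unattainable for these df")
  stats::uniroot(function(f2) pw(f2) - power, c(1e-12, 1e4),
                 tol = 1e-12)$root
}

#' Power of the term F-test at a given effect size
#'
#' Companion to [min_detectable_f2()] (round-trip check and sensitivity
#' curves).
#'
#' @inheritParams min_detectable_f2
#' @param f2 Cohen's f-squared.
#' @return power in (0, 1).
#' @export
f2_power <- function(f2, n_total, n_predictors, df_test = 1, alpha = 0.05,
                     ncp_convention = c("total_n", "df_error")) {
  ncp_convention <- match.arg(ncp_convention)
  df2 <- n_total - n_predictors - 1
  nc_scale <- if (ncp_convention == "total_n") n_total else df2
  1 - stats::pf(stats::qf(1 - alpha, df_test, df2), df_test, df2,
                ncp = f2 * nc_scale)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param family_alpha family-wise error rate (e.g. 0.05).
#' @param m number of tests in the family.
#' @return list with `alpha` (exact `family_alpha / m`), `printed` (the
#'   value rounded to one significant figure, the usual reporting
#'   precision), `family_alpha` and `m`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m) {
  if (!is.finite(m) || m < 1) stop("domain error: m must be >= 1")
  a <- family_alpha / m
  list(alpha = a, printed = signif(a, 1), family_alpha = family_alpha, m = m)
}

#' Demographic comparison battery
#'
#' Two-group demographic tests as used for cohort tables: Wilcoxon
#' rank-sum for each continuous variable (the first group's sample
#' supplies the reported W), a chi-squared test of independence on the
#' 2 x 2 sex table, and a one-sample Kolmogorov-Smirnov normality check
#' per continuous variable against either a normal with the sample's own
#' moments (default) or the standard normal.
#'
#' @param table a `cohort_table`.
#' @param continuous continuous column names (default age and BMI).
#' @param categorical categorical column (default sex).
#' @param groups two group labels to compare.
#' @param ks_reference `"sample_moments"` or `"standard_normal"`.
#' @param correct continuity correction for the chi-squared test.
#' @return data.frame with columns `test`, `variable`, `statistic`,
#'   `value`, `p`, `n1`, `n2`.
#' @export
demographic_tests <- function(table, continuous = c("age", "BMI"),
                              categorical = "sex",
                              groups = c("control", "psychosis"),
                              ks_reference = c("sample_moments",
                                               "standard_normal"),
                              correct = TRUE) {
  ks_reference <- match.arg(ks_reference)
  g1 <- table[table$group == groups[1], , drop = FALSE]
  g2 <- table[table$group == groups[2], , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2)
    stop("data error: need at least 2 observations per group")
  rows <- list()
  for (v in continuous) {
    wt <- suppressWarnings(stats::wilcox.test(g1[[v]], g2[[v]]))
    rows[[length(rows) + 1L]] <- data.frame(
      test = "wilcoxon", variable = v, statistic = "W",
      value = unname(wt$statistic), p = wt$p.value,
      n1 = nrow(g1), n2 = nrow(g2))
    x <- c(g1[[v]], g2[[v]])
    kt <- suppressWarnings(if (ks_reference == "sample_moments")
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x)) else
        stats::ks.test(x, "pnorm"))
    rows[[length(rows) + 1L]] <- data.frame(
      test = "ks_normality", variable = v, statistic = "D",
      value = unname(kt$statistic), p = kt$p.value,
      n1 = nrow(g1), n2 = nrow(g2))
  }
  tab <- table(factor(c(g1[[categorical]], g2[[categorical]])),
               rep(groups, c(nrow(g1), nrow(g2))))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  rows[[length(rows) + 1L]] <- data.frame(
    test = "chisq_independence", variable = categorical, statistic = "X2",
    value = unname(ct$statistic), p = ct$p.value,
    n1 = nrow(g1), n2 = nrow(g2))
  do.call(rbind, rows)
}
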