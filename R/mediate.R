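#' Causal mediation analysis with linear models and pairs bootstrap
#'
#' Product-of-coefficients mediation for a two-level treatment with
#' continuous mediator and outcome, adjusting for covariates in both
#' models and without a treatment-by-mediator interaction:
#' `mediator ~ treatment + covariates` supplies the treatment-to-mediator
#' path `a`, `outcome ~ treatment + mediator + covariates` supplies the
#' mediator-to-outcome path `b` and the average direct effect (ADE, the
#' treatment coefficient); the average causal mediation effect is
#' `ACME = a * b`, and `total = ACME + ADE` holds as an algebraic identity
#' for nested linear fits with a common covariate set. Uncertainty comes
#' from a nonparametric bootstrap: subjects are resampled as whole rows,
#' both models refit per draw, and percentile intervals and two-sided
#' bootstrap p-values (`2 * min(fraction <= 0, fraction >= 0)`, floored at
#' `2/n_boot`) are reported for ACME, ADE and the total effect.
#'
#' @param table data.frame with the analysis columns.
#' @param outcome,mediator column names (continuous).
#' @param treatment grouping column (default `"group"`).
#' @param groups length-2 character vector; first level coded 0.
#' @param covariates covariate columns (default age and sex; sex is coded
#'   male = 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf_level confidence level for percentile intervals.
#' @return object of class `mediation_result`: `estimates` (acme, ade,
#'   total), `ci` (3 x 2), `p` (length 3), `prop_mediated` (percent),
#'   `n`, `n_boot`, `seed`, and the bootstrap `draws` matrix.
#' @export
mediate <- function(table, outcome, mediator, treatment = "group",
                    groups = c("control", "psychosis"),
                    covariates = c("age", "sex"), n_boot = 1000L,
                    seed = 1L, conf_level = 0.95) {
  for (cn in c(outcome, mediator, treatment, covariates))
    if (!cn %in% names(table)) stop("data error: column '", cn, "' not found")
  sub <- table[table[[treatment]] %in% groups, , drop = FALSE]
  t01 <- as.integer(sub[[treatment]] == groups[2])
  if (length(unique(t01)) < 2L)
    stop("design error: treatment has a single level in the data")
  n <- nrow(sub)
  if (n < 20L) stop("design error: need at least 20 subjects")
  if (n_boot < 100L)
    warning("config: n_boot < 100 gives unstable bootstrap intervals")
  Z <- NULL
  for (cv in covariates) {
    v <- sub[[cv]]
    if (!is.numeric(v)) v <- as.integer(v == "male")
    Z <- cbind(Z, v)
  }
  m <- sub[[mediator]]
  y <- sub[[outcome]]
  Xm <- cbind(1, t01, Z)
  Xy <- cbind(1, t01, m, Z)
  fit_once <- function(idx) {
    cm <- stats::lm.fit(Xm[idx, , drop = FALSE], m[idx])$coefficients
    cy <- stats::lm.fit(Xy[idx, , drop = FALSE], y[idx])$coefficients
    a <- cm[2L]
    b <- cy[3L]
    ade <- cy[2L]
    c(acme = unname(a * b), ade = unname(ade),
      total = unname(a * b + ade))
  }
  est <- fit_once(seq_len(n))
  if (any(!is.finite(est)))
    stop("design error: mediator or outcome model is rank deficient")
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 3L,
                  dimnames = list(NULL, c("acme", "ade", "total")))
  for (i in seq_len(n_boot))
    draws[i, ] <- fit_once(sample.int(n, n, replace = TRUE))
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- t(apply(draws, 2L, stats::quantile, probs = probs, na.rm = TRUE))
  pvals <- apply(draws, 2L, function(d) {
    d <- d[is.finite(d)]
    max(2 * min(mean(d <= 0), mean(d >= 0)), 2 / n_boot)
  })
  res <- structure(
    list(estimates = est, ci = ci, p = pvals,
         prop_mediated = NA_real_, n = n, n_boot = n_boot, seed = seed,
         conf_level = conf_level, draws = draws,
         spec = list(outcome = outcome, mediator = mediator,
                     treatment = treatment, groups = groups,
                     covariates = covariates)),
    class = "mediation_result")
  res$prop_mediated <- tryCatch(proportion_mediated(res),
                                error = function(e) NA_real_)
  res
}

#' Proportion mediated
#'
#' `100 * ACME / total` from the point estimates. When ACME and the total
#' effect have opposite signs the signed ratio is returned with an
#' `opposite_sign` attribute set, since "proportion" is then not
#' interpretable as a share.
#'
#' @param result a `mediation_result`.
#' @return percentage (possibly signed; see above).
#' @export
proportion_mediated <- function(result) {
  est <- result$estimates
  if (est[["total"]] == 0)
    stop("undefined-proportion error: total effect is zero")
  out <- 100 * est[["acme"]] / est[["total"]]
  if (sign(est[["acme"]]) != 0 &&
      sign(est[["acme"]]) != sign(est[["total"]]))
    attr(out, "opposite_sign") <- TRUE
  out
}

#' Classify a mediation result
#'
#' `"full"` if the ACME is significant at `alpha` and the ADE is not;
#' `"partial"` if both are significant; `"none"` if the ACME is not
#' significant (regardless of the ADE).
#'
#' @param result a `mediation_result`.
#' @param alpha significance level (e.g. a Bonferroni-corrected alpha).
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
classify_mediation <- function(result, alpha = 0.05) {
  acme_sig <- result$p[["acme"]] < alpha
  ade_sig <- result$p[["ade"]] < alpha
  if (!acme_sig) "none" else if (ade_sig) "partial" else "full"
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: %s -> %s -> %s (n = %d, %d bootstrap draws)\n",
              x$spec$treatment, x$spec$mediator, x$spec$outcome,
              x$n, x$n_boot))
  lab <- c(acme = "ACME", ade = "ADE", total = "Total")
  for (k in names(lab))
    cat(sprintf("  %-6s %9.4g  [%9.4g, %9.4g]  p = %.4g\n", lab[k],
                x$estimates[[k]], x$ci[k, 1L], x$ci[k, 2L], x$p[[k]]))
  cat(sprintf("  proportion mediated: %.1f%%\n", x$prop_mediated))
  invisible(x)
}
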