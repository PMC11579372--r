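test_that("group regression matches the normal-equations oracle", {
  set.seed(31)
  n <- 500
  g <- rep(c("control", "psychosis"), each = n / 2)
  age <- rnorm(n, 40, 12)
  sex <- sample(c("male", "female"), n, TRUE)
  y <- -0.03 * (g == "psychosis") + 0.002 * age +
    0.01 * (sex == "male") + rnorm(n, 0, 0.05)
  df <- data.frame(group = factor(g), age = age, sex = sex, y = y)
  r <- fit_group_model(df, "y")
  # oracle: solve the normal equations directly
  X <- cbind(1, as.integer(g == "psychosis"), age, as.integer(sex == "male"))
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(r$estimate, beta[2], tolerance = 1e-10)
  # generator truth within 3 SE
  expect_lt(abs(r$estimate - (-0.03)), 3 * r$se)
  # t = estimate / SE identity
  expect_equal(r$t, r$estimate / r$se, tolerance = 1e-9)
})

test_that("outcome equal to a covariate yields a null group effect", {
  set.seed(5)
  n <- 500
  df <- data.frame(group = factor(rep(c("control", "psychosis"), n / 2)),
                   age = rnorm(n, 40, 12),
                   sex = sample(c("male", "female"), n, TRUE))
  df$y <- df$age
  r <- suppressWarnings(fit_group_model(df, "y"))
  expect_lt(abs(r$estimate), 1e-10)
  # with a perfect fit the t statistic is 0/0 noise; the meaningful
  # property is that no group effect is claimed
  expect_true(is.na(r$p) || r$p > 0.05)
})

test_that("rank-deficient designs raise collinearity errors", {
  df <- data.frame(group = factor(rep(c("control", "psychosis"), 10)),
                   age = rnorm(20), age2 = NA, sex = "male", y = rnorm(20))
  df$age2 <- df$age
  expect_error(fit_group_model(df, "y", covariates = c("age", "age2")),
               "collinearity")
  expect_error(fit_group_model(df, "nope"), "data error")
})

test_that("Cohen's f2 follows the R-squared increment definition", {
  expect_equal(cohens_f2(0.5, 0.4), 0.2)
  expect_equal(cohens_f2(0.3, 0.3), 0)
  expect_error(cohens_f2(1, 0.5), "domain")
  expect_error(cohens_f2(0.4, 0.5), "negative-increment")
  # RSS oracle on a random fit
  set.seed(12)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.3 * x1 + 0.2 * x2 + rnorm(n)
  rss <- function(fit) sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  f_full <- lm(y ~ x1 + x2)
  f_red <- lm(y ~ x2)
  f2_rss <- (rss(f_red) - rss(f_full)) / rss(f_full)
  expect_equal(cohens_f2(1 - rss(f_full) / tss, 1 - rss(f_red) / tss),
               f2_rss, tolerance = 1e-12)
})

test_that("sensitivity analysis reproduces the design's printed values", {
  expect_equal(round(min_detectable_f2(179, 3), 2), 0.04)
  expect_equal(round(min_detectable_f2(116, 3), 2), 0.07)
  # strictly decreasing in the total sample size
  f2s <- vapply(c(60, 100, 179, 400), min_detectable_f2,
                numeric(1), n_predictors = 3)
  expect_true(all(diff(f2s) < 0))
  # round trip: the returned f2 attains the requested power
  f2 <- min_detectable_f2(179, 3, power = 0.8)
  expect_equal(f2_power(f2, 179, 3), 0.8, tolerance = 1e-6)
  expect_error(min_detectable_f2(4, 3), "domain")
  expect_error(min_detectable_f2(100, 3, alpha = 0), "domain")
})

test_that("Bonferroni alphas reproduce the printed corrections", {
  expect_equal(bonferroni_alpha(0.05, 16)$printed, 0.003)
  expect_equal(bonferroni_alpha(0.05, 12)$printed, 0.004)
  expect_equal(bonferroni_alpha(0.05, 1)$alpha, 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "domain")
})

test_that("demographic battery behaves on identical and balanced data", {
  set.seed(3)
  n <- 40
  x <- rnorm(n, 40, 10)
  df <- data.frame(group = factor(rep(c("control", "psychosis"), each = n)),
                   age = c(x, x), BMI = c(x, x),
                   sex = rep(c("male", "female"), 2 * n / 2))
  res <- demographic_tests(df)
  w <- res[res$test == "wilcoxon" & res$variable == "age", ]
  expect_equal(w$value, n * n / 2)           # ties: W at its null centre
  expect_gt(w$p, 0.9)
  chi <- res[res$test == "chisq_independence", ]
  expect_equal(chi$value, 0)
  expect_equal(chi$p, 1)
})

test_that("small-sample Wilcoxon agrees with exhaustive enumeration", {
  x <- c(1.2, 3.4, 0.5, 2.2)
  y <- c(2.9, 4.4, 1.9, 5.0)
  df <- data.frame(group = factor(rep(c("control", "psychosis"), each = 4)),
                   age = c(x, y), BMI = c(x, y),
                   sex = rep("male", 8))
  res <- demographic_tests(df, continuous = "age")
  w <- res[res$test == "wilcoxon", ]
  oracle <- wilcoxon_enumeration(x, y)
  expect_equal(w$value, oracle$W)
  expect_equal(w$p, oracle$p, tolerance = 1e-12)
})

test_that("KS normality check flags bounded demographic variables", {
  co <- simulate_cohort(43, 136, 0, seed = 9)
  res <- demographic_tests(co, ks_reference = "standard_normal")
  d_age <- res$value[res$test == "ks_normality" & res$variable == "age"]
  expect_equal(d_age, 1)                     # ages >= 18 vs standard normal
  res2 <- demographic_tests(co)              # sample-moment reference
  d2 <- res2$value[res2$test == "ks_normality" & res2$variable == "age"]
  expect_lt(d2, 0.2)
})

test_that("type-I error of the group regression is calibrated", {
  set.seed(77)
  n <- 200
  reps <- 2000
  p <- numeric(reps)
  g <- factor(rep(c("control", "psychosis"), each = n / 2))
  for (i in seq_len(reps)) {
    df <- data.frame(group = g, age = rnorm(n, 40, 10),
                     sex = sample(c("male", "female"), n, TRUE),
                     y = rnorm(n))
    p[i] <- fit_group_model(df, "y")$p
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
  expect_true(all(p >= 0 & p <= 1))
})
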