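test_that("mediation recovers known paths and preserves the sum identity", {
  df <- make_mediation_data(n = 500, a = 1, b = 0.5, direct = 0.5, seed = 2)
  mr <- mediate(df, "outcome", "mediator", n_boot = 500, seed = 7)
  expect_lt(abs(mr$estimates[["acme"]] - 0.5), 0.15)
  expect_lt(abs(mr$estimates[["ade"]] - 0.5), 0.15)
  # identity holds for the point estimate and every bootstrap draw
  expect_equal(mr$estimates[["total"]],
               mr$estimates[["acme"]] + mr$estimates[["ade"]],
               tolerance = 1e-9)
  expect_lt(max(abs(mr$draws[, "total"] -
                      mr$draws[, "acme"] - mr$draws[, "ade"])), 1e-9)
  # CIs contain their point estimates
  expect_true(all(mr$ci[, 1] <= mr$estimates & mr$estimates <= mr$ci[, 2]))
})

test_that("null mediator path gives an ACME near zero with covering CI", {
  df <- make_mediation_data(n = 500, a = 1, b = 0, direct = 0.5, seed = 5)
  mr <- mediate(df, "outcome", "mediator", n_boot = 500, seed = 11)
  boot_se <- sd(mr$draws[, "acme"])
  expect_lt(abs(mr$estimates[["acme"]]), 3 * boot_se)
  expect_true(mr$ci["acme", 1] <= 0 && 0 <= mr$ci["acme", 2])
})

test_that("bootstrap is deterministic for a fixed seed", {
  df <- make_mediation_data(n = 200, seed = 3)
  m1 <- mediate(df, "outcome", "mediator", n_boot = 200, seed = 42)
  m2 <- mediate(df, "outcome", "mediator", n_boot = 200, seed = 42)
  expect_identical(m1$draws, m2$draws)
  expect_identical(m1$ci, m2$ci)
  m3 <- mediate(df, "outcome", "mediator", n_boot = 200, seed = 43)
  expect_false(identical(m1$draws, m3$draws))
})

test_that("total effect equals the covariate-adjusted group coefficient", {
  df <- make_mediation_data(n = 300, seed = 9)
  mr <- mediate(df, "outcome", "mediator", n_boot = 100, seed = 1)
  fg <- fit_group_model(df, "outcome")
  expect_equal(mr$estimates[["total"]], fg$estimate, tolerance = 1e-6)
})

test_that("ACME and ADE intervals cover the generating truth", {
  reps <- 200
  cover <- matrix(FALSE, reps, 2)
  for (i in seq_len(reps)) {
    df <- make_mediation_data(n = 500, a = 1, b = 0.5, direct = 0.5,
                              seed = 1000 + i)
    mr <- mediate(df, "outcome", "mediator", n_boot = 300, seed = i)
    cover[i, 1] <- mr$ci["acme", 1] <= 0.5 && 0.5 <= mr$ci["acme", 2]
    cover[i, 2] <- mr$ci["ade", 1] <= 0.5 && 0.5 <= mr$ci["ade", 2]
  }
  expect_gte(mean(cover[, 1]), 0.9)
  expect_gte(mean(cover[, 2]), 0.9)
})

test_that("null mediation is calibrated (false-positive rate <= 7%)", {
  reps <- 500
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    df <- make_mediation_data(n = 200, a = 0, b = 0, direct = 0,
                              seed = 5000 + i)
    mr <- mediate(df, "outcome", "mediator", n_boot = 300, seed = i)
    rej[i] <- mr$p[["acme"]] < 0.05
  }
  expect_lte(mean(rej), 0.07)
})

test_that("proportion mediated follows the point-estimate ratio", {
  fake <- structure(list(
    estimates = c(acme = -1.01, ade = -0.775, total = -1.785),
    p = c(acme = 1e-4, ade = 1e-4, total = 1e-4)),
    class = "mediation_result")
  expect_equal(proportion_mediated(fake), 100 * 1.01 / 1.785,
               tolerance = 1e-12)            # 56.6% as printed from Table 2
  fake$estimates <- c(acme = 0, ade = 0.4, total = 0.4)
  expect_equal(proportion_mediated(fake), 0)
  fake$estimates <- c(acme = 0.4, ade = 0, total = 0.4)
  expect_equal(proportion_mediated(fake), 100)
  fake$estimates <- c(acme = 0.4, ade = 0, total = 0)
  expect_error(proportion_mediated(fake), "undefined-proportion")
  fake$estimates <- c(acme = 0.2, ade = -0.5, total = -0.3)
  expect_true(isTRUE(attr(proportion_mediated(fake), "opposite_sign")))
})

test_that("mediation classification follows the ACME/ADE significance rule", {
  mk <- function(p_acme, p_ade) structure(
    list(p = c(acme = p_acme, ade = p_ade, total = 0.001)),
    class = "mediation_result")
  expect_identical(classify_mediation(mk(0.001, 0.18), 0.05), "full")
  expect_identical(classify_mediation(mk(0.001, 0.01), 0.05), "partial")
  expect_identical(classify_mediation(mk(0.5, 0.001), 0.05), "none")
})

test_that("design errors and configuration warnings are raised", {
  df <- make_mediation_data(n = 100, seed = 1)
  df$group <- factor("control", levels = c("control", "psychosis"))
  expect_error(mediate(df, "outcome", "mediator"), "single level")
  df2 <- make_mediation_data(n = 10, seed = 1)
  expect_error(mediate(df2, "outcome", "mediator"), "at least 20")
  df3 <- make_mediation_data(n = 100, seed = 1)
  expect_warning(mediate(df3, "outcome", "mediator", n_boot = 50),
                 "n_boot")
})
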