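test_that("OLS interaction fit equals the normal-equations oracle", {
  d <- make_ols_data()
  fit <- fit_bmi_interaction(d)
  # independent oracle: solve X'X b = X'y directly
  age_c <- d$age - mean(d$age)
  X <- cbind(1, d$grs, d$activity_binary, age_c, age_c^2, d$sex,
             d$grs * d$activity_binary)
  beta_hat <- solve(crossprod(X), crossprod(X, d$bmi))
  co <- coef(fit)
  expect_equal(co[[".grs"]], beta_hat[2], tolerance = 1e-10)
  expect_equal(co[[".activity"]], beta_hat[3], tolerance = 1e-10)
  expect_equal(co[[".grs:.activity"]], beta_hat[7], tolerance = 1e-10)
  # Wald z p-values consistent with estimate and SE
  tab <- fit$coefficients
  expect_equal(tab$p, 2 * pnorm(-abs(tab$estimate / tab$se)),
               tolerance = 1e-12)
  expect_true(all(tab$se > 0))
})

test_that("interaction coefficient is recovered, and null when absent", {
  co_null <- simulate_cohort(cohort_spec(50000, beta_ge = 0, seed = 61))
  f0 <- fit_bmi_interaction(co_null)
  row0 <- f0$coefficients[f0$coefficients$term == ".grs:.activity", ]
  expect_lt(abs(row0$estimate), 3 * row0$se)

  co_alt <- simulate_cohort(cohort_spec(50000, beta_ge = -0.2, seed = 62))
  f1 <- fit_bmi_interaction(co_alt)
  row1 <- f1$coefficients[f1$coefficients$term == ".grs:.activity", ]
  expect_lt(abs(row1$estimate + 0.2), 3 * row1$se)
})

test_that("single-center cohorts drop the center term with a warning", {
  d <- make_ols_data(200)
  d$center <- "only"
  expect_warning(fit <- fit_bmi_interaction(d, center = "center"),
                 "center")
  expect_false(any(grepl("center", fit$coefficients$term)))
  d$center <- rep(c("A", "B"), 100)
  fit2 <- fit_bmi_interaction(d, center = "center")
  expect_true(any(grepl("center", fit2$coefficients$term)))
  expect_error(fit_bmi_interaction(make_ols_data(40)), "50")
})

test_that("logistic OR equals the 2x2 cross-product ratio", {
  d <- make_2x2_cohort(30, 70, 20, 80)
  fit <- fit_obesity_logistic(d, activity = NULL, covariates = character(0))
  or <- fit$or_table$or[fit$or_table$term == ".grs"]
  expect_equal(or, (30 * 80) / (70 * 20), tolerance = 1e-4)
  expect_equal(or, 1.714, tolerance = 1e-3)
  # null effect: OR 1
  d0 <- make_2x2_cohort(25, 75, 25, 75)
  f0 <- fit_obesity_logistic(d0, activity = NULL, covariates = character(0))
  expect_equal(f0$or_table$or[f0$or_table$term == ".grs"], 1,
               tolerance = 1e-8)
})

test_that("overweight and underweight are excluded from the obesity fit", {
  d <- make_2x2_cohort()
  extra <- data.frame(grs = rep(c(0, 1), 20), bmi = rep(c(27, 17), 20))
  fit_aug <- fit_obesity_logistic(rbind(d, extra), activity = NULL,
                                  covariates = character(0))
  fit_ref <- fit_obesity_logistic(d, activity = NULL,
                                  covariates = character(0))
  expect_equal(fit_aug$n, fit_ref$n)
  expect_equal(coef(fit_aug), coef(fit_ref))
})

test_that("complete separation raises a diagnostic error", {
  d <- data.frame(grs = rep(c(0, 1), each = 50),
                  bmi = rep(c(22, 32), each = 50))
  expect_error(fit_obesity_logistic(d, activity = NULL,
                                    covariates = character(0)),
               "separation")
})

test_that("BMI classification boundaries are half-open as published", {
  cls <- classify_bmi(c(17, 18.5, 24.999, 25.0, 29.999, 30.0))
  expect_equal(as.character(cls),
               c("underweight", "normal", "normal", "overweight",
                 "overweight", "obese"))
})

test_that("weight conversion reproduces the published gram equivalents", {
  expect_equal(beta_to_weight(0.161), 465)
  expect_equal(beta_to_weight(0.186), 538)
  expect_equal(beta_to_weight(0.143), 413)
  expect_equal(beta_to_weight(0), 0)
  # linear and exact before rounding
  a <- 0.123; b <- 0.0456
  expect_equal(beta_to_weight(a + b, round = FALSE),
               beta_to_weight(a, round = FALSE) +
                 beta_to_weight(b, round = FALSE), tolerance = 1e-12)
})

test_that("stratum slope difference matches the interaction coefficient", {
  co <- simulate_cohort(cohort_spec(20000, beta_ge = -0.2, seed = 63))
  # saturated in activity (no shared covariates): exact equality
  st <- stratified_effects(co, covariates = character(0))
  fit <- fit_bmi_interaction(co, covariates = character(0))
  b_int <- coef(fit)[[".grs:.activity"]]
  expect_equal(st$difference$estimate, b_int, tolerance = 1e-10)
  # with shared covariates: approximate equality on synthetic data
  st2 <- stratified_effects(co)
  expect_lt(abs(st2$difference$estimate + 0.2), 3 * st2$difference$se)
})

test_that("a negative interaction shrinks the genetic slope in the active", {
  co <- simulate_cohort(cohort_spec(50000, beta_ge = -0.2, seed = 64))
  st <- stratified_effects(co)
  tab <- st$strata
  expect_gt(tab$beta_g[tab$stratum == "0"], tab$beta_g[tab$stratum == "1"])
  co0 <- simulate_cohort(cohort_spec(20000, beta_ge = 0, seed = 65))
  st0 <- stratified_effects(co0)
  expect_gt(st0$difference$p, 0.001)
})

test_that("adjusted means reduce to raw cell means in a balanced design", {
  set.seed(66)
  d <- expand.grid(grs_high = 0:1, activity_binary = 0:1)
  d <- d[rep(1:4, each = 100), ]
  d$bmi <- rnorm(400, 26 + d$grs_high - 0.5 * d$activity_binary, 2)
  ls <- lsmeans_by_group(d, covariates = character(0))
  raw <- aggregate(bmi ~ grs_high + activity_binary, d, mean)
  for (i in 1:4) {
    cell <- ls$cells[ls$cells$grs_group == ifelse(raw$grs_high[i] == 1,
                                                  "high", "low") &
                     ls$cells$activity_group ==
                       ifelse(raw$activity_binary[i] == 1, "active",
                              "inactive"), ]
    expect_equal(cell$mean, raw$bmi[i], tolerance = 1e-10)
  }
})

test_that("adjusted means agree with emmeans and recover known cells", {
  co <- simulate_cohort(cohort_spec(30000, beta_ge = -0.3, seed = 67))
  co$grs_high <- dichotomize_grs(co$grs, cut = 11.2)
  ls <- lsmeans_by_group(co)
  # interaction negative: high-vs-low GRS gap larger among the inactive
  ct <- ls$grs_contrast
  expect_gt(ct$estimate[ct$activity_group == "inactive"],
            ct$estimate[ct$activity_group == "active"])

  skip_if_not_installed("emmeans")
  co$age_c <- co$age - mean(co$age)
  co$age2 <- co$age_c^2  # own column so the reference grid holds its mean
  ref <- lm(bmi ~ grs_high * activity_binary + age_c + age2 + sex,
            data = co)
  em <- as.data.frame(emmeans::emmeans(
    ref, ~ grs_high * activity_binary,
    at = list(grs_high = c(0, 1), activity_binary = c(0, 1),
              sex = mean(co$sex))))
  for (i in seq_len(nrow(em))) {
    cell <- ls$cells[ls$cells$grs_group ==
                       ifelse(em$grs_high[i] == 1, "high", "low") &
                     ls$cells$activity_group ==
                       ifelse(em$activity_binary[i] == 1, "active",
                              "inactive"), ]
    expect_equal(cell$mean, em$emmean[i], tolerance = 1e-8)
  }
})

test_that("cohort_estimate extracts the pooling unit", {
  co <- simulate_cohort(cohort_spec(1000, seed = 68))
  est <- cohort_estimate(fit_bmi_interaction(co), "GLACIER-like")
  expect_named(est, c("cohort", "n", "beta", "se"))
  expect_equal(est$n, 1000L)
  expect_gt(est$se, 0)
})
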