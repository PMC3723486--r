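test_that("the same spec and seed reproduce an identical cohort", {
  spec <- cohort_spec(500, seed = 101)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1, c2)
  spec2 <- cohort_spec(500, seed = 102)
  expect_false(identical(simulate_cohort(spec2)$bmi, c1$bmi))
})

test_that("genotypes follow binomial moments and Hardy-Weinberg proportions", {
  n <- 50000
  geno <- simulate_genotypes(n, c(locusA = 0.4), seed = 1)
  se_mean <- sqrt(2 * 0.4 * 0.6 / n)
  expect_lt(abs(mean(geno) - 0.8), 3 * se_mean)
  qc <- qc_variants(geno)
  expect_gt(qc$hwe_p, 0.001)

  # near-fixed risk allele: almost every dosage is 2
  g2 <- simulate_genotypes(2000, c(x = 0.999999), seed = 2)
  expect_gt(mean(g2 == 2L), 0.99)

  # 12-locus panel comes back in declared order with risk alleles counted
  panel <- simulate_genotypes(10, seed = 3)
  expect_identical(colnames(panel), names(default_panel_freqs()))
  expect_identical(unname(attr(panel, "counted_allele")),
                   risk_allele_map()$risk_allele)
})

test_that("out-of-range frequencies are rejected naming the locus", {
  expect_error(simulate_genotypes(10, c(FTO = 0.5, MC4R = 1.2)), "MC4R")
  expect_error(simulate_genotypes(10, c(a = 0)), "\\ba\\b")
  expect_error(simulate_genotypes(10, c(a = NaN)), "a")
})

test_that("directly simulated GRS matches its normal law", {
  expect_equal(simulate_grs(50, mean = 11.2, variance = 0, seed = 1),
               rep(11.2, 50))
  n <- 100000
  g <- simulate_grs(n, seed = 7)
  expect_lt(abs(mean(g) - 11.2), 3 * sqrt(5.06 / n))
  expect_lt(abs(var(g) - 5.06), 3 * 5.06 * sqrt(2 / (n - 1)))
  expect_identical(simulate_grs(1000, seed = 9), simulate_grs(1000, seed = 9))
  expect_error(simulate_grs(10, variance = -1), ">= 0")
})

test_that("independent activity hits its marginal prevalence", {
  n <- 100000
  g <- simulate_grs(n, seed = 11)
  a <- simulate_activity(g, p_inactive = 0.30, rho = 0, seed = 12)
  expect_lt(abs(mean(a == 0) - 0.30), 3 * sqrt(0.3 * 0.7 / n))
  expect_lt(abs(cor(g, a)), 0.01)
  expect_error(simulate_activity(numeric(0)), "length")
})

test_that("copula activity realizes the target correlation and marginal", {
  n <- 200000
  g <- simulate_grs(n, seed = 21)
  a <- simulate_activity(g, p_inactive = 0.30, rho = 0.2, seed = 22)
  expect_lt(abs(cor(g, a) - 0.2), 0.02)
  # marginal inactive proportion preserved for any rho
  expect_lt(abs(mean(a == 0) - 0.30), 3 * sqrt(0.3 * 0.7 / n))
  a2 <- simulate_activity(g, p_inactive = 0.45, rho = -0.3, seed = 23)
  expect_lt(abs(mean(a2 == 0) - 0.45), 3 * sqrt(0.45 * 0.55 / n))
  expect_lt(abs(cor(g, a2) + 0.3), 0.02)
})

test_that("activity variance peaks at a balanced split", {
  g <- simulate_grs(100000, seed = 31)
  a <- simulate_activity(g, p_inactive = 0.5, seed = 32)
  expect_lt(abs(var(a) - 0.25), 0.005)
  expect_lte(var(a), 0.2501)
})

test_that("BMI follows the linear interaction model", {
  spec <- cohort_spec(6, sigma_bmi = 0, beta_ge = 0, seed = 1)
  grs <- c(8, 10, 12, 14, 9, 11)
  act <- c(0, 1, 0, 1, 1, 0)
  bmi <- simulate_bmi(grs, act, spec)
  expect_equal(bmi, spec$intercept + 0.154 * grs - 0.313 * act)
  # defaults carry the published base-scenario effects
  expect_equal(spec$beta_g, 0.154)
  expect_equal(spec$beta_e, -0.313)
})

test_that("OLS refit recovers the generating coefficients", {
  n <- 50000
  spec <- cohort_spec(n, seed = 77)
  co <- simulate_cohort(spec)
  fit <- lm(bmi ~ grs * activity_binary, data = co)
  est <- coef(summary(fit))
  truth <- c(spec$intercept, spec$beta_g, spec$beta_e, spec$beta_ge)
  for (i in 1:4) {
    expect_lt(abs(est[i, "Estimate"] - truth[i]), 3 * est[i, "Std. Error"])
  }
})

test_that("missingness injection is MCAR at the requested rate", {
  geno <- simulate_genotypes(2000, seed = 41)
  expect_identical(inject_missing_genotypes(geno, 0), geno)
  all_na <- inject_missing_genotypes(geno, 1, seed = 42)
  expect_true(all(is.na(all_na)))
  some <- inject_missing_genotypes(geno, 0.05, seed = 43)
  frac <- mean(is.na(some))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(geno)))
})

test_that("genotype-built GRS obeys the binomial-sum moment identity", {
  freqs <- default_panel_freqs()
  n <- 50000
  geno <- simulate_genotypes(n, freqs, seed = 51)
  grs <- rowSums(geno)
  mu <- sum(2 * freqs)
  v <- sum(2 * freqs * (1 - freqs))
  expect_equal(mu, 11.2, tolerance = 1e-12)
  expect_lt(abs(mean(grs) - mu), 3 * sqrt(v / n))
  expect_lt(abs(var(grs) - v), 3 * v * sqrt(2 / (n - 1)))
})

test_that("multi-cohort generation shares or disperses the interaction", {
  specs <- replicate(4, cohort_spec(300, beta_ge = -0.07), simplify = FALSE)
  cohorts <- simulate_multi_cohort(specs, between_sd = 0, master_seed = 5)
  betas <- vapply(cohorts, attr, numeric(1), "beta_ge")
  expect_true(all(betas == -0.07))
  expect_identical(names(cohorts), paste0("cohort", 1:4))
  # piecewise reproducible: regenerating gives the same cohorts
  again <- simulate_multi_cohort(specs, between_sd = 0, master_seed = 5)
  expect_identical(cohorts[[2]]$bmi, again[[2]]$bmi)
  spread <- simulate_multi_cohort(specs, between_sd = 0.02, master_seed = 5)
  expect_gt(sd(vapply(spread, attr, numeric(1), "beta_ge")), 0)
  expect_error(simulate_multi_cohort(specs, between_sd = -1), ">= 0")
})

test_that("cohort spec validates its parameters", {
  expect_error(cohort_spec(100, p_inactive = 0), "p_inactive")
  expect_error(cohort_spec(100, rho_grs_activity = 1), "rho")
  expect_error(cohort_spec(100, grs_variance = 0), "grs_variance")
  expect_error(cohort_spec(100, sigma_bmi = -1), "sigma_bmi")
  expect_error(cohort_spec(100, beta_g = Inf), "finite")
  expect_error(cohort_spec(100, risk_allele_freqs = rep(0.4, 11)), "12")
})
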