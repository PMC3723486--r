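# Shared fixtures, all generated in code.

# Small full-rank regression dataset for closed-form OLS comparisons.
make_ols_data <- function(n = 60, seed = 42) {
  set.seed(seed)
  data.frame(
    grs = rnorm(n, 11, 2),
    activity_binary = rbinom(n, 1, 0.7),
    age = rnorm(n, 50, 8),
    sex = rbinom(n, 1, 0.5),
    bmi = rnorm(n, 26, 3))
}

# Individual-level rows realizing a 2x2 exposure x obesity table with
# counts (exposed-obese, exposed-normal, unexposed-obese, unexposed-normal).
make_2x2_cohort <- function(a = 30, b = 70, c = 20, d = 80) {
  data.frame(
    grs = rep(c(1, 1, 0, 0), c(a, b, c, d)),
    bmi = rep(c(32, 22, 32, 22), c(a, b, c, d)))
}

# Cohort estimate table for meta-analysis tests.
make_estimates <- function(beta, se, n = NULL, cohort = NULL) {
  k <- length(beta)
  data.frame(
    cohort = if (is.null(cohort)) paste0("C", seq_len(k)) else cohort,
    n = if (is.null(n)) rep(1000, k) else n,
    beta = beta,
    se = rep_len(se, k))
}
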