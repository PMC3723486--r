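#' Default risk-allele frequencies for the 12-locus obesity panel
#'
#' Plausible European risk-allele frequencies for the 12 obesity
#' susceptibility loci, in panel order (see [risk_allele_map()]). They are
#' chosen so the expected genotype-built GRS, `sum(2 * freqs)`, equals 11.2
#' alleles and its variance, `sum(2 * freqs * (1 - freqs))`, is close to 5.05
#' alleles squared, matching the normal approximation used throughout the
#' power framework.
#'
#' @return Named numeric vector of length 12.
#' @export
#' @examples
#' sum(2 * default_panel_freqs())  # expected GRS = 11.2
default_panel_freqs <- function() {
  c(FTO    = 0.43, SH2B1 = 0.40, SEC16B = 0.19, MTCH2 = 0.36,
    MC4R   = 0.24, NEGR1 = 0.61, TMEM18 = 0.82, GNPDA2 = 0.43,
    BDNF   = 0.28, KCTD15 = 0.65, ETV5  = 0.78, FAIM2  = 0.41)
}

#' Specify a synthetic cohort
#'
#' Bundles every parameter of the generating model for a synthetic cohort:
#' BMI is linear in the genetic risk score (GRS), a binary physical-activity
#' indicator (1 = active), and their product, with Gaussian residual noise,
#'
#' \deqn{BMI_i = \mu + \beta_G G_i + \beta_E E_i + \beta_{GE} G_i E_i +
#'   \epsilon_i, \quad \epsilon_i \sim N(0, \sigma^2).}
#'
#' Defaults are the base scenario of the power study: GRS ~ Normal(11.2,
#' 5.06), 30% inactive, \eqn{\beta_G} = 0.154 kg/m2 per allele, \eqn{\beta_E}
#' = -0.313 kg/m2 (active vs inactive), \eqn{\beta_{GE}} = -0.07 kg/m2 per
#' allele per activity unit, residual SD 3.5 kg/m2.
#'
#' @param n_participants Cohort size (>= 1).
#' @param risk_allele_freqs Optional vector of 12 risk-allele frequencies in
#'   (0, 1); when supplied, [simulate_cohort()] draws genotypes and builds the
#'   GRS by allele counting instead of the direct normal draw.
#' @param grs_mean,grs_variance Mean (alleles) and variance (alleles^2) of
#'   the directly simulated GRS.
#' @param p_inactive Population proportion inactive, in (0, 1).
#' @param rho_grs_activity Target point-biserial correlation between GRS and
#'   the activity indicator, |rho| < 1 (0 = independent).
#' @param beta_g,beta_e,beta_ge Marginal GRS, marginal activity, and
#'   interaction effects on BMI (kg/m2).
#' @param sigma_bmi Residual SD of BMI given the predictors (kg/m2), >= 0.
#' @param intercept Model intercept (kg/m2).
#' @param cohort_id Label attached to every participant.
#' @param seed Integer seed; the same spec and seed reproduce an identical
#'   cohort.
#'
#' @return An object of class `cohort_spec` (a named list).
#' @seealso [simulate_cohort()], [simulate_multi_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(1000, seed = 1)
#' head(simulate_cohort(spec))
cohort_spec <- function(n_participants,
                        risk_allele_freqs = NULL,
                        grs_mean = 11.2, grs_variance = 5.06,
                        p_inactive = 0.30, rho_grs_activity = 0,
                        beta_g = 0.154, beta_e = -0.313, beta_ge = -0.07,
                        sigma_bmi = 3.5, intercept = 25.5,
                        cohort_id = "cohort1", seed = NULL) {
  stopifnot(is.numeric(n_participants), length(n_participants) == 1L,
            n_participants >= 1)
  if (!is.null(risk_allele_freqs)) {
    if (length(risk_allele_freqs) != 12L)
      stop("`risk_allele_freqs` must have exactly 12 entries", call. = FALSE)
    check_freqs(risk_allele_freqs)
  }
  stop_if_not_scalar_prob(p_inactive, "p_inactive")
  if (!is.numeric(rho_grs_activity) || abs(rho_grs_activity) >= 1)
    stop("`rho_grs_activity` must satisfy |rho| < 1", call. = FALSE)
  if (!is.finite(grs_variance) || grs_variance <= 0)
    stop("`grs_variance` must be > 0", call. = FALSE)
  if (!is.finite(sigma_bmi) || sigma_bmi < 0)
    stop("`sigma_bmi` must be >= 0", call. = FALSE)
  for (p in c(beta_g = beta_g, beta_e = beta_e, beta_ge = beta_ge,
              intercept = intercept)) {
    if (!is.finite(p)) stop("model coefficients must be finite", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         risk_allele_freqs = risk_allele_freqs,
         grs_mean = grs_mean, grs_variance = grs_variance,
         p_inactive = p_inactive, rho_grs_activity = rho_grs_activity,
         beta_g = beta_g, beta_e = beta_e, beta_ge = beta_ge,
         sigma_bmi = sigma_bmi, intercept = intercept,
         cohort_id = cohort_id, seed = seed),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  n = %d (%s)\n", x$n_participants, x$cohort_id))
  cat(sprintf("  GRS: %s; mean %.3g, variance %.3g\n",
              if (is.null(x$risk_allele_freqs)) "direct normal"
              else "12-locus genotypes", x$grs_mean, x$grs_variance))
  cat(sprintf("  activity: p_inactive %.2f, rho(GRS, activity) %.2f\n",
              x$p_inactive, x$rho_grs_activity))
  cat(sprintf("  BMI: %.3g + %.3g GRS %+.3g act %+.3g GRS:act + N(0, %.3g^2)\n",
              x$intercept, x$beta_g, x$beta_e, x$beta_ge, x$sigma_bmi))
  invisible(x)
}

check_freqs <- function(freqs) {
  nm <- names(freqs)
  if (is.null(nm)) nm <- paste0("locus", seq_along(freqs))
  bad <- which(!is.finite(freqs) | freqs <= 0 | freqs >= 1)
  if (length(bad)) {
    stop(sprintf("risk-allele frequency out of (0, 1) at: %s",
                 paste(nm[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(freqs)
}

#' Simulate genotype dosages under Hardy-Weinberg proportions
#'
#' Draws each dosage independently as Binomial(2, freq), i.e. unlinked loci
#' in Hardy-Weinberg equilibrium, with dosage counting the risk allele.
#'
#' @param n Number of participants.
#' @param freqs Risk-allele frequencies in (0, 1); defaults to the 12-locus
#'   panel of [default_panel_freqs()]. Columns are ordered as given.
#' @param seed Optional integer seed.
#' @return Integer matrix (`n` rows) with one column per locus, column names
#'   from `freqs`, and a `counted_allele` attribute marking every column as
#'   counting the risk allele.
#' @export
simulate_genotypes <- function(n, freqs = default_panel_freqs(), seed = NULL) {
  stopifnot(n >= 1)
  check_freqs(freqs)
  nm <- names(freqs)
  if (is.null(nm)) nm <- paste0("locus", seq_along(freqs))
  geno <- with_seed(seed, {
    vapply(freqs, function(f) stats::rbinom(n, 2L, f), integer(n))
  })
  geno <- matrix(geno, nrow = n, dimnames = list(NULL, nm))
  map <- risk_allele_map()
  counted <- if (all(nm %in% map$gene)) {
    stats::setNames(map$risk_allele[match(nm, map$gene)], nm)
  } else {
    stats::setNames(rep(NA_character_, length(nm)), nm)
  }
  attr(geno, "counted_allele") <- counted
  geno
}

#' Simulate a genetic risk score directly from a normal distribution
#'
#' Used by the power framework when genotype-level detail is unnecessary:
#' the 12-SNP GRS is approximated by Normal(mean, variance).
#'
#' @param n Number of draws.
#' @param mean Mean in alleles (default 11.2).
#' @param variance Variance in alleles squared (default 5.06).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_grs <- function(n, mean = 11.2, variance = 5.06, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.finite(variance) || variance < 0)
    stop("`variance` must be >= 0", call. = FALSE)
  with_seed(seed, stats::rnorm(n, mean, sqrt(variance)))
}

# Latent-correlation coefficient for the Gaussian-copula activity draw:
# activity = 1{a * z_grs + sqrt(1 - a^2) * noise > qnorm(p_inactive)}.
# With standardized normal GRS the point-biserial correlation is
# a * dnorm(c) / sqrt(p (1 - p)), c = qnorm(p_inactive), so invert for a.
latent_rho <- function(rho, p_inactive) {
  c0 <- stats::qnorm(p_inactive)
  a <- rho * sqrt(p_inactive * (1 - p_inactive)) / stats::dnorm(c0)
  if (!is.finite(a) || abs(a) > 1) {
    stop(sprintf(
      "target correlation %.3g is unattainable at p_inactive = %.3g", rho,
      p_inactive), call. = FALSE)
  }
  a
}

#' Simulate a binary physical-activity indicator
#'
#' Codes activity 1 = active, 0 = inactive. With `rho = 0` the indicator is
#' i.i.d. Bernoulli(1 - p_inactive). With `rho != 0` a Gaussian copula is
#' used: a latent normal is built as `a * scale(grs) + sqrt(1 - a^2) * noise`
#' and thresholded at `qnorm(p_inactive)`, with `a` chosen so the realized
#' point-biserial correlation between the GRS and the indicator equals `rho`
#' when the GRS is normal (see Details).
#'
#' @details For a standard bivariate normal pair with latent correlation `a`
#' and threshold `c = qnorm(p_inactive)`, `cor(G, 1{L > c}) = a * dnorm(c) /
#' sqrt(p(1-p))`, so `a = rho * sqrt(p(1-p)) / dnorm(c)`. The marginal
#' inactive proportion is `p_inactive` exactly in expectation for any `rho`.
#'
#' @param grs Numeric GRS vector (length >= 1).
#' @param p_inactive Proportion inactive, in (0, 1); default 0.30.
#' @param rho Target GRS-activity point-biserial correlation, |rho| < 1.
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector the length of `grs`.
#' @export
simulate_activity <- function(grs, p_inactive = 0.30, rho = 0, seed = NULL) {
  if (length(grs) == 0L) stop("`grs` must have length >= 1", call. = FALSE)
  stop_if_not_scalar_prob(p_inactive, "p_inactive")
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  n <- length(grs)
  with_seed(seed, {
    if (rho == 0) {
      stats::rbinom(n, 1L, 1 - p_inactive)
    } else {
      s <- stats::sd(grs)
      if (!is.finite(s) || s == 0)
        stop("cannot correlate activity with a constant GRS", call. = FALSE)
      a <- latent_rho(rho, p_inactive)
      z <- (grs - mean(grs)) / s
      latent <- a * z + sqrt(1 - a^2) * stats::rnorm(n)
      as.integer(latent > stats::qnorm(p_inactive))
    }
  })
}

#' Simulate BMI from the linear interaction model
#'
#' @param grs,activity Conformable numeric vectors; activity coded 1 = active.
#' @param spec A [cohort_spec()] supplying the coefficients and residual SD.
#' @param seed Optional integer seed.
#' @return Numeric BMI vector (kg/m2).
#' @export
simulate_bmi <- function(grs, activity, spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), length(grs) == length(activity))
  mu <- spec$intercept + spec$beta_g * grs + spec$beta_e * activity +
    spec$beta_ge * grs * activity
  with_seed(seed, mu + stats::rnorm(length(grs), 0, spec$sigma_bmi))
}

#' Set genotype entries missing completely at random
#'
#' Testing utility for the GRS imputation and exclusion rules: each dosage is
#' independently replaced by `NA` with probability `rate`.
#'
#' @param geno Genotype dosage matrix.
#' @param rate Missingness probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return The matrix with `NA` marking missing calls.
#' @export
inject_missing_genotypes <- function(geno, rate, seed = NULL) {
  stop_if_not_scalar_prob(rate, "rate", open = FALSE)
  if (rate == 0) return(geno)
  out <- geno
  with_seed(seed, {
    miss <- stats::runif(length(out)) < rate
    out[miss] <- NA
  })
  out
}

#' Generate a complete synthetic cohort
#'
#' Draws the GRS (directly normal, or summed from Hardy-Weinberg genotypes
#' when `spec$risk_allele_freqs` is set), the binary activity indicator, a
#' four-level activity index consistent with it (level 1 = inactive), BMI
#' from the linear interaction model, and demographic covariates (age, sex,
#' height) that are independent of the model so they perturb nothing.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with columns `participant_id`, `cohort_id`, `grs`,
#'   `activity_binary`, `activity_cpai`, `age`, `sex`, `height_m`, `bmi`,
#'   plus a `genotypes` attribute when genotypes were drawn.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(spec$seed, {
    if (is.null(spec$risk_allele_freqs)) {
      geno <- NULL
      grs <- stats::rnorm(n, spec$grs_mean, sqrt(spec$grs_variance))
    } else {
      geno <- simulate_genotypes(n, spec$risk_allele_freqs)
      grs <- rowSums(geno)
    }
    act <- simulate_activity(grs, spec$p_inactive, spec$rho_grs_activity)
    # actives spread over CPAI 2-4 with the marginal pattern seen in large
    # European cohorts; inactive participants are CPAI 1 by construction
    cpai <- ifelse(act == 0L, 1L,
                   sample(2:4, n, replace = TRUE, prob = c(0.40, 0.33, 0.27)))
    bmi <- simulate_bmi(grs, act, spec)
    out <- data.frame(
      participant_id = seq_len(n),
      cohort_id = spec$cohort_id,
      grs = grs,
      activity_binary = as.integer(act),
      activity_cpai = as.integer(cpai),
      age = round(pmin(pmax(stats::rnorm(n, 55, 10), 20), 85), 1),
      sex = stats::rbinom(n, 1L, 0.5),
      height_m = round(stats::rnorm(n, 1.70, 0.09), 3),
      bmi = bmi)
    if (!is.null(geno)) attr(out, "genotypes") <- geno
    out
  })
}

#' Generate several cohorts with between-cohort interaction heterogeneity
#'
#' Each cohort's interaction coefficient is drawn from
#' Normal(shared beta_ge, between_sd^2); cohort `i` is then generated with
#' seed `master_seed + i`, so multi-cohort runs are reproducible piecewise.
#'
#' @param specs List of [cohort_spec()] objects (>= 1); their `beta_ge` is
#'   taken as the shared value from the first spec.
#' @param between_sd SD of the per-cohort interaction coefficients (>= 0).
#' @param master_seed Integer master seed.
#' @return List of cohort `data.frame`s; each carries its realized
#'   interaction coefficient as attribute `beta_ge`.
#' @export
simulate_multi_cohort <- function(specs, between_sd = 0, master_seed = 1L) {
  stopifnot(is.list(specs), length(specs) >= 1L,
            all(vapply(specs, inherits, TRUE, "cohort_spec")))
  if (!is.finite(between_sd) || between_sd < 0)
    stop("`between_sd` must be >= 0", call. = FALSE)
  shared <- specs[[1L]]$beta_ge
  k <- length(specs)
  betas <- with_seed(master_seed, stats::rnorm(k, shared, between_sd))
  out <- vector("list", k)
  for (i in seq_len(k)) {
    sp <- specs[[i]]
    sp$beta_ge <- betas[i]
    sp$seed <- master_seed + i
    if (identical(sp$cohort_id, "cohort1") && k > 1L)
      sp$cohort_id <- paste0("cohort", i)
    cohort <- simulate_cohort(sp)
    attr(cohort, "beta_ge") <- betas[i]
    out[[i]] <- cohort
  }
  names(out) <- vapply(out, function(d) d$cohort_id[1L], "")
  out
}
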