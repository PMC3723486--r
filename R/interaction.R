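#' Classify BMI into WHO categories
#'
#' Half-open intervals: underweight BMI < 18.5, normal 18.5 <= BMI < 25,
#' overweight 25 <= BMI < 30, obese BMI >= 30 kg/m2.
#'
#' @param bmi Numeric BMI vector (kg/m2).
#' @return Factor with levels underweight, normal, overweight, obese.
#' @export
classify_bmi <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf),
      labels = c("underweight", "normal", "overweight", "obese"),
      right = FALSE)
}

# Assemble the adjustment design shared by the linear and logistic fits:
# age centered before squaring (near-collinearity guard), sex as given,
# center as indicator contrasts -- dropped with a warning when the cohort
# has a single center, since multicenter adjustment is conditional.
build_model_data <- function(data, grs, activity, covariates, center) {
  if (is.null(activity)) {
    md <- data.frame(.grs = data[[grs]])
    rhs <- ".grs"
  } else {
    md <- data.frame(.grs = data[[grs]], .activity = data[[activity]])
    rhs <- c(".grs", ".activity", ".grs:.activity")
  }
  for (v in covariates) {
    if (!v %in% names(data)) stop(sprintf("covariate `%s` not found", v),
                                  call. = FALSE)
    if (v == "age") {
      age_c <- data$age - mean(data$age, na.rm = TRUE)
      md$.age <- age_c
      md$.age2 <- age_c^2
      rhs <- c(rhs, ".age", ".age2")
    } else {
      md[[paste0(".", v)]] <- data[[v]]
      rhs <- c(rhs, paste0(".", v))
    }
  }
  if (!is.null(center)) {
    f <- factor(data[[center]])
    if (nlevels(f) < 2L) {
      warning("single study center: center adjustment dropped", call. = FALSE)
    } else {
      md$.center <- f
      rhs <- c(rhs, ".center")
    }
  }
  list(data = md, formula = stats::reformulate(rhs, response = ".y"))
}

wald_table <- function(coefs, ses, df = Inf) {
  z <- coefs / ses
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = names(coefs), estimate = unname(coefs),
             se = unname(ses), z = unname(z), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Fit the BMI gene-by-activity interaction model
#'
#' Ordinary least squares for
#' `BMI ~ GRS + activity + GRS:activity + age + age^2 + sex (+ center)`,
#' the standard adjustment set for cohort analyses of this design. Age is
#' centered before squaring; study center enters as indicator contrasts and
#' is dropped (with a warning) for single-center cohorts. Per-term two-sided
#' p-values use the large-sample Wald z statistic.
#'
#' @param data Cohort `data.frame` containing the outcome and predictors.
#' @param grs,activity Column names of the score and the activity variable
#'   (binary 0/1 or CPAI level 1-4 entered as a linear trend). Setting
#'   `activity = NULL` fits the marginal genetic model without activity or
#'   interaction terms.
#' @param outcome Column name of the BMI outcome (default `"bmi"`).
#' @param covariates Adjustment covariates; `"age"` expands to centered age
#'   and its square. Default `c("age", "sex")`.
#' @param center Optional column name of the study-center label.
#' @return An object of class `gxe_fit`: the per-term Wald table, the
#'   interaction row, `n`, the outcome scale, and the underlying `lm` fit.
#' @seealso [fit_obesity_logistic()], [stratified_effects()],
#'   [cohort_estimate()]
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(2000, seed = 7))
#' fit <- fit_bmi_interaction(cohort)
#' summary(fit)
fit_bmi_interaction <- function(data, grs = "grs",
                                activity = "activity_binary",
                                outcome = "bmi",
                                covariates = c("age", "sex"),
                                center = NULL) {
  built <- build_model_data(data, grs, activity, covariates, center)
  md <- built$data
  md$.y <- data[[outcome]]
  md <- md[stats::complete.cases(md), , drop = FALSE]
  if (nrow(md) < 50L)
    stop("fewer than 50 complete cases", call. = FALSE)
  fit <- stats::lm(built$formula, data = md)
  tab <- wald_table(stats::coef(fit), sqrt(diag(stats::vcov(fit))))
  structure(
    list(coefficients = tab, interaction_term = ".grs:.activity",
         n = nrow(md), outcome_scale = "kg/m2", model = "ols", fit = fit),
    class = "gxe_fit")
}

#' Fit the logistic obesity interaction model
#'
#' Maximum-likelihood logistic regression of obese (BMI >= 30) versus
#' normal weight (18.5 <= BMI < 25); overweight and underweight participants
#' are excluded from the contrast. Same predictor structure as
#' [fit_bmi_interaction()]; estimates are reported on the log-odds scale
#' with odds ratios and 95% confidence intervals alongside.
#'
#' @inheritParams fit_bmi_interaction
#' @param interaction Include the GRS x activity term (default `TRUE`);
#'   set `FALSE` for the marginal genetic-association model.
#' @return A `gxe_fit` with `outcome_scale = "log-odds"` and an `or_table`
#'   element (OR, 95% CI per term).
#' @export
fit_obesity_logistic <- function(data, grs = "grs",
                                 activity = "activity_binary",
                                 outcome = "bmi",
                                 covariates = c("age", "sex"),
                                 center = NULL, interaction = TRUE) {
  cls <- classify_bmi(data[[outcome]])
  keep <- cls %in% c("normal", "obese")
  data <- data[keep, , drop = FALSE]
  if (is.null(activity)) interaction <- FALSE
  built <- build_model_data(data, grs, activity, covariates, center)
  md <- built$data
  md$.y <- as.integer(cls[keep] == "obese")
  if (!interaction && !is.null(activity)) {
    built$formula <- stats::update(built$formula, . ~ . - .grs:.activity)
  }
  md <- md[stats::complete.cases(md), , drop = FALSE]
  if (nrow(md) < 50L) stop("fewer than 50 complete cases", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(built$formula, family = stats::binomial(), data = md))
  co <- stats::coef(fit)
  if (!fit$converged || any(abs(co[-1L]) > 15)) {
    stop(paste0(
      "logistic fit did not converge to finite estimates ",
      "(complete or quasi-complete separation suspected); ",
      "largest |log-odds| = ", fmt_num(max(abs(co[-1L])))), call. = FALSE)
  }
  tab <- wald_table(co, sqrt(diag(stats::vcov(fit))))
  or <- data.frame(term = tab$term, or = exp(tab$estimate),
                   ci_lo = exp(tab$estimate - 1.959964 * tab$se),
                   ci_hi = exp(tab$estimate + 1.959964 * tab$se),
                   p = tab$p, stringsAsFactors = FALSE)
  structure(
    list(coefficients = tab, or_table = or,
         interaction_term = if (interaction) ".grs:.activity" else NA,
         n = nrow(md), outcome_scale = "log-odds", model = "logistic",
         fit = fit),
    class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Gene x activity %s fit (n = %d, outcome scale %s)\n",
              if (x$model == "ols") "linear" else "logistic",
              x$n, x$outcome_scale))
  tab <- x$coefficients
  tab[, -1] <- lapply(tab[, -1], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.gxe_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              or_table = object$or_table,
              interaction = interaction_row(object),
              n = object$n, model = object$model)
  class(out) <- "summary.gxe_fit"
  out
}

#' @export
print.summary.gxe_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s interaction model, n = %d\n",
              if (x$model == "ols") "Linear (BMI)" else "Logistic (obesity)",
              x$n))
  tab <- x$coefficients
  tab[, -1] <- lapply(tab[, -1], signif, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$interaction) && nrow(x$interaction)) {
    cat(sprintf("\nInteraction: %s = %s (SE %s), p = %s\n",
                x$interaction$term, fmt_num(x$interaction$estimate),
                fmt_num(x$interaction$se), fmt_num(x$interaction$p)))
  }
  if (!is.null(x$or_table)) {
    cat("\nOdds ratios (95% CI):\n")
    or <- x$or_table
    or[, -1] <- lapply(or[, -1], signif, digits)
    print(or, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.gxe_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.gxe_fit <- function(object, ...) stats::vcov(object$fit)

#' @export
confint.gxe_fit <- function(object, parm, level = 0.95, ...) {
  tab <- object$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(tab$estimate - z * tab$se, tab$estimate + z * tab$se)
  rownames(ci) <- tab$term
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.gxe_fit <- function(object, ...) stats::predict(object$fit, ...)

#' @export
residuals.gxe_fit <- function(object, ...) stats::residuals(object$fit, ...)

interaction_row <- function(fit) {
  fit$coefficients[fit$coefficients$term == fit$interaction_term, ,
                   drop = FALSE]
}

#' Extract a cohort's interaction estimate for meta-analysis
#'
#' @param fit A `gxe_fit` from [fit_bmi_interaction()] or
#'   [fit_obesity_logistic()].
#' @param label Cohort label.
#' @return One-row `data.frame` with `cohort`, `n`, `beta`, `se` — the unit
#'   pooled by [pool_estimates()].
#' @export
cohort_estimate <- function(fit, label = "cohort") {
  stopifnot(inherits(fit, "gxe_fit"))
  row <- interaction_row(fit)
  if (nrow(row) == 0L) stop("fit has no interaction term", call. = FALSE)
  data.frame(cohort = label, n = fit$n, beta = row$estimate, se = row$se,
             stringsAsFactors = FALSE)
}

#' Genetic effect on BMI by activity stratum
#'
#' Refits the marginal GRS model (`BMI ~ GRS + covariates`) within each
#' activity stratum and reports per-stratum slopes. For two strata, the
#' active-minus-inactive slope difference (with SE combined under
#' independence) approximates the interaction coefficient; it equals the
#' interaction estimate exactly when the interaction model is saturated in
#' activity (no covariates shared across strata).
#'
#' @inheritParams fit_bmi_interaction
#' @param strata Column name of the stratifying variable (e.g. the binary
#'   activity indicator or CPAI level).
#' @param min_n Minimum complete cases per stratum (default 50); smaller
#'   strata are omitted with a warning.
#' @return A list of class `gxe_strata`: `strata` (per-stratum slope table)
#'   and, for two strata, `difference` (slope difference, SE, z, p).
#' @export
stratified_effects <- function(data, strata = "activity_binary",
                               grs = "grs", outcome = "bmi",
                               covariates = c("age", "sex"),
                               center = NULL, min_n = 50L) {
  f <- factor(data[[strata]])
  levs <- levels(f)
  rows <- list()
  for (lv in levs) {
    d <- data[!is.na(f) & f == lv, , drop = FALSE]
    built <- build_model_data(
      d, grs, grs, covariates,
      if (!is.null(center) && nlevels(factor(d[[center]])) > 1L) center
      else NULL)
    md <- built$data
    md$.activity <- NULL
    md$.y <- d[[outcome]]
    md <- md[stats::complete.cases(md), , drop = FALSE]
    if (nrow(md) < min_n) {
      warning(sprintf("stratum %s has %d complete cases; omitted", lv,
                      nrow(md)), call. = FALSE)
      next
    }
    rhs <- setdiff(names(md), ".y")
    fit <- stats::lm(stats::reformulate(rhs, ".y"), data = md)
    rows[[lv]] <- data.frame(
      stratum = lv, n = nrow(md),
      beta_g = stats::coef(fit)[[".grs"]],
      se = sqrt(stats::vcov(fit)[".grs", ".grs"]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no stratum met the size requirement", call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  out <- list(strata = tab, difference = NULL)
  if (nrow(tab) == 2L) {
    diff <- tab$beta_g[2L] - tab$beta_g[1L]
    se <- sqrt(sum(tab$se^2))
    out$difference <- data.frame(
      contrast = paste(tab$stratum[2L], "-", tab$stratum[1L]),
      estimate = diff, se = se, z = diff / se,
      p = 2 * stats::pnorm(-abs(diff / se)), stringsAsFactors = FALSE)
  }
  class(out) <- "gxe_strata"
  out
}

#' @export
print.gxe_strata <- function(x, digits = 4, ...) {
  cat("Per-stratum genetic effect on BMI (kg/m2 per allele)\n")
  tab <- x$strata
  tab[, c("beta_g", "se")] <- lapply(tab[, c("beta_g", "se")], signif, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$difference)) {
    d <- x$difference
    cat(sprintf("Slope difference (%s): %s (SE %s), p = %s\n", d$contrast,
                fmt_num(d$estimate), fmt_num(d$se), fmt_num(d$p)))
  }
  invisible(x)
}

#' Convert a per-allele BMI effect to body weight
#'
#' Expresses a BMI coefficient (kg/m2) as grams of body weight for a person
#' of the given height: `grams = beta * height^2 * 1000`.
#'
#' @param beta BMI effect in kg/m2.
#' @param height Height in meters (default 1.70).
#' @param round Round to the nearest gram for display (default `TRUE`).
#' @return Weight difference in grams.
#' @export
#' @examples
#' beta_to_weight(0.161)  # 465 g
beta_to_weight <- function(beta, height = 1.70, round = TRUE) {
  stopifnot(is.numeric(beta), height > 0)
  g <- beta * height^2 * 1000
  if (round) round(g) else g
}

#' Adjusted least-squares mean BMI by GRS and activity group
#'
#' Fits `BMI ~ GRS group x activity group + covariates` and reports the
#' covariate-adjusted predicted mean (and 95% CI) in each of the four cells,
#' i.e. predictions at the average covariate values, plus the high-minus-low
#' GRS difference within each activity group with its standard error.
#'
#' @param data Cohort `data.frame`.
#' @param grs_binary,activity_binary Column names of the two 0/1 factors.
#' @param outcome BMI column (default `"bmi"`).
#' @param covariates Adjustment covariates as in [fit_bmi_interaction()];
#'   may be empty.
#' @return A list of class `gxe_lsmeans`: `cells` (per-cell adjusted mean,
#'   SE, 95% CI, n) and `grs_contrast` (per activity group).
#' @export
lsmeans_by_group <- function(data, grs_binary = "grs_high",
                             activity_binary = "activity_binary",
                             outcome = "bmi",
                             covariates = c("age", "sex")) {
  g <- data[[grs_binary]]
  a <- data[[activity_binary]]
  if (!all(stats::na.omit(g) %in% 0:1) || !all(stats::na.omit(a) %in% 0:1))
    stop("both grouping variables must be binary 0/1", call. = FALSE)
  built <- build_model_data(data, grs_binary, activity_binary, covariates,
                            NULL)
  md <- built$data
  md$.y <- data[[outcome]]
  md <- md[stats::complete.cases(md), , drop = FALSE]
  cells <- expand.grid(.grs = 0:1, .activity = 0:1)
  n_cell <- mapply(function(gg, aa) sum(md$.grs == gg & md$.activity == aa),
                   cells$.grs, cells$.activity)
  if (any(n_cell == 0L)) stop("empty GRS x activity cell", call. = FALSE)
  fit <- stats::lm(built$formula, data = md)
  covs <- setdiff(names(md), c(".y", ".grs", ".activity"))
  newdata <- cells
  for (v in covs) newdata[[v]] <- mean(md[[v]])
  pr <- stats::predict(fit, newdata = newdata, se.fit = TRUE)
  cells_out <- data.frame(
    grs_group = ifelse(cells$.grs == 1, "high", "low"),
    activity_group = ifelse(cells$.activity == 1, "active", "inactive"),
    n = n_cell, mean = pr$fit, se = pr$se.fit,
    ci_lo = pr$fit - 1.959964 * pr$se.fit,
    ci_hi = pr$fit + 1.959964 * pr$se.fit, stringsAsFactors = FALSE)
  # high-minus-low GRS contrast inside each activity group via c'beta
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                           newdata)
  V <- stats::vcov(fit)
  contrast <- function(act) {
    hi <- X[cells$.grs == 1 & cells$.activity == act, , drop = FALSE]
    lo <- X[cells$.grs == 0 & cells$.activity == act, , drop = FALSE]
    cvec <- as.numeric(hi - lo)
    est <- sum(cvec * stats::coef(fit))
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    data.frame(activity_group = if (act == 1) "active" else "inactive",
               estimate = est, se = se,
               p = 2 * stats::pnorm(-abs(est / se)), stringsAsFactors = FALSE)
  }
  out <- list(cells = cells_out,
              grs_contrast = rbind(contrast(0), contrast(1)),
              n = nrow(md))
  class(out) <- "gxe_lsmeans"
  out
}

#' @export
print.gxe_lsmeans <- function(x, digits = 4, ...) {
  cat(sprintf("Adjusted mean BMI by GRS and activity group (n = %d)\n", x$n))
  cells <- x$cells
  num <- c("mean", "se", "ci_lo", "ci_hi")
  cells[, num] <- lapply(cells[, num], signif, digits)
  print(cells, row.names = FALSE)
  cat("\nHigh - low GRS difference by activity group:\n")
  ct <- x$grs_contrast
  ct[, -1] <- lapply(ct[, -1], signif, digits)
  print(ct, row.names = FALSE)
  invisible(x)
}
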