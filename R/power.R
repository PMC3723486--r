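#' Specify a power-simulation scenario
#'
#' Full parameterization of one Monte-Carlo power setting for the
#' GRS x activity interaction test. Defaults are the base scenario: GRS ~
#' Normal(11.2, 5.06) (optionally dichotomized at its mean), 30% inactive,
#' effects beta_g = 0.154, beta_e = -0.313, beta_ge = -0.07 kg/m2, residual
#' SD 3.5 kg/m2, two-sided alpha 0.05, 1,000 iterations.
#'
#' @param n Sample size per iteration (>= 4).
#' @param beta_g,beta_e,beta_ge Marginal and interaction effects (kg/m2).
#' @param grs_mean,grs_variance GRS distribution parameters.
#' @param grs_binary Dichotomize the GRS at `grs_mean` before fitting
#'   (default `FALSE`). The interaction effect stays on its per-unit scale.
#' @param p_inactive Proportion inactive in (0, 1).
#' @param rho Target GRS-activity correlation (see [simulate_activity()]).
#' @param sigma Residual BMI SD (kg/m2), > 0.
#' @param alpha Two-sided test level in (0, 1).
#' @param n_iter Monte-Carlo iterations (>= 100).
#' @param seed Optional integer seed.
#' @return Object of class `power_scenario`.
#' @seealso [analytic_power()], [simulate_power()], [required_sample_size()]
#' @export
power_scenario <- function(n = 20000, beta_g = 0.154, beta_e = -0.313,
                           beta_ge = -0.07, grs_mean = 11.2,
                           grs_variance = 5.06, grs_binary = FALSE,
                           p_inactive = 0.30, rho = 0, sigma = 3.5,
                           alpha = 0.05, n_iter = 1000, seed = NULL) {
  stopifnot(n >= 4, n_iter >= 100, sigma > 0, grs_variance > 0,
            is.logical(grs_binary), abs(rho) < 1)
  stop_if_not_scalar_prob(alpha, "alpha")
  stop_if_not_scalar_prob(p_inactive, "p_inactive")
  structure(
    list(n = as.integer(n), beta_g = beta_g, beta_e = beta_e,
         beta_ge = beta_ge, grs_mean = grs_mean,
         grs_variance = grs_variance, grs_binary = isTRUE(grs_binary),
         p_inactive = p_inactive, rho = rho, sigma = sigma, alpha = alpha,
         n_iter = as.integer(n_iter), seed = seed),
    class = "power_scenario")
}

#' @export
print.power_scenario <- function(x, ...) {
  cat("Interaction power scenario\n")
  cat(sprintf("  n = %d, beta_ge = %.4g, sigma = %.3g, alpha = %.3g\n",
              x$n, x$beta_ge, x$sigma, x$alpha))
  cat(sprintf("  GRS %s(mean %.3g, var %.3g); p_inactive = %.2f, rho = %.2f\n",
              if (x$grs_binary) "binary at mean, " else "continuous ",
              x$grs_mean, x$grs_variance, x$p_inactive, x$rho))
  cat(sprintf("  %d iterations%s\n", x$n_iter,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

# Effective variance of the genetic predictor: the continuous GRS keeps its
# variance; dichotomizing a normal GRS at a cut leaves Bernoulli variance
# p_cut (1 - p_cut), equal to 0.25 at the mean (median) cut.
grs_effective_variance <- function(scenario) {
  if (!scenario$grs_binary) return(scenario$grs_variance)
  p_cut <- 0.5  # cut at the mean of a normal = median split
  p_cut * (1 - p_cut)
}

#' Closed-form power for the interaction Wald test
#'
#' With independent predictors (`rho = 0`), the OLS interaction coefficient
#' has asymptotic variance `sigma^2 / (n v)` where
#' `v = Var(G_eff) * p (1 - p)` is the variance of the centered product term
#' (G_eff the continuous GRS, or its mean-split indicator with variance
#' 0.25). The Wald noncentrality is `lambda = n beta_ge^2 v / sigma^2` and
#'
#' \deqn{power = \Phi(\sqrt\lambda - z_{1-\alpha/2}) +
#'   \Phi(-\sqrt\lambda - z_{1-\alpha/2}).}
#'
#' @param scenario A [power_scenario()] with `rho = 0`.
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' analytic_power(power_scenario(n = 20000))  # about 0.83
analytic_power <- function(scenario) {
  stopifnot(inherits(scenario, "power_scenario"))
  if (scenario$rho != 0)
    stop("closed form requires rho = 0; use simulate_power()", call. = FALSE)
  v <- grs_effective_variance(scenario) *
    scenario$p_inactive * (1 - scenario$p_inactive)
  lambda <- scenario$n * scenario$beta_ge^2 * v / scenario$sigma^2
  zc <- stats::qnorm(1 - scenario$alpha / 2)
  stats::pnorm(sqrt(lambda) - zc) + stats::pnorm(-sqrt(lambda) - zc)
}

# One simulated draw of (g, e, y) under a scenario; returns the two-sided
# Wald p-value of the interaction coefficient from the OLS fit with both
# marginal terms. Fast closed-form least squares on the 4-column design.
simulate_one_pvalue <- function(scenario) {
  n <- scenario$n
  g <- stats::rnorm(n, scenario$grs_mean, sqrt(scenario$grs_variance))
  e <- if (scenario$rho == 0) {
    stats::rbinom(n, 1L, 1 - scenario$p_inactive)
  } else {
    simulate_activity(g, scenario$p_inactive, scenario$rho)
  }
  if (scenario$grs_binary) g <- as.numeric(g > scenario$grs_mean)
  y <- scenario$beta_g * g + scenario$beta_e * e +
    scenario$beta_ge * g * e + stats::rnorm(n, 0, scenario$sigma)
  X <- cbind(1, g, e, g * e)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(cnd) NULL)
  if (is.null(R)) return(NA_real_)  # singular draw; caller redraws
  coefs <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  rss <- sum((y - X %*% coefs)^2)
  sigma2 <- rss / (n - 4L)
  XtX_inv_44 <- sum(backsolve(R, c(0, 0, 0, 1), transpose = TRUE)^2)
  se <- sqrt(sigma2 * XtX_inv_44)
  2 * stats::pnorm(-abs(coefs[4L] / se))
}

#' Monte-Carlo power for the interaction test
#'
#' Repeats, `n_iter` times: draw a cohort under the scenario (GRS continuous
#' or mean-split, activity Bernoulli or copula-correlated, BMI from the
#' linear model), fit OLS with both marginal terms and the interaction, and
#' reject when the interaction's two-sided Wald p-value is below `alpha`.
#' Iterations with a singular design (possible at tiny n) are redrawn and
#' counted.
#'
#' @param scenario A [power_scenario()].
#' @return Object of class `power_result`: `power`, `mc_se`
#'   (`sqrt(power (1 - power) / n_iter)`), `ci95`, `analytic` (closed-form
#'   power when `rho = 0`, else `NA`), `n_singular`, and the scenario.
#' @export
simulate_power <- function(scenario) {
  stopifnot(inherits(scenario, "power_scenario"))
  with_seed(scenario$seed, {
    n_singular <- 0L
    reject <- logical(scenario$n_iter)
    for (i in seq_len(scenario$n_iter)) {
      p <- simulate_one_pvalue(scenario)
      while (is.na(p)) {
        n_singular <- n_singular + 1L
        if (n_singular > 100L * scenario$n_iter)
          stop("design persistently singular; increase n", call. = FALSE)
        p <- simulate_one_pvalue(scenario)
      }
      reject[i] <- p < scenario$alpha
    }
    power <- mean(reject)
    mc_se <- sqrt(power * (1 - power) / scenario$n_iter)
    structure(
      list(power = power, mc_se = mc_se,
           ci95 = c(max(0, power - 1.959964 * mc_se),
                    min(1, power + 1.959964 * mc_se)),
           analytic = if (scenario$rho == 0) analytic_power(scenario)
                      else NA_real_,
           n_singular = n_singular, scenario = scenario),
      class = "power_result")
  })
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Simulated power %.3f (MC SE %.4f, 95%% CI %.3f-%.3f) at n = %d\n",
    x$power, x$mc_se, x$ci95[1], x$ci95[2], x$scenario$n))
  if (!is.na(x$analytic))
    cat(sprintf("Analytic power %.3f\n", x$analytic))
  if (x$n_singular > 0)
    cat(sprintf("%d singular draws redrawn\n", x$n_singular))
  invisible(x)
}

#' Sample size required for a target power
#'
#' For `rho = 0` the closed form is inverted directly: bisection on
#' [analytic_power()] over n (the power is strictly increasing in n), with
#' an optional Monte-Carlo confirmation at the returned size. For
#' `rho != 0` a simulation-based bisection is used with `scenario$n_iter`
#' iterations per probe. The reported n is rounded to the nearest 1,000
#' (the convention for sample sizes of this magnitude); the exact solution
#' is retained as `n_exact`.
#'
#' @param scenario A [power_scenario()]; its `n` is ignored.
#' @param target_power Target power in (alpha, 1), default 0.80.
#' @param confirm Run [simulate_power()] at the returned n (default
#'   `FALSE`); warns when the simulated power misses the target by more
#'   than 3 Monte-Carlo SE.
#' @param confirm_iter Iterations for the confirmation run (default 500).
#' @return Object of class `required_n`: `n` (rounded), `n_exact`,
#'   `target_power`, `analytic_power_at_n`, and `confirmation` (a
#'   `power_result` or `NULL`).
#' @export
#' @examples
#' required_sample_size(power_scenario(sigma = 4.5))  # about 31,000
required_sample_size <- function(scenario, target_power = 0.80,
                                 confirm = FALSE, confirm_iter = 500) {
  stopifnot(inherits(scenario, "power_scenario"))
  if (scenario$beta_ge == 0)
    stop("beta_ge = 0: target power unreachable", call. = FALSE)
  if (target_power <= scenario$alpha || target_power >= 1)
    stop("`target_power` must lie in (alpha, 1)", call. = FALSE)
  power_at <- function(n) {
    sc <- scenario
    sc$n <- as.integer(max(4, round(n)))
    if (scenario$rho == 0) analytic_power(sc)
    else simulate_power(sc)$power
  }
  lo <- 4; hi <- 1000
  while (power_at(hi) < target_power) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e9) stop("required n exceeds 1e9; effect too small",
                       call. = FALSE)
  }
  if (scenario$rho == 0) {
    n_exact <- stats::uniroot(function(n) power_at(n) - target_power,
                              c(lo, hi), tol = 0.25)$root
  } else {
    # noisy bisection: narrow to a 2% window on the simulated power curve
    while (hi / lo > 1.02) {
      mid <- sqrt(lo * hi)
      if (power_at(mid) < target_power) lo <- mid else hi <- mid
    }
    n_exact <- sqrt(lo * hi)
  }
  n_rounded <- max(1000, round(n_exact / 1000) * 1000)
  confirmation <- NULL
  if (confirm) {
    sc <- scenario
    sc$n <- as.integer(n_rounded)
    sc$n_iter <- as.integer(confirm_iter)
    confirmation <- simulate_power(sc)
    slack <- 3 * sqrt(target_power * (1 - target_power) / confirm_iter)
    if (abs(confirmation$power - target_power) > slack) {
      warning(sprintf(
        "simulated power %.3f at n = %d misses target %.2f by > 3 MC SE",
        confirmation$power, sc$n, target_power), call. = FALSE)
    }
  }
  structure(
    list(n = n_rounded, n_exact = n_exact, target_power = target_power,
         analytic_power_at_n = if (scenario$rho == 0) {
           sc <- scenario; sc$n <- as.integer(n_rounded); analytic_power(sc)
         } else NA_real_,
         confirmation = confirmation, scenario = scenario),
    class = "required_n")
}

#' @export
print.required_n <- function(x, ...) {
  cat(sprintf(
    "Required n for %.0f%% power: %s (exact %.0f)\n",
    100 * x$target_power, format(x$n, big.mark = ","), x$n_exact))
  if (!is.null(x$confirmation)) {
    cat(sprintf("Simulation confirmation at n = %s: power %.3f (MC SE %.4f)\n",
                format(x$confirmation$scenario$n, big.mark = ","),
                x$confirmation$power, x$confirmation$mc_se))
  }
  invisible(x)
}

sweepable_params <- c("n", "beta_g", "beta_e", "beta_ge", "grs_mean",
                      "grs_variance", "grs_binary", "p_inactive", "rho",
                      "sigma", "alpha")

#' Sweep one scenario parameter
#'
#' Evaluates power (and optionally required sample size) over a grid of
#' values for a single scenario parameter, holding everything else fixed —
#' the sweeps behind activity-prevalence, effect-size, correlation, and
#' residual-variance sensitivity tables.
#'
#' @param base A [power_scenario()].
#' @param param Parameter name; one of n, beta_g, beta_e, beta_ge, grs_mean,
#'   grs_variance, grs_binary, p_inactive, rho, sigma, alpha.
#' @param values Non-empty grid of values for `param`.
#' @param what `"power"` (simulated + analytic at fixed n) or
#'   `"required_n"` (sample size for `target_power`).
#' @param target_power Target for `what = "required_n"` (default 0.80).
#' @param simulate For `what = "power"`, also run the Monte-Carlo estimate
#'   (default `TRUE`); `FALSE` returns the analytic values only.
#' @return A `data.frame`, one row per grid value: the swept value, `power`
#'   and `mc_se` (when simulated), `analytic_power`, or `required_n` and
#'   `required_n_exact`.
#' @export
scenario_sweep <- function(base, param, values,
                           what = c("power", "required_n"),
                           target_power = 0.80, simulate = TRUE) {
  stopifnot(inherits(base, "power_scenario"), length(values) >= 1L)
  what <- match.arg(what)
  if (!param %in% sweepable_params) {
    stop(sprintf("unknown parameter `%s`; sweepable: %s", param,
                 paste(sweepable_params, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(seq_along(values), function(i) {
    sc <- base
    sc[[param]] <- if (param %in% c("n")) as.integer(values[i])
                   else values[i]
    if (!is.null(base$seed)) sc$seed <- base$seed + i
    row <- stats::setNames(data.frame(values[i]), param)
    if (what == "power") {
      if (simulate) {
        pr <- simulate_power(sc)
        row$power <- pr$power
        row$mc_se <- pr$mc_se
      }
      row$analytic_power <- if (sc$rho == 0) analytic_power(sc) else NA_real_
    } else {
      rs <- required_sample_size(sc, target_power)
      row$required_n <- rs$n
      row$required_n_exact <- rs$n_exact
    }
    row
  })
  do.call(rbind, rows)
}
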