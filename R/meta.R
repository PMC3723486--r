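check_estimates <- function(estimates) {
  need <- c("cohort", "n", "beta", "se")
  if (!all(need %in% names(estimates)))
    stop("estimates need columns cohort, n, beta, se", call. = FALSE)
  bad_n <- estimates$cohort[!is.finite(estimates$n) | estimates$n < 1]
  if (length(bad_n))
    stop(sprintf("non-positive sample size for: %s",
                 paste(bad_n, collapse = ", ")), call. = FALSE)
  bad_se <- estimates$cohort[!is.finite(estimates$se) | estimates$se <= 0]
  if (length(bad_se))
    stop(sprintf("non-positive SE for: %s",
                 paste(bad_se, collapse = ", ")), call. = FALSE)
  invisible(estimates)
}

meta_result <- function(beta, se, method, estimates, Q = NA_real_,
                        df = NA_integer_, I2 = NA_real_, p_het = NA_real_,
                        tau2 = NA_real_, weights = NULL) {
  z <- beta / se
  structure(
    list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
         ci_lo = beta - 1.959964 * se, ci_hi = beta + 1.959964 * se,
         Q = Q, df = df, I2 = I2, p_het = p_het, tau2 = tau2,
         k = nrow(estimates), method = method, weights = weights,
         estimates = estimates),
    class = "gxe_meta")
}

#' Pool cohort estimates
#'
#' Combines per-cohort interaction coefficients three ways:
#'
#' * `"sample_size"` (the primary method): weights proportional to cohort
#'   size, pooled beta `sum(n_i b_i) / sum(n_i)` with SE
#'   `sqrt(sum(n_i^2 se_i^2)) / sum(n_i)`, the weighted-sum variance under
#'   independence.
#' * `"fixed"`: inverse-variance weights `1 / se_i^2`.
#' * `"random"`: DerSimonian-Laird, `tau2 = max(0, (Q - df) /
#'   (sum(w) - sum(w^2) / sum(w)))` with weights `1 / (se_i^2 + tau2)`.
#'
#' Heterogeneity (Cochran's Q with inverse-variance weights, I2, chi-square
#' p) is attached for every method whenever at least two estimates are
#' supplied; see [heterogeneity()].
#'
#' @param estimates `data.frame` with columns `cohort`, `n`, `beta`, `se`
#'   (e.g. rows from [cohort_estimate()]).
#' @param method One of `"sample_size"`, `"fixed"`, `"random"`.
#' @return An object of class `gxe_meta` with the pooled beta, SE, z, p,
#'   95% CI, heterogeneity statistics, per-cohort weights (summing to 1) and
#'   the input table.
#' @export
#' @examples
#' est <- data.frame(cohort = c("A", "B", "C"), n = c(1000, 2000, 3000),
#'                   beta = c(0.1, 0.2, 0.3), se = 0.05)
#' pool_estimates(est)
pool_estimates <- function(estimates,
                           method = c("sample_size", "fixed", "random")) {
  method <- match.arg(method)
  check_estimates(estimates)
  k <- nrow(estimates)
  het <- if (k >= 2L) heterogeneity(estimates) else NULL
  tau2 <- NA_real_
  if (method == "sample_size") {
    w <- estimates$n
    beta <- sum(w * estimates$beta) / sum(w)
    se <- sqrt(sum(w^2 * estimates$se^2)) / sum(w)
  } else if (method == "fixed") {
    w <- 1 / estimates$se^2
    beta <- sum(w * estimates$beta) / sum(w)
    se <- sqrt(1 / sum(w))
  } else {
    if (k < 2L) stop("random-effects pooling needs >= 2 estimates",
                     call. = FALSE)
    wf <- 1 / estimates$se^2
    tau2 <- max(0, (het$Q - het$df) / (sum(wf) - sum(wf^2) / sum(wf)))
    w <- 1 / (estimates$se^2 + tau2)
    beta <- sum(w * estimates$beta) / sum(w)
    se <- sqrt(1 / sum(w))
  }
  meta_result(beta, se, method, estimates,
              Q = if (is.null(het)) NA_real_ else het$Q,
              df = if (is.null(het)) NA_integer_ else het$df,
              I2 = if (is.null(het)) NA_real_ else het$I2,
              p_het = if (is.null(het)) NA_real_ else het$p_het,
              tau2 = tau2, weights = w / sum(w))
}

#' Pool by cohort sample size
#'
#' Convenience wrapper for `pool_estimates(estimates, "sample_size")`, the
#' primary pooling method.
#' @inheritParams pool_estimates
#' @return A `gxe_meta`; see [pool_estimates()].
#' @export
pool_sample_size_weighted <- function(estimates) {
  pool_estimates(estimates, "sample_size")
}

#' Pool by inverse variance
#'
#' Fixed-effect, or DerSimonian-Laird random-effects, inverse-variance
#' pooling; wrapper around [pool_estimates()].
#' @inheritParams pool_estimates
#' @param random Use the random-effects model (default `FALSE`).
#' @return A `gxe_meta`.
#' @export
pool_inverse_variance <- function(estimates, random = FALSE) {
  pool_estimates(estimates, if (random) "random" else "fixed")
}

#' Between-study heterogeneity
#'
#' Cochran's Q with fixed-effect inverse-variance weights (the conventional
#' choice even when the point estimate is pooled by sample size),
#' `df = k - 1`, `I2 = max(0, (Q - df) / Q) * 100`, and the upper-tail
#' chi-square p-value.
#'
#' @inheritParams pool_estimates
#' @return List with `Q`, `df`, `I2` (percent), `p_het`.
#' @export
#' @examples
#' # Q = 15.51 on 15 df gives I2 = 3.3% and p about 0.415
#' est <- data.frame(cohort = 1:2, n = 100, beta = c(0, 0), se = 1)
#' heterogeneity(est)
heterogeneity <- function(estimates) {
  check_estimates(estimates)
  k <- nrow(estimates)
  if (k < 2L) stop("heterogeneity needs >= 2 estimates", call. = FALSE)
  w <- 1 / estimates$se^2
  beta_fixed <- sum(w * estimates$beta) / sum(w)
  Q <- sum(w * (estimates$beta - beta_fixed)^2)
  df <- k - 1L
  list(Q = Q, df = df, I2 = i_squared(Q, df),
       p_het = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' I-squared from Q and its degrees of freedom
#'
#' `I2 = max(0, (Q - df) / Q) * 100`: the percentage of total variation
#' across studies attributable to heterogeneity rather than chance.
#'
#' @param Q Cochran's Q statistic.
#' @param df Degrees of freedom (`k - 1`).
#' @return I-squared in percent, in \[0, 100\].
#' @export
#' @examples
#' i_squared(15.51, 15)  # 3.3%
i_squared <- function(Q, df) {
  stopifnot(Q >= 0, df >= 1)
  if (Q == 0) 0 else max(0, (Q - df) / Q) * 100
}

#' @export
print.gxe_meta <- function(x, digits = 4, ...) {
  lbl <- c(sample_size = "sample-size-weighted",
           fixed = "inverse-variance fixed-effect",
           random = "DerSimonian-Laird random-effects")[x$method]
  cat(sprintf("Meta-analysis of %d cohort estimates (%s)\n", x$k, lbl))
  cat(sprintf("  pooled beta = %s (SE %s), 95%% CI [%s, %s], p = %s\n",
              fmt_num(x$beta, digits), fmt_num(x$se, digits),
              fmt_num(x$ci_lo, digits), fmt_num(x$ci_hi, digits),
              fmt_num(x$p, digits)))
  if (!is.na(x$Q)) {
    cat(sprintf("  heterogeneity: Q = %s (df = %d), I2 = %.1f%%, p = %s\n",
                fmt_num(x$Q, digits), x$df, x$I2, fmt_num(x$p_het, digits)))
  }
  if (!is.na(x$tau2)) cat(sprintf("  tau2 = %s\n", fmt_num(x$tau2, digits)))
  invisible(x)
}

#' @export
summary.gxe_meta <- function(object, ...) {
  c(object["beta"], object["se"], object["p"], object["Q"], object["df"],
    object["I2"], object["p_het"], object["tau2"], object["method"])
}

#' Forest-plot table
#'
#' Per-cohort rows (label, n, beta, 95% CI, percent weight) followed by one
#' summary row per group (when `group` is given) and the overall pooled row.
#' Weights are the pooling weights of `meta`, normalized to sum to 100
#' within the exported table.
#'
#' @param meta A `gxe_meta` from [pool_estimates()].
#' @param group Optional vector (length k) of subgroup labels, e.g.
#'   continental ancestry; each subgroup gets its own pooled summary row
#'   computed with the same method.
#' @return A `data.frame` with columns `label`, `type` (`"cohort"`,
#'   `"subgroup"`, `"summary"`), `group`, `n`, `beta`, `ci_lo`, `ci_hi`,
#'   `weight_pct`.
#' @export
forest_export <- function(meta, group = NULL) {
  stopifnot(inherits(meta, "gxe_meta"))
  est <- meta$estimates
  rows <- data.frame(
    label = as.character(est$cohort), type = "cohort",
    group = if (is.null(group)) NA_character_ else as.character(group),
    n = est$n, beta = est$beta,
    ci_lo = est$beta - 1.959964 * est$se,
    ci_hi = est$beta + 1.959964 * est$se,
    weight_pct = 100 * meta$weights, stringsAsFactors = FALSE)
  out <- rows
  if (!is.null(group)) {
    stopifnot(length(group) == nrow(est))
    for (g in unique(group)) {
      sub <- pool_estimates(est[group == g, , drop = FALSE], meta$method)
      out <- rbind(out, data.frame(
        label = paste0(g, " subtotal"), type = "subgroup", group = g,
        n = sum(est$n[group == g]), beta = sub$beta, ci_lo = sub$ci_lo,
        ci_hi = sub$ci_hi,
        weight_pct = sum(rows$weight_pct[group == g]),
        stringsAsFactors = FALSE))
    }
  }
  rbind(out, data.frame(
    label = "Overall", type = "summary", group = NA_character_,
    n = sum(est$n), beta = meta$beta, ci_lo = meta$ci_lo,
    ci_hi = meta$ci_hi, weight_pct = 100, stringsAsFactors = FALSE))
}

#' Draw a forest plot
#'
#' Base-graphics forest plot of the per-cohort estimates and the pooled
#' summary of a `gxe_meta`.
#'
#' @param x A `gxe_meta`.
#' @param xlab Axis label.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [forest_export()] table that was drawn.
#' @export
plot.gxe_meta <- function(x, xlab = "Interaction effect (kg/m2)", ...) {
  tab <- forest_export(x)
  k <- nrow(tab)
  ys <- rev(seq_len(k))
  graphics::plot(tab$beta, ys, xlim = range(tab$ci_lo, tab$ci_hi, 0),
                 ylim = c(0.5, k + 0.5), pch = ifelse(tab$type == "cohort",
                                                      15, 18),
                 cex = ifelse(tab$type == "cohort",
                              0.5 + 1.5 * tab$weight_pct / 100, 1.6),
                 yaxt = "n", ylab = "", xlab = xlab, ...)
  graphics::segments(tab$ci_lo, ys, tab$ci_hi, ys)
  graphics::abline(v = 0, lty = 3)
  graphics::abline(v = x$beta, lty = 2, col = "grey40")
  graphics::axis(2, at = ys, labels = tab$label, las = 1, cex.axis = 0.8)
  invisible(tab)
}
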