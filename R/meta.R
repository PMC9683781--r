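#' Recover a standard error from a Wald confidence interval
#'
#' `(hi - lo) / (2 * z)` with `z = qnorm(1 - (1 - level)/2)` (1.959964 at the
#' default 95% level).
#' @param lo,hi Interval bounds (`hi > lo`).
#' @param level Confidence level (default 0.95).
#' @return Standard error.
#' @export
se_from_ci <- function(lo, hi, level = 0.95) {
  if (any(hi <= lo)) stop("interval bounds out of order (need hi > lo)")
  (hi - lo) / (2 * stats::qnorm(1 - (1 - level) / 2))
}

#' Build a per-study estimate
#'
#' @param label Study label.
#' @param estimate Point estimate (beta, log-OR, or attributable fraction).
#' @param se Standard error; may be omitted when `ci` is given.
#' @param ci Optional `c(lo, hi)` 95% interval from which the SE is derived.
#' @return Object of class `study_estimate`.
#' @export
study_estimate <- function(label, estimate, se = NULL, ci = NULL) {
  if (is.null(se)) {
    if (is.null(ci)) stop("provide se or ci")
    se <- se_from_ci(ci[1], ci[2])
  }
  if (se <= 0) stop("se must be > 0")
  structure(list(label = label, estimate = estimate, se = se),
            class = "study_estimate")
}

#' Inverse-variance fixed-effect pooling
#'
#' Pools study estimates with weights `1/se^2`; the pooled SE is
#' `1/sqrt(sum(w))` and the CI is Wald. Heterogeneity is quantified by
#' Cochran's Q (`sum w (x - pooled)^2`), its upper-tail chi-squared p-value
#' on k-1 degrees of freedom, and `I^2 = max(0, (Q - df)/Q) * 100`. A single
#' study passes through with the heterogeneity fields flagged undefined.
#'
#' @param estimates List of [study_estimate()]s (or a data.frame with
#'   `estimate` and `se` columns).
#' @return Object of class `meta_result`: `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   `p`, `Q`, `df`, `het_p`, `I2`, `k`.
#' @export
pool_fixed <- function(estimates) {
  if (is.data.frame(estimates)) {
    est <- estimates$estimate; se <- estimates$se
  } else {
    est <- vapply(estimates, `[[`, 0, "estimate")
    se <- vapply(estimates, `[[`, 0, "se")
  }
  if (any(se <= 0)) stop("all standard errors must be > 0")
  k <- length(est)
  z <- stats::qnorm(0.975)
  if (k == 1L) {
    return(structure(
      list(estimate = est, se = se, ci_lo = est - z * se,
           ci_hi = est + z * se,
           p = 2 * stats::pnorm(-abs(est / se)),
           Q = NA_real_, df = 0L, het_p = NA_real_, I2 = NA_real_, k = 1L,
           single_study = TRUE),
      class = "meta_result"))
  }
  w <- 1 / se^2
  pooled <- sum(w * est) / sum(w)
  pse <- 1 / sqrt(sum(w))
  het <- heterogeneity(est, se, pooled)
  structure(
    list(estimate = pooled, se = pse, ci_lo = pooled - z * pse,
         ci_hi = pooled + z * pse,
         p = 2 * stats::pnorm(-abs(pooled / pse)),
         Q = het$Q, df = het$df, het_p = het$p, I2 = het$I2, k = k,
         single_study = FALSE),
    class = "meta_result"
  )
}

#' Cochran's Q and I-squared
#'
#' @param est,se Study estimates and standard errors.
#' @param pooled Fixed-effect pooled estimate (computed when omitted).
#' @return List with `Q`, `df`, `p` and `I2` (percent, reported rounded to
#'   integer via `round(I2)` by callers that print).
#' @export
heterogeneity <- function(est, se, pooled = NULL) {
  if (length(est) < 2L) stop("heterogeneity undefined for a single study")
  w <- 1 / se^2
  if (is.null(pooled)) pooled <- sum(w * est) / sum(w)
  Q <- sum(w * (est - pooled)^2)
  df <- length(est) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = max(0, (Q - df) / Q) * 100)
}

#' Pool odds ratios on the log scale
#'
#' Log-transforms the ORs and their CIs, pools by [pool_fixed()], and
#' exponentiates the pooled estimate and CI; Q, its p and I^2 come from the
#' log scale.
#' @param or Vector of odds ratios (> 0).
#' @param ci_lo,ci_hi 95% CI bounds of each OR.
#' @param labels Optional study labels.
#' @return A `meta_result` whose `estimate`, `ci_lo`, `ci_hi` are on the OR
#'   scale (and `log_estimate`, `log_se` retained).
#' @export
pool_or <- function(or, ci_lo, ci_hi, labels = NULL) {
  if (any(or <= 0 | ci_lo <= 0 | ci_hi <= 0)) {
    stop("odds ratios and CI bounds must be > 0")
  }
  est <- log(or)
  se <- se_from_ci(log(ci_lo), log(ci_hi))
  res <- pool_fixed(data.frame(estimate = est, se = se))
  res$log_estimate <- res$estimate
  res$log_se <- res$se
  res$estimate <- exp(res$log_estimate)
  res$ci_lo <- exp(res$ci_lo)
  res$ci_hi <- exp(res$ci_hi)
  res$scale <- "odds ratio"
  res
}

#' Random-effects (DerSimonian-Laird) pooling
#'
#' Optional alternative to the fixed-effect default: the between-study
#' variance `tau^2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` inflates
#' the weights.
#' @inheritParams pool_fixed
#' @return A `meta_result` with an added `tau2`.
#' @export
pool_random <- function(estimates) {
  if (is.data.frame(estimates)) {
    est <- estimates$estimate; se <- estimates$se
  } else {
    est <- vapply(estimates, `[[`, 0, "estimate")
    se <- vapply(estimates, `[[`, 0, "se")
  }
  fe <- pool_fixed(data.frame(estimate = est, se = se))
  if (fe$k == 1L) return(fe)
  w <- 1 / se^2
  tau2 <- max(0, (fe$Q - fe$df) / (sum(w) - sum(w^2) / sum(w)))
  w2 <- 1 / (se^2 + tau2)
  pooled <- sum(w2 * est) / sum(w2)
  pse <- 1 / sqrt(sum(w2))
  z <- stats::qnorm(0.975)
  structure(
    list(estimate = pooled, se = pse, ci_lo = pooled - z * pse,
         ci_hi = pooled + z * pse,
         p = 2 * stats::pnorm(-abs(pooled / pse)),
         Q = fe$Q, df = fe$df, het_p = fe$het_p, I2 = fe$I2, k = fe$k,
         tau2 = tau2, single_study = FALSE),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, digits = 4, ...) {
  cat(sprintf("<meta_result> pooled %.4g [%.4g, %.4g], p = %.3g\n",
              x$estimate, x$ci_lo, x$ci_hi, x$p))
  if (!is.na(x$Q)) {
    cat(sprintf("  Q = %.3g (df %d), het p = %.3g, I2 = %d%%\n",
                x$Q, x$df, x$het_p, round(x$I2)))
  } else cat("  single study: heterogeneity undefined\n")
  invisible(x)
}
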