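#' Configuration for interaction power simulation
#'
#' @param n Sample size per simulated dataset.
#' @param b1,b2 Main-effect sizes of the two predictors.
#' @param b3 Interaction effect size.
#' @param rho Correlation between the two predictors (|rho| < 1).
#' @param family `"linear"` (Gaussian outcome) or `"logistic"` (binary).
#' @param residual_sd Residual SD for the linear outcome.
#' @param prevalence Baseline outcome prevalence for the logistic outcome.
#' @param alpha Significance level in (0, 1).
#' @param n_sims Number of Monte-Carlo simulations (>= 1).
#' @param seed Optional integer seed.
#' @return Object of class `power_config`.
#' @export
power_config <- function(n, b1 = 0, b2 = 0, b3 = 0, rho = 0,
                         family = c("linear", "logistic"),
                         residual_sd = 1, prevalence = 0.15,
                         alpha = 0.05, n_sims = 10000L, seed = NULL) {
  family <- match.arg(family)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  structure(list(n = as.integer(n), b1 = b1, b2 = b2, b3 = b3, rho = rho,
                 family = family, residual_sd = residual_sd,
                 prevalence = prevalence, alpha = alpha,
                 n_sims = as.integer(n_sims), seed = seed),
            class = "power_config")
}

#' Monte-Carlo power to detect a two-way interaction
#'
#' Per simulation: draw two standard-normal predictors with correlation
#' `rho`, generate the outcome from
#' `b1*x1 + b2*x2 + b3*x1*x2` plus Gaussian noise (linear) or through a
#' logistic link around the configured baseline prevalence (logistic), fit
#' the interaction model, and record whether the interaction p-value falls
#' below `alpha`. Power is the rejection fraction; its Monte-Carlo standard
#' error is `sqrt(p*(1-p)/n_sims)`. Non-convergent logistic fits are counted
#' and excluded (a warning fires above 5% non-convergence).
#'
#' @param config A [power_config()].
#' @return List of class `power_result`: `power`, `mc_se`,
#'   `n_nonconverged`, `n_sims_used`, `alpha`.
#' @export
interaction_power_mc <- function(config) {
  stopifnot(inherits(config, "power_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  a <- config$rho
  b <- sqrt(1 - a^2)
  crit <- config$alpha
  reject <- logical(config$n_sims)
  ok <- logical(config$n_sims)
  for (i in seq_len(config$n_sims)) {
    x1 <- stats::rnorm(n)
    x2 <- a * x1 + b * stats::rnorm(n)
    x12 <- x1 * x2
    eta <- config$b1 * x1 + config$b2 * x2 + config$b3 * x12
    X <- cbind(1, x1, x2, x12)
    if (config$family == "linear") {
      y <- eta + stats::rnorm(n, 0, config$residual_sd)
      fit <- stats::.lm.fit(X, y)
      df <- n - 4L
      rss <- sum(fit$residuals^2)
      XtXinv_44 <- chol2inv(chol(crossprod(X)))[4, 4]
      se <- sqrt(rss / df * XtXinv_44)
      tstat <- fit$coefficients[4] / se
      pval <- 2 * stats::pt(-abs(tstat), df)
      ok[i] <- TRUE
    } else {
      y <- stats::rbinom(n, 1L,
                         stats::plogis(stats::qlogis(config$prevalence) + eta))
      fit <- tryCatch(
        suppressWarnings(
          stats::glm.fit(X, y, family = stats::binomial(),
                         control = stats::glm.control(epsilon = 1e-8,
                                                      maxit = 25))),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { ok[i] <- FALSE; next }
      W <- fit$weights
      V <- tryCatch(chol2inv(chol(crossprod(X * sqrt(W)))),
                    error = function(e) NULL)
      if (is.null(V)) { ok[i] <- FALSE; next }
      zstat <- fit$coefficients[4] / sqrt(V[4, 4])
      pval <- 2 * stats::pnorm(-abs(zstat))
      ok[i] <- TRUE
    }
    reject[i] <- ok[i] && pval < crit
  }
  used <- sum(ok)
  n_nc <- config$n_sims - used
  if (n_nc > 0.05 * config$n_sims) {
    warning(sprintf("%.1f%% of fits did not converge",
                    100 * n_nc / config$n_sims))
  }
  pw <- sum(reject) / used
  structure(
    list(power = pw, mc_se = sqrt(pw * (1 - pw) / used),
         n_nonconverged = n_nc, n_sims_used = used, alpha = config$alpha),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> power = %.3f (MC se %.4f, %d sims, alpha %.3g)\n",
              x$power, x$mc_se, x$n_sims_used, x$alpha))
  if (x$n_nonconverged > 0) {
    cat("  non-converged fits:", x$n_nonconverged, "\n")
  }
  invisible(x)
}
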