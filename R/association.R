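z975 <- stats::qnorm(0.975)  # 1.959964

#' Pearson chi-squared test of independence
#'
#' Classical Pearson statistic without continuity correction, upper-tail
#' p-value on (r-1)(c-1) degrees of freedom.
#' @param tab An r x c matrix of counts.
#' @return List with `statistic`, `df`, `p`, and the expected counts.
#' @export
chi_squared_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero marginal")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  if (any(ct$expected <= 0)) stop("degenerate table: non-positive expected count")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Two-sample t-test from raw values or summary statistics
#'
#' Student's pooled-variance t by default; Welch available. Accepts either
#' two raw vectors (`x`, `y`) or the six summary statistics.
#' @param x,y Raw values per group (optional when summaries are given).
#' @param m1,s1,n1,m2,s2,n2 Group means, SDs and sizes.
#' @param welch Use the Welch (unequal-variance) statistic.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(x = NULL, y = NULL, m1 = NULL, s1 = NULL, n1 = NULL,
                         m2 = NULL, s2 = NULL, n2 = NULL, welch = FALSE) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    m1 <- mean(x); s1 <- stats::sd(x); n1 <- length(x)
    m2 <- mean(y); s2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (welch) {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- se^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tt <- (m1 - m2) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Specify a regression model
#'
#' Lightweight container naming the outcome, the main-effect predictors, an
#' optional interaction pair (both members must appear as main effects) and
#' the family.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor columns.
#' @param interaction Optional character pair `c(a, b)` adding `a:b`.
#' @param family `"linear"` or `"logistic"`.
#' @return Object of class `model_spec` with a `formula`.
#' @export
model_spec <- function(outcome, predictors,
                       interaction = NULL,
                       family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2,
              all(interaction %in% predictors))
  }
  rhs <- paste(predictors, collapse = " + ")
  if (!is.null(interaction)) {
    rhs <- paste(rhs, paste(interaction, collapse = ":"), sep = " + ")
  }
  structure(list(outcome = outcome, predictors = predictors,
                 interaction = interaction, family = family,
                 formula = stats::as.formula(paste(outcome, "~", rhs))),
            class = "model_spec")
}

fit_tidy <- function(fit, family, n_used) {
  sm <- summary(fit)$coefficients
  est <- sm[, 1]; se <- sm[, 2]; p <- sm[, 4]
  out <- data.frame(
    term = rownames(sm), estimate = est, se = se,
    ci_lo = est - z975 * se, ci_hi = est + z975 * se, p = p,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (family == "logistic") {
    out$or <- exp(out$estimate)
    out$or_lo <- exp(out$ci_lo)
    out$or_hi <- exp(out$ci_hi)
  }
  structure(list(tidy = out, family = family, n = n_used,
                 vcov = stats::vcov(fit), fit = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<regression_fit> %s model, n = %d\n", x$family, x$n))
  print(format(x$tidy, digits = digits), row.names = FALSE)
  invisible(x)
}

check_rank <- function(fit) {
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinearity: aliased columns ", paste(aliased, collapse = ", "))
  }
}

#' Fit a linear model (complete-case, classical SEs, Wald CIs)
#'
#' @param spec A [model_spec()] or a formula.
#' @param data data.frame; rows with any missing model variable are dropped.
#' @return A `regression_fit`: tidy coefficient table (`term`, `estimate`,
#'   `se`, `ci_lo`, `ci_hi`, `p`), `n`, covariance matrix and the underlying
#'   `lm` fit.
#' @export
fit_linear <- function(spec, data) {
  f <- if (inherits(spec, "model_spec")) spec$formula else spec
  mf <- stats::model.frame(f, data = data, na.action = stats::na.omit)
  fit <- stats::lm(f, data = mf)
  check_rank(fit)
  fit_tidy(fit, "linear", nrow(mf))
}

#' Fit a logistic model by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit (`glm`, binomial/logit) with convergence
#' tolerance 1e-8 and at most 25 iterations; SEs from the observed
#' information. Odds ratios and exponentiated CIs are attached. Perfect
#' separation is reported as an error.
#' @inheritParams fit_linear
#' @return A `regression_fit` with `or`, `or_lo`, `or_hi` columns.
#' @export
fit_logistic <- function(spec, data) {
  f <- if (inherits(spec, "model_spec")) spec$formula else spec
  mf <- stats::model.frame(f, data = data, na.action = stats::na.omit)
  yname <- all.vars(f)[1]
  yy <- mf[[yname]]
  if (length(unique(yy)) < 2L) stop("outcome has a single class")
  fit <- suppressWarnings(
    stats::glm(f, data = mf, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 25))
  )
  check_rank(fit)
  mu <- stats::fitted(fit)
  separated <- all(mu > 0.5 | yy == 0) && all(mu < 0.5 | yy == 1) &&
    max(abs(stats::coef(fit))) > 15
  if (!fit$converged || separated) {
    stop("logistic fit did not converge (probable separation; max |coef| = ",
         round(max(abs(stats::coef(fit))), 1), ")")
  }
  fit_tidy(fit, "logistic", nrow(mf))
}

#' Fit a model with a PRS-by-factor interaction term
#'
#' Adds the product term to the main-effects model and returns the full fit
#' plus the interaction row.
#' @param outcome Outcome column.
#' @param exposure Continuous exposure (default `"prs_z"`).
#' @param modifier The interacting factor column.
#' @param covariates Additional adjustment columns.
#' @param data data.frame.
#' @param family `"linear"` or `"logistic"`.
#' @return A `regression_fit` with an extra `interaction` element (one-row
#'   tidy data.frame for the product term).
#' @export
fit_interaction <- function(outcome, exposure = "prs_z", modifier,
                            covariates = character(), data,
                            family = c("linear", "logistic")) {
  family <- match.arg(family)
  spec <- model_spec(outcome, unique(c(exposure, modifier, covariates)),
                     interaction = c(exposure, modifier), family = family)
  fit <- if (family == "linear") fit_linear(spec, data) else
    fit_logistic(spec, data)
  iterm <- paste(exposure, modifier, sep = ":")
  row <- fit$tidy[fit$tidy$term %in%
                    c(iterm, paste(modifier, exposure, sep = ":")), ,
                  drop = FALSE]
  fit$interaction <- row
  fit
}

#' Predicted outcome curves stratified by a factor, with 95% bands
#'
#' Evaluates the fitted model over a grid of exposure values at
#' stratum-specific covariate values (covariates fixed at their within-
#' stratum means), with pointwise Wald bands from the delta method on the
#' linear predictor (for logistic fits the band is computed on the logit
#' scale and then inverse-linked).
#'
#' @param fit A `regression_fit` from [fit_linear()]/[fit_logistic()]
#'   (or [fit_interaction()]).
#' @param data The analysis data (used for stratum covariate means).
#' @param exposure Name of the exposure column the grid runs over.
#' @param stratifier Name of the stratifying column.
#' @param grid Numeric grid of exposure values; defaults to 50 points over
#'   the observed range. Values outside the observed range trigger a warning.
#' @return data.frame with `stratum`, exposure value, `fit`, `lo`, `hi`.
#' @export
stratified_predictions <- function(fit, data, exposure = "prs_z",
                                   stratifier, grid = NULL) {
  mm_terms <- stats::delete.response(stats::terms(fit$fit))
  rng <- range(data[[exposure]], na.rm = TRUE)
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 50)
  if (any(grid < rng[1] | grid > rng[2])) {
    warning("prediction grid extends beyond the observed ", exposure,
            " range; extrapolating")
  }
  strata <- sort(unique(data[[stratifier]]))
  out <- list()
  for (st in strata) {
    sub <- data[data[[stratifier]] == st, , drop = FALSE]
    nd <- sub[rep(1L, length(grid)), , drop = FALSE]
    num <- vapply(nd, is.numeric, TRUE)
    for (v in names(nd)[num]) nd[[v]] <- mean(sub[[v]], na.rm = TRUE)
    nd[[exposure]] <- grid
    X <- stats::model.matrix(mm_terms, nd)
    eta <- drop(X %*% stats::coef(fit$fit))
    se <- sqrt(rowSums((X %*% fit$vcov) * X))
    lo <- eta - z975 * se; hi <- eta + z975 * se
    if (fit$family == "logistic") {
      eta <- stats::plogis(eta); lo <- stats::plogis(lo)
      hi <- stats::plogis(hi)
    }
    out[[length(out) + 1L]] <- data.frame(stratum = st, x = grid, fit = eta,
                                          lo = lo, hi = hi)
  }
  res <- do.call(rbind, out)
  names(res)[2] <- exposure
  res
}
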