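#' Recode a derived cohort into binary PAF exposures
#'
#' Applies the attributable-fraction exposure codings: age in three levels
#' (reference < 29, 29-31, >= 32), BMI dichotomized at the South-Asian
#' obesity cutoff (>= 23, inclusive), PRS tertile 3 versus tertiles 1+2,
#' parity >= 1 versus 0, study-scheme post-secondary education,
#' parental history yes/no, born in South Asia yes/no, and low diet quality
#' yes/no. An alternative binary age coding (>= 29 vs < 29) is available.
#'
#' @param data Derived cohort containing `age`, `bmi`, `prs_tertile`,
#'   `parity`, `post_secondary`, `parental_history`, `born_sa`, `diet_low`.
#' @param age_binary Use the two-level age coding instead of three.
#' @return `data` with appended columns `age_29_31`, `age_32_plus` (or
#'   `age_ge29`), `bmi_high`, `prs_t3`, `parity_ge1`, `edu_post`,
#'   `parental`, `born_sa_bin`, `diet_low_bin`.
#' @export
binarize_for_paf <- function(data, age_binary = FALSE) {
  out <- data
  if (age_binary) {
    out$age_ge29 <- as.numeric(out$age >= 29)
  } else {
    out$age_29_31 <- as.numeric(out$age >= 29 & out$age < 32)
    out$age_32_plus <- as.numeric(out$age >= 32)
  }
  out$bmi_high <- as.numeric(out$bmi >= 23)
  if (!is.null(out$prs_tertile)) out$prs_t3 <- as.numeric(out$prs_tertile == 3)
  out$parity_ge1 <- as.numeric(out$parity >= 1)
  if (!is.null(out$post_secondary)) out$edu_post <- as.numeric(out$post_secondary)
  if (!is.null(out$parental_history)) {
    out$parental <- as.numeric(out$parental_history == "one-or-both")
  }
  if (!is.null(out$born_sa)) out$born_sa_bin <- as.numeric(out$born_sa)
  if (!is.null(out$diet_low) && any(!is.na(out$diet_low))) {
    out$diet_low_bin <- as.numeric(out$diet_low)
  }
  out
}

#' Closed-form attributable fraction from a 2x2 table
#'
#' With exposed cases `a`, exposed non-cases `b`, unexposed cases `c`,
#' unexposed non-cases `d`, the risk ratio is `RR = [a/(a+b)] / [c/(c+d)]`
#' and `AF = [a/(a+c)] * (RR - 1)/RR` (the case-based Miettinen form).
#' @param a,b,c,d Non-negative counts; margins must be non-empty.
#' @return Attributable fraction (proportion, not percent).
#' @export
af_2x2_closed_form <- function(a, b, c, d) {
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0) {
    stop("degenerate table: empty margin")
  }
  rr <- (a / (a + b)) / (c / (c + d))
  (a / (a + c)) * (rr - 1) / rr
}

af_point <- function(coefs, X, y, exposure_col) {
  X0 <- X
  X0[, exposure_col] <- 0
  p0 <- stats::plogis(drop(X0 %*% coefs))
  1 - sum(p0) / sum(y)
}

#' Model-based population attributable fraction
#'
#' Fits (or accepts) a logistic model and estimates
#' `AF = 1 - sum_i p_hat_i(exposure set to reference) / sum_i Y_i`: the
#' fitted case count expected if the binary exposure were removed, with
#' confounders held at observed values, relative to the observed case count.
#' Uncertainty comes from a seeded nonparametric bootstrap (percentile CI,
#' SD of replicates as SE) by default, or an approximate delta-method
#' variance conditional on the observed cases.
#'
#' @param formula Logistic model formula; the exposure must be one of its
#'   binary terms.
#' @param data Analysis data (complete cases used).
#' @param exposure Name of the binary exposure column.
#' @param B Bootstrap replicates (default 500).
#' @param seed Optional integer seed for the bootstrap.
#' @param method `"bootstrap"` or `"delta"`.
#' @param conf_level CI level (default 0.95).
#' @return Object of class `paf_result`: `af` (%), `se` (%), `ci_lo`,
#'   `ci_hi` (%), `p`, `exposure`, `n`, `method`.
#' @export
af_model_based <- function(formula, data, exposure, B = 500, seed = NULL,
                           method = c("bootstrap", "delta"),
                           conf_level = 0.95) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (sum(y) == 0) stop("no cases: attributable fraction undefined")
  X <- stats::model.matrix(formula, mf)
  ecol <- grep(paste0("^", exposure), colnames(X), value = TRUE)
  if (length(ecol) != 1L) {
    stop("exposure must map to exactly one model column; found: ",
         paste(ecol, collapse = ", "))
  }
  ex <- X[, ecol]
  if (!all(ex %in% c(0, 1))) stop("exposure column must be binary 0/1")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  )
  af <- af_point(fit$coefficients, X, y, ecol)
  n <- nrow(X)
  alpha <- 1 - conf_level
  if (method == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    reps <- numeric(B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      if (sum(yb) == 0 || length(unique(Xb[, ecol])) < 2L) {
        reps[b] <- NA_real_
        next
      }
      fb <- suppressWarnings(
        stats::glm.fit(Xb, yb, family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-8,
                                                    maxit = 25))
      )
      reps[b] <- af_point(fb$coefficients, Xb, yb, ecol)
    }
    reps <- reps[!is.na(reps)]
    se <- stats::sd(reps)
    ci <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  } else {
    # delta method on the coefficient vector, conditional on observed cases
    X0 <- X
    X0[, ecol] <- 0
    p0 <- stats::plogis(drop(X0 %*% fit$coefficients))
    grad <- -colSums(p0 * (1 - p0) * X0) / sum(y)
    W <- fit$weights  # IRLS weights = p(1-p) at convergence
    V <- solve(crossprod(X * sqrt(W)))
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    z <- stats::qnorm(1 - alpha / 2)
    ci <- c(af - z * se, af + z * se)
  }
  zstat <- af / se
  structure(
    list(af = 100 * af, se = 100 * se, ci_lo = 100 * ci[1],
         ci_hi = 100 * ci[2], p = 2 * stats::pnorm(-abs(zstat)),
         exposure = exposure, n = n, method = method),
    class = "paf_result"
  )
}

#' @export
print.paf_result <- function(x, ...) {
  cat(sprintf("<paf_result> %s: AF = %.1f%% [%.1f, %.1f], p = %.3g (n = %d, %s)\n",
              x$exposure, x$af, x$ci_lo, x$ci_hi, x$p, x$n, x$method))
  invisible(x)
}

#' Sum of attributable-fraction point estimates
#'
#' Arithmetic sum of the point estimates of several PAF results, reported as
#' an approximation (no independence of exposures is claimed).
#' @param results List of `paf_result`s (or numeric AFs in percent).
#' @return Numeric, percent.
#' @export
sum_paf <- function(results) {
  if (length(results) == 0L) return(0)
  vals <- vapply(results, function(r) {
    if (inherits(r, "paf_result")) r$af else as.numeric(r)
  }, 0)
  sum(vals)
}
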