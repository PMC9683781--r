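#' Odds ratio from 2x2 counts
#'
#' Cross-product ratio; no continuity correction. Swapping the exposure
#' labels inverts the ratio.
#' @param exposed_cases,exposed_controls,unexposed_cases,unexposed_controls
#'   Strictly positive counts.
#' @return Odds ratio.
#' @export
or_from_counts <- function(exposed_cases, exposed_controls,
                           unexposed_cases, unexposed_controls) {
  counts <- c(exposed_cases, exposed_controls,
              unexposed_cases, unexposed_controls)
  if (any(counts <= 0)) stop("zero (or negative) cell: odds ratio undefined")
  (exposed_cases * unexposed_controls) /
    (exposed_controls * unexposed_cases)
}

#' Detection rate implied by an odds ratio under a Gaussian risk-score model
#'
#' Assumes a screening score that is standard normal in unaffected women and
#' normal with mean `d`, SD 1 in affected women. Given the odds ratio for
#' scoring in the top `exposed_fraction` of the population, the model solves
#' for the implied mean separation `d` and converts it to the detection rate
#' (sensitivity) at a fixed false-positive rate:
#' `c = qnorm(1 - f)`; `p_case` from
#' `OR = [p_case/(1 - p_case)] * [(1 - f)/f]`;
#' `d = c - qnorm(1 - p_case)`; `DR = 1 - pnorm(qnorm(1 - fpr) - d)`.
#'
#' @param or_value Odds ratio (> 0) of the top score group for disease.
#' @param exposed_fraction Population fraction above the score cutoff
#'   (default one-third, the tertile contrast).
#' @param fpr False-positive rate(s) at which the detection rate is evaluated
#'   (default 0.05).
#' @return Object of class `screening_result`: `or`, `exposed_fraction`,
#'   `d`, and a data.frame `dr` with `fpr`, `detection_rate`.
#' @export
detection_rate <- function(or_value, exposed_fraction = 1 / 3, fpr = 0.05) {
  if (or_value <= 0) stop("odds ratio must be > 0")
  if (any(fpr <= 0 | fpr >= 1) || exposed_fraction <= 0 ||
      exposed_fraction >= 1) {
    stop("exposed_fraction and fpr must be in (0, 1)")
  }
  f <- exposed_fraction
  odds_case <- or_value * f / (1 - f)
  p_case <- odds_case / (1 + odds_case)
  if (!is.finite(p_case) || p_case <= 0 || p_case >= 1) {
    stop("odds ratio too extreme: implied case exposure probability ",
         "outside (0, 1)")
  }
  cutoff <- stats::qnorm(1 - f)
  d <- cutoff - stats::qnorm(1 - p_case)
  dr <- 1 - stats::pnorm(stats::qnorm(1 - fpr) - d)
  structure(
    list(or = or_value, exposed_fraction = f, d = d, p_case = p_case,
         dr = data.frame(fpr = fpr, detection_rate = dr)),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> OR = %.3f, d = %.3f SD\n", x$or, x$d))
  for (i in seq_len(nrow(x$dr))) {
    cat(sprintf("  DR = %.1f%% at FPR = %.0f%%\n",
                100 * x$dr$detection_rate[i], 100 * x$dr$fpr[i]))
  }
  invisible(x)
}
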