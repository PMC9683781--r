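#' Classify gestational diabetes from an OGTT, with self-report fallback
#'
#' Applies one of two inclusive threshold rules to 75-g OGTT glucose values
#' (mmol/L):
#' * `IADPSG`: GDM iff fasting >= 5.1, or 1-hour >= 10.8 (when measured),
#'   or 2-hour >= 8.5;
#' * `SA`: the South-Asian-specific definition, GDM iff fasting >= 5.2 or
#'   2-hour >= 7.2.
#'
#' A pregnancy is classified "no-GDM" only when every threshold the rule uses
#' could be checked (fasting and 2-hour present). When the OGTT is too
#' incomplete to classify, a self-reported / chart GDM status is used if
#' available; otherwise the status is missing. Women with pre-existing
#' diabetes must be excluded before classification.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param fpg,g1h,g2h Fasting, 1-hour and 2-hour glucose (mmol/L); `NA` where
#'   not measured.
#' @param self_report Optional 0/1 self-reported GDM status (`NA` if absent).
#' @param criteria `"IADPSG"` or `"SA"`.
#' @return A data.frame with columns `status` (factor GDM / no-GDM, `NA` when
#'   unclassifiable), `gdm` (0/1 numeric) and `source` ("OGTT",
#'   "self-report", or `NA`).
#' @export
classify_gdm <- function(fpg, g1h = NULL, g2h = NULL, self_report = NULL,
                         criteria = c("IADPSG", "SA")) {
  criteria <- match.arg(criteria)
  n <- max(length(fpg), length(g1h), length(g2h), length(self_report))
  fpg <- rep_len(fpg, n)
  g1h <- if (is.null(g1h)) rep(NA_real_, n) else rep_len(g1h, n)
  g2h <- if (is.null(g2h)) rep(NA_real_, n) else rep_len(g2h, n)
  self_report <- if (is.null(self_report)) rep(NA_integer_, n) else
    rep_len(self_report, n)

  if (criteria == "IADPSG") {
    pos <- (!is.na(fpg) & fpg >= 5.1) | (!is.na(g1h) & g1h >= 10.8) |
      (!is.na(g2h) & g2h >= 8.5)
  } else {
    pos <- (!is.na(fpg) & fpg >= 5.2) | (!is.na(g2h) & g2h >= 7.2)
  }
  complete <- !is.na(fpg) & !is.na(g2h)   # enough of the OGTT to rule out
  gdm <- rep(NA_integer_, n)
  source <- rep(NA_character_, n)
  gdm[pos] <- 1L; source[pos] <- "OGTT"
  neg <- !pos & complete
  gdm[neg] <- 0L; source[neg] <- "OGTT"
  fall <- is.na(gdm) & !is.na(self_report)
  gdm[fall] <- as.integer(self_report[fall] > 0)
  source[fall] <- "self-report"
  data.frame(
    status = factor(ifelse(is.na(gdm), NA,
                           ifelse(gdm == 1L, "GDM", "no-GDM")),
                    levels = c("no-GDM", "GDM")),
    gdm = gdm, source = source, stringsAsFactors = FALSE
  )
}

#' Area under the OGTT glucose curve (trapezoidal rule)
#'
#' Computes the area under the glucose-time curve in mmol.hr over the
#' available timepoints: fasting/1h/2h for a 3-point OGTT
#' (`0.5*(fpg+g1h) + 0.5*(g1h+g2h)`), fasting/2h for a 2-point OGTT
#' (`0.5*(fpg+g2h)*2`). Vectorized; rows with a missing 1-hour value fall
#' back to the 2-point formula only when `g1h` is `NA`.
#'
#' @param fpg,g1h,g2h Glucose values (mmol/L); `g1h` may be `NA`.
#' @return Numeric vector of areas; `NA` where fewer than two timepoints are
#'   present.
#' @export
auc_glucose <- function(fpg, g1h = NULL, g2h = NULL) {
  n <- max(length(fpg), length(g1h), length(g2h))
  fpg <- rep_len(fpg, n)
  g1h <- if (is.null(g1h)) rep(NA_real_, n) else rep_len(g1h, n)
  g2h <- if (is.null(g2h)) rep(NA_real_, n) else rep_len(g2h, n)
  three <- !is.na(fpg) & !is.na(g1h) & !is.na(g2h)
  two <- !is.na(fpg) & is.na(g1h) & !is.na(g2h)
  out <- rep(NA_real_, n)
  out[three] <- 0.5 * (fpg[three] + g1h[three]) +
    0.5 * (g1h[three] + g2h[three])
  out[two] <- 0.5 * (fpg[two] + g2h[two]) * 2
  if (n == 1 && is.na(out) && sum(!is.na(c(fpg, g1h, g2h))) < 2) {
    stop("insufficient data: AUC needs at least two OGTT timepoints")
  }
  out
}

#' Log-transform, winsorize and standardize
#'
#' Natural-log transforms positive values, clamps them to the empirical
#' `lower_pct`/`upper_pct` percentiles, then centers and scales to mean 0 and
#' SD 1 (moments computed after clamping). Intended to be applied within each
#' study separately. `NA`s are carried through.
#'
#' @param values Positive numeric vector.
#' @param lower_pct,upper_pct Winsorization percentiles (defaults 0.01/0.99).
#' @return Numeric z-scores, same length as `values`.
#' @export
log_winsorize_standardize <- function(values, lower_pct = 0.01,
                                      upper_pct = 0.99) {
  ok <- !is.na(values)
  if (any(values[ok] <= 0)) stop("all values must be > 0 before log transform")
  x <- log(values)
  q <- stats::quantile(x[ok], c(lower_pct, upper_pct), names = FALSE)
  x <- pmin(pmax(x, q[1]), q[2])
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: zero variance after winsorization")
  }
  (x - mean(x[ok])) / s
}

#' Diet-quality score from six food-group intakes
#'
#' One point per favourable group (green leafy vegetables, raw vegetables,
#' other cooked vegetables, fruits) consumed at or above the study-population
#' median, and one point per unfavourable group (fried/fast food/snacks,
#' meat/poultry) consumed strictly below its median. The 0-6 point sum is
#' categorized as Low (<= 2 points), Medium (3-4) or High (5-6); the binary
#' variable is Low versus Medium/High. A missing intake in any group makes
#' the score missing.
#'
#' @param ffq Matrix or data.frame with the six columns of [ffq_groups()].
#' @param medians Named per-group medians from the same study population;
#'   computed from `ffq` when omitted.
#' @return A data.frame with `points`, `category` and `binary_low`.
#' @export
diet_quality <- function(ffq, medians = NULL) {
  ffq <- as.matrix(ffq[, ffq_groups(), drop = FALSE])
  if (is.null(medians)) {
    medians <- apply(ffq, 2, stats::median, na.rm = TRUE)
  }
  medians <- medians[ffq_groups()]
  fav <- ffq_groups()[1:4]
  unf <- ffq_groups()[5:6]
  pts <- rowSums(sweep(ffq[, fav, drop = FALSE], 2, medians[fav], ">=")) +
    rowSums(sweep(ffq[, unf, drop = FALSE], 2, medians[unf], "<"))
  category <- cut(pts, breaks = c(-1, 2, 4, 6),
                  labels = c("Low", "Medium", "High"))
  data.frame(points = as.integer(pts), category = category,
             binary_low = pts <= 2)
}

#' Recode raw education categories to an ordinal level
#'
#' Maps a raw category label to its ordinal level under the study scheme
#' (five levels START-like, four levels BiB-like; see [education_labels()]).
#' The unclassifiable-foreign-degree token maps to missing. The
#' post-secondary binary is level >= 3 under the five-level scheme and
#' level 4 (higher than A-level) under the four-level scheme.
#'
#' @param raw Character vector of raw labels (matched case-insensitively).
#' @param scheme `"START"` or `"BiB"`.
#' @return data.frame with `level` (integer, `NA` for unclassifiable/missing)
#'   and `post_secondary` (logical).
#' @export
recode_education <- function(raw, scheme = c("START", "BiB")) {
  scheme <- match.arg(scheme)
  labs <- education_labels(scheme)
  norm <- function(x) tolower(trimws(x))
  lev <- match(norm(raw), norm(labs))
  unclass_tok <- norm(raw) == norm(education_unclassifiable())
  bad <- !is.na(raw) & is.na(lev) & !unclass_tok
  if (any(bad)) {
    stop("unknown education category ", sQuote(raw[bad][1]),
         "; valid labels: ", paste(labs, collapse = "; "))
  }
  cut <- if (scheme == "START") 3L else 4L
  data.frame(level = lev,
             post_secondary = ifelse(is.na(lev), NA, lev >= cut))
}

#' Born-in-South-Asia indicator
#'
#' `TRUE` iff the (case-insensitively normalized) country of birth is India,
#' Pakistan, Sri Lanka or Bangladesh; `NA` for a missing country.
#' @param country Character vector.
#' @return Logical vector.
#' @export
born_in_south_asia <- function(country) {
  sa <- c("india", "pakistan", "sri lanka", "bangladesh")
  out <- tolower(trimws(country)) %in% sa
  out[is.na(country)] <- NA
  out
}

#' Body-mass index
#'
#' @param weight_kg Weight in kg.
#' @param height_cm Height in cm (> 0).
#' @return BMI in kg/m^2; `NA` where either input is missing.
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(!is.na(height_cm) & height_cm <= 0)) {
    stop("height must be > 0")
  }
  weight_kg / (height_cm / 100)^2
}

#' Select the index pregnancy for one mother
#'
#' Applies, in order: (1) drop pregnancies with missing GDM status; (2) if any
#' pregnancy has zero missing covariates, keep only those; (3) otherwise keep
#' the pregnancies with the fewest missing covariates; (4) among the
#' survivors, keep the latest pregnancy if none had GDM ("keep older
#' controls"), else the earliest GDM-positive pregnancy ("keep younger
#' cases"). A date tie among GDM-positive survivors keeps the first row in
#' input order.
#'
#' @param rows data.frame of one mother's pregnancies.
#' @param gdm_col Name of the 0/1 GDM column.
#' @param order_col Name of the ordering column (e.g. pregnancy year).
#' @param covariate_cols Covariate columns whose completeness is prioritized.
#' @return A one-row data.frame with an added `selection_rule` attribute, or
#'   a zero-row data.frame when every pregnancy has missing GDM.
#' @export
select_index_pregnancy <- function(rows, gdm_col = "gdm",
                                   order_col = "preg_year",
                                   covariate_cols = character()) {
  keep <- !is.na(rows[[gdm_col]])
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L) {
    attr(rows, "selection_rule") <- "excluded: GDM missing at all pregnancies"
    return(rows)
  }
  if (length(covariate_cols)) {
    nmiss <- rowSums(is.na(rows[, covariate_cols, drop = FALSE]))
  } else nmiss <- rep(0L, nrow(rows))
  rows <- rows[nmiss == min(nmiss), , drop = FALSE]
  pos <- rows[[gdm_col]] > 0
  if (any(pos)) {
    cand <- rows[pos, , drop = FALSE]
    out <- cand[which.min(cand[[order_col]]), , drop = FALSE]
    rule <- "earliest GDM-positive"
  } else {
    out <- rows[which.max(rows[[order_col]]), , drop = FALSE]
    rule <- "latest GDM-negative"
  }
  attr(out, "selection_rule") <- rule
  out
}

#' Derive analysis variables for a whole cohort table
#'
#' Adds to a raw pregnancy-level cohort table: BMI, GDM under both criteria
#' (with self-report fallback), raw and standardized (log-winsorized, per
#' study) AUC glucose, diet score columns (where food-frequency data exist),
#' education level and post-secondary indicator, and the born-in-South-Asia
#' flag. Diet medians and AUC standardization are computed within study.
#'
#' @param cohort A cohort data.frame as produced by [simulate_cohort()].
#' @param edu_scheme Named character vector mapping study label to education
#'   scheme.
#' @param winsor_limits Lower/upper winsorization percentiles for AUCg.
#' @return The cohort with derived columns appended.
#' @export
derive_phenotypes <- function(cohort,
                              edu_scheme = c(START = "START", BiB = "BiB"),
                              winsor_limits = c(0.01, 0.99)) {
  out <- cohort
  out$bmi <- bmi(out$weight, out$height)
  gi <- classify_gdm(out$fpg, out$g1h, out$g2h, out$self_report_gdm, "IADPSG")
  gs <- classify_gdm(out$fpg, out$g1h, out$g2h, out$self_report_gdm, "SA")
  out$gdm_iadpsg <- gi$gdm
  out$gdm_source <- gi$source
  out$gdm_sa <- gs$gdm
  out$auc_raw <- auc_glucose(out$fpg, out$g1h, out$g2h)
  out$auc_z <- NA_real_
  out$edu_level <- NA_integer_
  out$post_secondary <- NA
  out$diet_points <- NA_integer_
  out$diet_low <- NA
  for (s in unique(out$study)) {
    i <- out$study == s
    ok <- i & !is.na(out$auc_raw)
    if (sum(ok) >= 2) {
      out$auc_z[ok] <- log_winsorize_standardize(out$auc_raw[ok],
                                                 winsor_limits[1],
                                                 winsor_limits[2])
    }
    sch <- if (s %in% names(edu_scheme)) edu_scheme[[s]] else "START"
    ed <- recode_education(out$education_raw[i], sch)
    out$edu_level[i] <- ed$level
    out$post_secondary[i] <- ed$post_secondary
    ffq_i <- out[i, ffq_groups(), drop = FALSE]
    if (any(stats::complete.cases(ffq_i))) {
      ds <- diet_quality(ffq_i)
      out$diet_points[i] <- ds$points
      out$diet_low[i] <- ds$binary_low
    }
  }
  out$born_sa <- born_in_south_asia(out$country_of_birth)
  out
}

#' Select index pregnancies for every mother in a cohort
#'
#' Applies [select_index_pregnancy()] mother by mother and returns one row per
#' mother with non-missing GDM, plus a selection log.
#'
#' @inheritParams select_index_pregnancy
#' @param cohort Derived cohort data.frame (must contain `mother_id`).
#' @return A list with `selected` (data.frame) and `log` (data.frame with
#'   `mother_id`, `kept_pregnancy_id`, `rule`).
#' @export
select_index_pregnancies <- function(cohort, gdm_col = "gdm_iadpsg",
                                     order_col = "preg_year",
                                     covariate_cols = c("age", "bmi",
                                                        "parental_history",
                                                        "country_of_birth",
                                                        "parity",
                                                        "edu_level")) {
  pieces <- split(cohort, cohort$mother_id)
  sel <- vector("list", length(pieces))
  logs <- vector("list", length(pieces))
  for (j in seq_along(pieces)) {
    r <- select_index_pregnancy(pieces[[j]], gdm_col, order_col,
                                covariate_cols)
    sel[[j]] <- r
    logs[[j]] <- data.frame(
      mother_id = names(pieces)[j],
      kept_pregnancy_id = if (nrow(r)) r$pregnancy_id else NA_character_,
      rule = attr(r, "selection_rule"),
      stringsAsFactors = FALSE
    )
  }
  selected <- do.call(rbind, sel[vapply(sel, nrow, 0L) > 0])
  rownames(selected) <- NULL
  list(selected = selected, log = do.call(rbind, logs))
}
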