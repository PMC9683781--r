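test_that("GDM classification applies inclusive thresholds and fallback", {
  # mean glucose profile of a non-GDM group is classified non-GDM
  expect_equal(classify_gdm(4.27, 7.31, 5.96)$gdm, 0L)
  # inclusive boundary: fasting exactly at 5.1
  expect_equal(classify_gdm(5.1, NA, 0.1)$gdm, 1L)
  expect_equal(classify_gdm(5.0999, NA, 8.5)$gdm, 1L)    # 2h boundary
  expect_equal(classify_gdm(4.0, 10.8, 5.0)$gdm, 1L)     # 1h boundary
  # criteria disagreement: IADPSG positive, South-Asian-specific negative
  expect_equal(classify_gdm(5.15, NA, 7.0, criteria = "IADPSG")$gdm, 1L)
  expect_equal(classify_gdm(5.15, NA, 7.0, criteria = "SA")$gdm, 0L)
  # and the reverse direction (2h in [7.2, 8.5), fasting < 5.1)
  expect_equal(classify_gdm(4.9, NA, 7.5, criteria = "IADPSG")$gdm, 0L)
  expect_equal(classify_gdm(4.9, NA, 7.5, criteria = "SA")$gdm, 1L)
  # fallback to self-report when the OGTT is absent; missing otherwise
  r <- classify_gdm(NA, NA, NA, self_report = 1L)
  expect_equal(r$gdm, 1L)
  expect_equal(r$source, "self-report")
  expect_true(is.na(classify_gdm(NA, NA, NA)$gdm))
  # incomplete OGTT cannot rule GDM out: falls back, then missing
  expect_true(is.na(classify_gdm(4.5, NA, NA)$gdm))
  expect_equal(classify_gdm(4.5, NA, NA, self_report = 0L)$gdm, 0L)
})

test_that("trapezoidal AUC matches printed group means and linearity", {
  expect_equal(auc_glucose(4.27, 7.31, 5.96), 12.425)
  expect_equal(auc_glucose(4.53, NA, 5.49), 10.02)
  expect_equal(auc_glucose(5.34, NA, 9.14), 14.48)
  expect_equal(auc_glucose(6, 6, 6), 12)       # constant profile: rectangle
  expect_equal(auc_glucose(6, NA, 6), 12)
  expect_error(auc_glucose(5, NA, NA), "two OGTT timepoints")

  # linearity: trapezoid of mean profile == mean of per-row trapezoids
  set.seed(5)
  f <- runif(50, 4, 6); g1 <- runif(50, 6, 9); g2 <- runif(50, 5, 8)
  expect_equal(auc_glucose(mean(f), mean(g1), mean(g2)),
               mean(auc_glucose(f, g1, g2)), tolerance = 1e-10)
})

test_that("log-winsorize-standardize yields unit moments and clamps tails", {
  set.seed(9)
  x <- rlnorm(500, 2, 0.4)
  z <- log_winsorize_standardize(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  # monotone rank preservation for interior points
  q <- quantile(log(x), c(0.01, 0.99))
  interior <- log(x) > q[1] & log(x) < q[2]
  expect_equal(order(z[interior]), order(x[interior]))
  # one extreme outlier is pulled to the upper clamp value
  y <- c(rlnorm(999, 2, 0.3), 1e6)
  zy <- log_winsorize_standardize(y)
  clamp <- quantile(log(y), 0.99)
  expected_z <- (clamp - mean(pmin(pmax(log(y),
                                        quantile(log(y), 0.01)), clamp))) /
    sd(pmin(pmax(log(y), quantile(log(y), 0.01)), clamp))
  expect_equal(zy[1000], unname(expected_z), tolerance = 1e-10)
  expect_error(log_winsorize_standardize(c(-1, 2, 3)), "> 0")
  expect_error(log_winsorize_standardize(rep(5, 10)), "degenerate")
})

test_that("diet score ties at the median and categories behave as defined", {
  med <- setNames(rep(2, 6), ffq_groups())
  at_median <- matrix(2, 1, 6, dimnames = list(NULL, ffq_groups()))
  ds <- diet_quality(at_median, med)
  expect_equal(ds$points, 4L)                # >= passes, < fails at equality
  expect_equal(as.character(ds$category), "Medium")
  expect_false(ds$binary_low)

  best <- matrix(c(3, 3, 3, 3, 1, 1), 1, dimnames = list(NULL, ffq_groups()))
  expect_equal(diet_quality(best, med)$points, 6L)
  expect_equal(as.character(diet_quality(best, med)$category), "High")

  two <- matrix(c(3, 3, 1, 1, 3, 3), 1, dimnames = list(NULL, ffq_groups()))
  ds2 <- diet_quality(two, med)
  expect_equal(ds2$points, 2L)
  expect_true(ds2$binary_low)

  zero <- matrix(c(1, 1, 1, 1, 3, 3), 1, dimnames = list(NULL, ffq_groups()))
  expect_true(diet_quality(zero, med)$binary_low)   # 0 points counts as Low

  with_na <- matrix(c(NA, 3, 3, 3, 1, 1), 1,
                    dimnames = list(NULL, ffq_groups()))
  expect_true(is.na(diet_quality(with_na, med)$points))

  # raising an intake to the median never loses a favourable point
  set.seed(11)
  ffq <- matrix(rlnorm(60), 10, 6, dimnames = list(NULL, ffq_groups()))
  base_pts <- diet_quality(ffq, med)$points
  bumped <- ffq
  bumped[, "fruits"] <- pmax(bumped[, "fruits"], med["fruits"])
  expect_true(all(diet_quality(bumped, med)$points >= base_pts))
})

test_that("education recoding follows the two study schemes", {
  expect_equal(recode_education("High school completed", "START")$level, 2L)
  r <- recode_education("Master's, Doctorate or professional degree", "START")
  expect_equal(r$level, 5L)
  expect_true(r$post_secondary)
  expect_false(recode_education("High school completed",
                                "START")$post_secondary)
  expect_true(is.na(recode_education(education_unclassifiable(),
                                     "BiB")$level))
  expect_equal(recode_education("A-level equivalent", "BiB")$level, 3L)
  expect_false(recode_education("A-level equivalent", "BiB")$post_secondary)
  expect_true(recode_education("Higher than A-level", "BiB")$post_secondary)
  expect_error(recode_education("PhD in basket weaving", "START"),
               "valid labels")
})

test_that("country and BMI helpers behave", {
  expect_true(born_in_south_asia("Pakistan"))
  expect_true(born_in_south_asia("sri lanka"))
  expect_false(born_in_south_asia("Canada"))
  expect_true(is.na(born_in_south_asia(NA)))
  expect_equal(bmi(61.7, 162.5), 23.36, tolerance = 1e-3)
  expect_equal(bmi(100, 200), 25)
  expect_true(is.na(bmi(NA, 170)))
  expect_error(bmi(70, -1), "height")
})

test_that("index-pregnancy selection applies the four rules in order", {
  # rule 1: missing GDM dropped
  r <- select_index_pregnancy(preg_rows(c(2010, 2012), c(NA, 0)),
                              covariate_cols = c("cov_a", "cov_b"))
  expect_equal(r$preg_year, 2012)
  # all-negative: keep the latest
  r <- select_index_pregnancy(preg_rows(c(2011, 2014), c(0, 0)),
                              covariate_cols = c("cov_a", "cov_b"))
  expect_equal(r$preg_year, 2014)
  expect_equal(attr(r, "selection_rule"), "latest GDM-negative")
  # any positive: keep the earliest positive
  r <- select_index_pregnancy(preg_rows(c(2011, 2013, 2015), c(0, 1, 1)),
                              covariate_cols = c("cov_a", "cov_b"))
  expect_equal(r$preg_year, 2013)
  expect_equal(attr(r, "selection_rule"), "earliest GDM-positive")
  # rules 2-3: complete-covariate rows beat incomplete ones
  rows <- preg_rows(c(2011, 2013), c(1, 1), miss = c(1, 0))
  r <- select_index_pregnancy(rows, covariate_cols = c("cov_a", "cov_b"))
  expect_equal(r$preg_year, 2013)
  # least-missing wins when none are complete
  rows <- preg_rows(c(2011, 2013), c(0, 0), miss = c(2, 1))
  r <- select_index_pregnancy(rows, covariate_cols = c("cov_a", "cov_b"))
  expect_equal(r$preg_year, 2013)
  # all GDM missing: mother excluded with a log entry
  r <- select_index_pregnancy(preg_rows(2010, NA),
                              covariate_cols = c("cov_a", "cov_b"))
  expect_equal(nrow(r), 0)
  expect_match(attr(r, "selection_rule"), "excluded")
  # date tie between positives: first in input order
  rows <- preg_rows(c(2012, 2012), c(1, 1))
  r <- select_index_pregnancy(rows, covariate_cols = c("cov_a", "cov_b"))
  expect_equal(r$pregnancy_id, "M1_P1")
  # idempotence: selecting from the selected row returns it unchanged
  r2 <- select_index_pregnancy(r, covariate_cols = c("cov_a", "cov_b"))
  expect_equal(r2$pregnancy_id, r$pregnancy_id)
})

test_that("whole-cohort derivation returns one analysis row per mother", {
  s <- small_sim(seed = 61)
  d <- derive_phenotypes(s$sim$cohort)
  expect_true(all(c("bmi", "gdm_iadpsg", "gdm_sa", "auc_raw", "auc_z",
                    "diet_points", "edu_level", "born_sa") %in% names(d)))
  # standardized AUC has unit moments within study
  for (st in unique(d$study)) {
    z <- d$auc_z[d$study == st & !is.na(d$auc_z)]
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
  }
  sel <- select_index_pregnancies(d)
  expect_false(any(duplicated(sel$selected$mother_id)))
  expect_true(all(!is.na(sel$selected$gdm_iadpsg)))
  # idempotent: re-selecting changes nothing
  sel2 <- select_index_pregnancies(sel$selected)
  expect_equal(sel2$selected$pregnancy_id, sel$selected$pregnancy_id)
})
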