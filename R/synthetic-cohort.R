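#' Simulate genotype dosages at independent variants
#'
#' Draws allele dosages for `n_individuals` at `n_variants` biallelic variants.
#' Each variant is assigned a minor-allele frequency sampled uniformly in
#' `[maf_low, maf_high]`, and each dosage is the sum of two independent
#' Bernoulli allele draws, so dosages live in \{0, 1, 2\} and are in
#' Hardy-Weinberg proportions. Variants are unlinked (no LD).
#'
#' @param n_individuals Number of individuals (rows).
#' @param n_variants Number of variants (columns).
#' @param maf_low,maf_high Bounds for the per-variant allele frequency;
#'   `0 < maf_low <= maf_high < 0.5`.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `genotype_matrix`: a list with
#'   `individual_ids`, `variant_ids`, `dosages` (individuals x variants),
#'   `effect_alleles`, `other_alleles`, and the sampled `maf` per variant.
#' @export
generate_genotypes <- function(n_individuals, n_variants,
                               maf_low = 0.05, maf_high = 0.45,
                               seed = NULL) {
  if (n_individuals < 1 || n_variants < 1) {
    stop("n_individuals and n_variants must be >= 1")
  }
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high < 0.5)) {
    stop("invalid MAF bounds: need 0 < maf_low <= maf_high < 0.5")
  }
  if (!is.null(seed)) set.seed(seed)
  maf <- stats::runif(n_variants, maf_low, maf_high)
  dos <- sapply(maf, function(p) stats::rbinom(n_individuals, 2L, p))
  dos <- matrix(as.numeric(dos), nrow = n_individuals, ncol = n_variants)
  ind_ids <- sprintf("ID%05d", seq_len(n_individuals))
  var_ids <- sprintf("var%05d", seq_len(n_variants))
  dimnames(dos) <- list(ind_ids, var_ids)
  alleles <- c("A", "C", "G", "T")
  eff <- sample(alleles, n_variants, replace = TRUE)
  # other allele never equals the effect allele
  oth <- vapply(eff, function(a) sample(setdiff(alleles, a), 1L), character(1))
  structure(
    list(individual_ids = ind_ids, variant_ids = var_ids, dosages = dos,
         effect_alleles = eff, other_alleles = unname(oth), maf = maf),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants\n",
              length(x$individual_ids), length(x$variant_ids)))
  invisible(x)
}

#' Simulate a variant-weight table emulating GWAS summary input
#'
#' A fixed fraction of variants (`floor(n_variants * prop_nonzero)`) is
#' designated causal: they receive normal weights with standard deviation
#' `weight_sd` and source-GWAS p-values concentrated below 1.4e-3 (log-uniform
#' between 1e-10 and 1.4e-3). The remaining variants carry weight zero and
#' uniform p-values, so p-value-threshold subsetting can separate signal from
#' noise.
#'
#' @param n_variants Number of variants.
#' @param prop_nonzero Fraction of variants with a nonzero weight, in (0, 1].
#' @param weight_sd Standard deviation of nonzero weights (> 0).
#' @param seed Optional integer seed.
#' @param genotypes Optional `genotype_matrix`; when given, variant ids and
#'   effect alleles are copied from it so the two tables align for scoring.
#' @return A `data.frame` with columns `variant_id`, `effect_allele`,
#'   `weight`, `gwas_p`.
#' @export
generate_weights <- function(n_variants, prop_nonzero = 0.1, weight_sd = 0.05,
                             seed = NULL, genotypes = NULL) {
  if (!(prop_nonzero > 0 && prop_nonzero <= 1)) {
    stop("prop_nonzero must be in (0, 1]")
  }
  if (weight_sd <= 0) stop("weight_sd must be > 0")
  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "genotype_matrix"))
    if (length(genotypes$variant_ids) != n_variants) {
      stop("n_variants does not match the genotype matrix")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n_causal <- floor(n_variants * prop_nonzero)
  if (n_causal < 1) stop("degenerate config: no causal variants")
  causal <- seq_len(n_causal)  # first block; scoring is order-invariant
  weight <- numeric(n_variants)
  weight[causal] <- stats::rnorm(n_causal, 0, weight_sd)
  gwas_p <- stats::runif(n_variants)
  gwas_p[causal] <- 10^stats::runif(n_causal, -10, log10(1.4e-3))
  if (is.null(genotypes)) {
    var_ids <- sprintf("var%05d", seq_len(n_variants))
    eff <- sample(c("A", "C", "G", "T"), n_variants, replace = TRUE)
  } else {
    var_ids <- genotypes$variant_ids
    eff <- genotypes$effect_alleles
  }
  data.frame(variant_id = var_ids, effect_allele = eff,
             weight = weight, gwas_p = gwas_p,
             stringsAsFactors = FALSE)
}

# Food-frequency groups used by the diet-quality score. The first four are
# favourable (point for intake >= study median), the last two unfavourable
# (point for intake < study median).
#' @rdname diet_quality
#' @export
ffq_groups <- function() {
  c("green_leafy_veg", "raw_veg", "cooked_veg", "fruits",
    "fried_fast_snacks", "meat_poultry")
}

#' Education category labels per study scheme
#'
#' Ordered category labels for the two study-specific education recodings:
#' a five-level scheme (START-like) and a four-level UK-qualifications scheme
#' (BiB-like). The unclassifiable token maps to missing under either scheme.
#' @return Character vector of ordered labels.
#' @export
education_labels <- function(scheme = c("START", "BiB")) {
  scheme <- match.arg(scheme)
  if (scheme == "START") {
    c("Less than high school",
      "High school completed",
      "Diploma or certificate from trade, technical or vocational school",
      "Bachelor's or undergraduate degree, or teacher's college",
      "Master's, Doctorate or professional degree")
  } else {
    c("Less than 5 GCSE equivalent",
      "5 GCSE equivalent",
      "A-level equivalent",
      "Higher than A-level")
  }
}

#' @rdname education_labels
#' @export
education_unclassifiable <- function() "Unclassifiable foreign degree"

#' Configuration for the two-study synthetic cohort
#'
#' Holds every parameter of the generative model: per-study sample sizes and
#' covariate distributions, trait coefficients (defaults are the pooled
#' multivariable estimates the generator is meant to reproduce), glucose
#' intercepts and residual standard deviations, missingness rates, and the
#' fraction of mothers contributing more than one pregnancy. GDM itself is
#' never simulated: it must emerge downstream from threshold classification
#' of the simulated glucose values.
#'
#' @param n_mothers Integer vector, mothers per study.
#' @param study_labels Study names; the first study is 3-point OGTT
#'   (fasting/1h/2h) with diet data, the second 2-point (fasting/2h) without.
#' @param ogtt_points 3 or 2 per study.
#' @param has_diet Logical per study: are food-frequency intakes collected?
#' @param edu_scheme Education coding scheme per study ("START" or "BiB").
#' @param born_sa_prob Probability a mother was born in South Asia, per study.
#' @param parental_prob Probability of a parental history of diabetes.
#' @param age_mean,age_sd,height_mean,height_sd,bmi_mean,bmi_sd,years_mean
#'   Per-study covariate distribution parameters.
#' @param coefficients 3 x 8 matrix of trait coefficients (rows `fpg`, `g1h`,
#'   `g2h`; columns `prs`, `age`, `bmi`, `parental`, `born_sa`, `parity`,
#'   `edu`, `diet_low`).
#' @param intercepts,residual_sd Named numeric per trait.
#' @param interaction Optional `list(trait=, var=, beta=)` adding
#'   `beta * PRS_z * var` to one trait's linear predictor; `var` is one of the
#'   design columns (e.g. `"diet_low"`, `"bmi"`).
#' @param multi_preg_frac Fraction of mothers with 2-3 pregnancy rows.
#' @param missing_rates Named per-field completely-at-random missingness
#'   probabilities in [0, 1).
#' @param self_report_prob Fraction of pregnancies with a self-reported GDM
#'   status available (used downstream only when OGTT is missing).
#' @param self_report_accuracy Agreement of the self-report with the
#'   OGTT-derived status.
#' @param preexisting_prob Probability of pre-existing diabetes (flagged,
#'   excluded by the pipeline).
#' @param age_parity_rate Per-study rate linking age to expected parity
#'   (induces the positive age-parity correlation).
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_mothers = c(840L, 4300L),
                          study_labels = c("START", "BiB"),
                          ogtt_points = c(3L, 2L),
                          has_diet = c(TRUE, FALSE),
                          edu_scheme = c("START", "BiB"),
                          born_sa_prob = c(0.886, 0.556),
                          parental_prob = c(0.42, 0.29),
                          age_mean = c(29.5, 28.0),
                          age_sd = c(4.0, 5.0),
                          height_mean = c(162.0, 159.7),
                          height_sd = c(6.2, 5.7),
                          bmi_mean = c(23.9, 25.7),
                          bmi_sd = c(4.5, 5.3),
                          years_mean = c(6.6, 9.7),
                          coefficients = default_trait_coefficients(),
                          intercepts = c(fpg = 3.30, g1h = 5.49, g2h = 2.50),
                          residual_sd = c(fpg = 0.45, g1h = 1.70, g2h = 1.45),
                          interaction = NULL,
                          multi_preg_frac = 0.15,
                          missing_rates = default_missing_rates(),
                          self_report_prob = 0.6,
                          self_report_accuracy = 0.9,
                          preexisting_prob = 0.01,
                          age_parity_rate = c(0.065, 0.11)) {
  k <- length(n_mothers)
  stopifnot(k == length(study_labels), k == length(ogtt_points))
  if (any(n_mothers < 1)) stop("n_mothers must be >= 1")
  if (any(residual_sd <= 0)) stop("residual SDs must be > 0")
  if (any(missing_rates < 0 | missing_rates >= 1)) {
    stop("missingness rates must be in [0, 1)")
  }
  if (!all(ogtt_points %in% c(2L, 3L))) stop("ogtt_points must be 2 or 3")
  stopifnot(is.matrix(coefficients),
            identical(rownames(coefficients), c("fpg", "g1h", "g2h")))
  if (ncol(coefficients) != 8L) {
    stop("config error: coefficient vectors must have 8 terms")
  }
  if (!is.null(interaction)) {
    stopifnot(is.list(interaction),
              all(c("trait", "var", "beta") %in% names(interaction)),
              interaction$trait %in% rownames(coefficients))
  }
  structure(
    list(n_mothers = as.integer(n_mothers), study_labels = study_labels,
         ogtt_points = as.integer(ogtt_points), has_diet = has_diet,
         edu_scheme = edu_scheme, born_sa_prob = born_sa_prob,
         parental_prob = parental_prob,
         age_mean = age_mean, age_sd = age_sd,
         height_mean = height_mean, height_sd = height_sd,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd, years_mean = years_mean,
         coefficients = coefficients, intercepts = intercepts,
         residual_sd = residual_sd, interaction = interaction,
         multi_preg_frac = multi_preg_frac, missing_rates = missing_rates,
         self_report_prob = self_report_prob,
         self_report_accuracy = self_report_accuracy,
         preexisting_prob = preexisting_prob,
         age_parity_rate = age_parity_rate),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_trait_coefficients <- function() {
  terms <- c("prs", "age", "bmi", "parental", "born_sa", "parity",
             "edu", "diet_low")
  # fpg and g2h rows are the pooled multivariable estimates (diet from the
  # diet-collecting study); g1h is taken as their midpoint (not reported).
  m <- rbind(
    fpg = c(0.085, 0.015, 0.031, 0.060, 0.076, -0.018, -0.019, 0.102),
    g1h = c(0.146, 0.046, 0.047, 0.163, 0.192, -0.064, -0.045, 0.234),
    g2h = c(0.207, 0.076, 0.062, 0.265, 0.308, -0.110, -0.071, 0.365)
  )
  colnames(m) <- terms
  m
}

#' @rdname cohort_config
#' @export
default_missing_rates <- function() {
  c(height = 0.01, weight = 0.01, education_raw = 0.01,
    country_of_birth = 0.005, years_in_country = 0.03,
    parental_history = 0.02, ffq = 0.03,
    fpg = 0.02, g1h = 0.02, g2h = 0.02)
}

#' Simulate a two-study pregnancy cohort
#'
#' Draws covariates per mother from the configured distributions, computes the
#' standardized PRS from the supplied genotypes and weights (one genotype per
#' mother, shared across her pregnancies), generates fasting/1h/2h glucose as
#' linear functions of the design plus Gaussian noise, gives a configured
#' fraction of mothers 2-3 pregnancies with independent OGTT draws, and
#' finally applies completely-at-random missingness per field. Rows of the
#' 2-point-OGTT study never carry a 1-hour value.
#'
#' @param config A [cohort_config()].
#' @param genotypes A `genotype_matrix` with at least `sum(n_mothers)` rows.
#' @param weights A variant-weight table as from [generate_weights()].
#' @param seed Optional integer seed.
#' @return A list with `cohort` (one row per pregnancy) and `truth` (the
#'   configured coefficients, the per-row design matrix before missingness,
#'   the per-row linear predictors, and the per-mother standardized PRS) for
#'   parameter-recovery testing.
#' @export
simulate_cohort <- function(config, genotypes, weights, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(genotypes, "genotype_matrix"))
  total <- sum(config$n_mothers)
  if (length(genotypes$individual_ids) < total) {
    stop("genotype rows must cover all mothers (one genotype per mother)")
  }
  if (!is.null(seed)) set.seed(seed)

  raw_scores <- score_individuals(genotypes, weights, p_threshold = 1)
  co <- config$coefficients

  study_rows <- vector("list", length(config$n_mothers))
  offset <- 0L
  for (s in seq_along(config$n_mothers)) {
    n <- config$n_mothers[s]
    idx <- offset + seq_len(n)
    offset <- offset + n
    mother_id <- genotypes$individual_ids[idx]
    prs_z <- as.numeric(scale(raw_scores[idx]))  # standardized within study

    age0 <- pmin(pmax(stats::rnorm(n, config$age_mean[s], config$age_sd[s]),
                      18), 43)
    height <- stats::rnorm(n, config$height_mean[s], config$height_sd[s])
    bmi <- pmax(stats::rnorm(n, config$bmi_mean[s], config$bmi_sd[s]), 15)
    weight_kg <- bmi * (height / 100)^2
    parity0 <- stats::rpois(n, pmax((age0 - 18) * config$age_parity_rate[s],
                                    0.05))
    labs <- education_labels(config$edu_scheme[s])
    edu_probs <- if (config$edu_scheme[s] == "START") {
      c(0.05, 0.11, 0.15, 0.45, 0.24)
    } else c(0.30, 0.25, 0.16, 0.29)
    edu_level <- sample(seq_along(labs), n, replace = TRUE, prob = edu_probs)
    education_raw <- labs[edu_level]
    if (config$edu_scheme[s] == "BiB") {
      # a sliver of unclassifiable foreign qualifications
      unk <- stats::runif(n) < 0.01
      education_raw[unk] <- education_unclassifiable()
    }
    born_sa <- stats::rbinom(n, 1L, config$born_sa_prob[s])
    sa_countries <- c("India", "Pakistan", "Sri Lanka", "Bangladesh")
    sa_w <- if (s == 1L) c(0.72, 0.23, 0.03, 0.02) else c(0.05, 0.92, 0.01, 0.02)
    country <- ifelse(born_sa == 1L,
                      sample(sa_countries, n, replace = TRUE, prob = sa_w),
                      sample(c("Canada", "United Kingdom", "Other"), n,
                             replace = TRUE))
    years_in <- stats::rgamma(n, shape = 2,
                              rate = 2 / config$years_mean[s])
    parental <- stats::rbinom(n, 1L, config$parental_prob[s])

    if (config$has_diet[s]) {
      # fried/fast-food intake drifts up with BMI (diet-adiposity association)
      ffq <- cbind(
        green_leafy_veg = stats::rlnorm(n, 1.0, 0.6),
        raw_veg = stats::rlnorm(n, 0.8, 0.6),
        cooked_veg = stats::rlnorm(n, 1.2, 0.6),
        fruits = stats::rlnorm(n, 1.1, 0.6),
        fried_fast_snacks = stats::rlnorm(n, 0.5 + 0.02 * (bmi - 24), 0.6),
        meat_poultry = stats::rlnorm(n, 0.9, 0.6)
      )
      med <- apply(ffq, 2, stats::median)
      ds <- diet_quality(ffq, med)
      diet_low <- as.numeric(ds$binary_low)
    } else {
      ffq <- matrix(NA_real_, n, 6,
                    dimnames = list(NULL, ffq_groups()))
      diet_low <- rep(0, n)  # diet term inert where no FFQ is collected
    }

    n_preg <- rep(1L, n)
    multi <- stats::runif(n) < config$multi_preg_frac
    n_preg[multi] <- sample(2:3, sum(multi), replace = TRUE,
                            prob = c(0.7, 0.3))
    rep_idx <- rep(seq_len(n), n_preg)
    preg_no <- sequence(n_preg)
    nr <- length(rep_idx)

    age <- age0[rep_idx] + 2.2 * (preg_no - 1L)
    parity <- parity0[rep_idx] + (preg_no - 1L)
    preg_year <- 2008L + as.integer(round(age - age0[rep_idx])) +
      sample(0:3, nr, replace = TRUE)
    # ensure strictly increasing order within mother
    preg_year <- preg_year + preg_no

    design <- data.frame(
      prs_z = prs_z[rep_idx], age = age, bmi = bmi[rep_idx],
      parental = parental[rep_idx], born_sa = born_sa[rep_idx],
      parity = parity, edu = edu_level[rep_idx],
      diet_low = diet_low[rep_idx]
    )
    design$edu[is.na(design$edu)] <- mean(edu_level, na.rm = TRUE)
    X <- as.matrix(design)

    traits <- list()
    for (tr in c("fpg", "g1h", "g2h")) {
      if (tr == "g1h" && config$ogtt_points[s] != 3L) {
        traits[[tr]] <- rep(NA_real_, nr)
        next
      }
      lp <- config$intercepts[[tr]] + drop(X %*% co[tr, ])
      if (!is.null(config$interaction) && config$interaction$trait == tr) {
        lp <- lp + config$interaction$beta *
          design$prs_z * design[[config$interaction$var]]
      }
      traits[[tr]] <- lp + stats::rnorm(nr, 0, config$residual_sd[[tr]])
    }

    # truth-level IADPSG status drives the (imperfect) self-report
    true_gdm <- (traits$fpg >= 5.1) |
      (!is.na(traits$g1h) & traits$g1h >= 10.8) | (traits$g2h >= 8.5)
    has_sr <- stats::runif(nr) < config$self_report_prob
    sr <- ifelse(stats::runif(nr) < config$self_report_accuracy,
                 true_gdm, !true_gdm)
    self_report <- ifelse(has_sr, as.integer(sr), NA_integer_)

    tab <- data.frame(
      mother_id = mother_id[rep_idx],
      pregnancy_id = paste0(mother_id[rep_idx], "_P", preg_no),
      preg_year = preg_year,
      study = config$study_labels[s],
      age = age,
      height = height[rep_idx],
      weight = weight_kg[rep_idx],
      parity = parity,
      education_raw = education_raw[rep_idx],
      country_of_birth = country[rep_idx],
      years_in_country = years_in[rep_idx],
      parental_history = ifelse(parental[rep_idx] == 1L,
                                "one-or-both", "none"),
      stringsAsFactors = FALSE
    )
    tab <- cbind(tab, as.data.frame(ffq[rep_idx, , drop = FALSE]))
    tab$fpg <- traits$fpg
    tab$g1h <- traits$g1h
    tab$g2h <- traits$g2h
    tab$self_report_gdm <- self_report
    tab$preexisting_diabetes <-
      stats::rbinom(n, 1L, config$preexisting_prob)[rep_idx]

    study_rows[[s]] <- list(tab = tab, design = design,
                            prs_z = stats::setNames(prs_z, mother_id))
  }

  cohort <- do.call(rbind, lapply(study_rows, `[[`, "tab"))
  design <- do.call(rbind, lapply(study_rows, `[[`, "design"))
  rownames(cohort) <- rownames(design) <- NULL

  # completely-at-random missingness, applied last, per field
  mr <- config$missing_rates
  for (f in names(mr)) {
    if (mr[[f]] <= 0) next
    if (f == "ffq") {
      hit <- stats::runif(nrow(cohort)) < mr[[f]]
      cohort[hit, ffq_groups()] <- NA_real_
    } else if (f %in% names(cohort)) {
      hit <- stats::runif(nrow(cohort)) < mr[[f]]
      cohort[[f]][hit] <- NA
    }
  }

  prs_all <- unlist(lapply(study_rows, `[[`, "prs_z"))
  list(cohort = cohort,
       truth = list(coefficients = co, intercepts = config$intercepts,
                    residual_sd = config$residual_sd,
                    interaction = config$interaction,
                    design = design, prs_z = prs_all))
}
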