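#' Per-study descriptive table (cases versus non-cases)
#'
#' Means (SD) of continuous characteristics with pooled-variance t-test
#' p-values, and PRS-tertile and parity category counts with chi-squared
#' p-values, stratified by GDM status.
#'
#' @param data Analysis data with `gdm` column (0/1) plus `age`, `bmi`,
#'   `fpg`, `g2h`, `auc_raw`, `prs_tertile`, `parity`.
#' @param gdm_col Name of the 0/1 GDM column.
#' @return List with `continuous` (data.frame) and `categorical` (data.frame
#'   of chi-squared tests).
#' @export
study_descriptives <- function(data, gdm_col = "gdm_iadpsg") {
  g <- data[[gdm_col]]
  cont_vars <- intersect(c("age", "height", "weight", "bmi", "fpg", "g1h",
                           "g2h", "auc_raw", "prs_z"), names(data))
  cont <- do.call(rbind, lapply(cont_vars, function(v) {
    x0 <- data[[v]][g == 0]; x1 <- data[[v]][g == 1]
    x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
    if (length(x0) < 2 || length(x1) < 2) return(NULL)
    tt <- two_sample_t(x0, x1)
    data.frame(variable = v, mean_nogdm = mean(x0), sd_nogdm = stats::sd(x0),
               mean_gdm = mean(x1), sd_gdm = stats::sd(x1), p = tt$p)
  }))
  cat_rows <- list()
  if ("prs_tertile" %in% names(data)) {
    tab <- table(factor(g, levels = 0:1), data$prs_tertile)
    if (all(dim(tab) >= 2)) {
      cs <- chi_squared_independence(tab)
      cat_rows$tertile <- data.frame(variable = "prs_tertile",
                                     statistic = cs$statistic, df = cs$df,
                                     p = cs$p)
    }
  }
  if ("parity" %in% names(data)) {
    pcat <- cut(data$parity, c(-1, 0, 1, Inf), labels = c("0", "1", "2+"))
    tab <- table(factor(g, levels = 0:1), pcat)
    if (all(dim(tab) >= 2) && all(colSums(tab) > 0)) {
      cs <- chi_squared_independence(tab[, colSums(tab) > 0, drop = FALSE])
      cat_rows$parity <- data.frame(variable = "parity_category",
                                    statistic = cs$statistic, df = cs$df,
                                    p = cs$p)
    }
  }
  list(continuous = cont, categorical = do.call(rbind, cat_rows))
}

default_adjustment <- function(data, pcs = paste0("PC", 1:5)) {
  base <- c("prs_z", "age", "bmi", "parental", "born_sa_bin", "parity",
            "edu_level")
  if ("diet_low_bin" %in% names(data) &&
      any(!is.na(data$diet_low_bin))) {
    base <- c(base, "diet_low_bin")
  }
  c(base, intersect(pcs, names(data)))
}

#' Run the full analysis for one study
#'
#' Sequences the pipeline for a single study's rows: derive phenotypes,
#' exclude pre-existing diabetes, select one index pregnancy per mother,
#' score and standardize the PRS with tertiles, compute genotype principal
#' components, build descriptive statistics, fit the multivariable linear
#' (fasting glucose, 2-hour glucose, standardized AUC glucose) and logistic
#' (GDM) models, the PRS-by-factor interaction models, and the population
#' attributable fractions. A filter ledger records row counts after every
#' stage.
#'
#' @param cohort Raw cohort table (all studies; filtered internally).
#' @param genotypes A `genotype_matrix` covering the study's mothers.
#' @param weights Variant-weight table.
#' @param study Study label to analyse.
#' @param edu_scheme Education scheme for this study.
#' @param p_threshold PRS p-value threshold (default 1: all variants).
#' @param k_pcs Number of genotype PCs to adjust for.
#' @param gdm_col Outcome criteria column (`"gdm_iadpsg"` or `"gdm_sa"`).
#' @param interaction_modifiers Columns to interact with the PRS.
#' @param paf_exposures Binary exposure columns for attributable fractions.
#' @param paf_B Bootstrap replicates per PAF.
#' @param seed Seed for the PAF bootstrap.
#' @return A list of class `study_bundle` with `study`, `data` (analysis
#'   rows), `descriptives`, `models` (per outcome), `interactions`, `paf`,
#'   `selection_log`, `filter_ledger`, `pca`, and `manifest`.
#' @export
run_study <- function(cohort, genotypes, weights, study,
                      edu_scheme = "START", p_threshold = 1, k_pcs = 5L,
                      gdm_col = "gdm_iadpsg",
                      interaction_modifiers = c("age", "bmi", "parental",
                                                "born_sa_bin", "parity",
                                                "edu_level"),
                      paf_exposures = c("prs_t3", "parental"),
                      paf_B = 200L, seed = NULL) {
  ledger <- data.frame(stage = character(), rows = integer())
  note <- function(stage, n) {
    ledger <<- rbind(ledger, data.frame(stage = stage, rows = n))
  }
  sub <- cohort[cohort$study == study, , drop = FALSE]
  note("input pregnancies", nrow(sub))

  es <- stats::setNames(edu_scheme, study)
  derived <- derive_phenotypes(sub, edu_scheme = es)

  pre <- !is.na(derived$preexisting_diabetes) &
    derived$preexisting_diabetes == 1
  derived <- derived[!pre, , drop = FALSE]
  note("after pre-existing diabetes exclusion", nrow(derived))

  sel <- select_index_pregnancies(derived, gdm_col = gdm_col)
  dat <- sel$selected
  note("index pregnancies (non-missing GDM)", nrow(dat))

  gsub <- subset_genotypes(genotypes, dat$mother_id)
  prs <- prs_result(gsub, weights, rep(study, nrow(dat)), p_threshold)
  dat$prs_z <- prs$z_score
  dat$prs_tertile <- prs$tertile
  pca <- genotype_pca(gsub, k = k_pcs)
  dat <- cbind(dat, as.data.frame(pca$scores))

  dat$parental <- as.numeric(dat$parental_history == "one-or-both")
  dat$born_sa_bin <- as.numeric(dat$born_sa)
  dat$gdm <- dat[[gdm_col]]
  dat <- binarize_for_paf(dat)
  note("analysis rows", nrow(dat))

  desc <- study_descriptives(dat, gdm_col = "gdm")

  adj <- default_adjustment(dat, paste0("PC", seq_len(k_pcs)))
  models <- list()
  for (outc in intersect(c("fpg", "g2h", "auc_z"), names(dat))) {
    if (all(is.na(dat[[outc]]))) next
    models[[outc]] <- fit_linear(model_spec(outc, adj), dat)
  }
  models$gdm <- fit_logistic(model_spec("gdm", adj, family = "logistic"), dat)

  inter <- list()
  mods <- intersect(interaction_modifiers, names(dat))
  if ("diet_low_bin" %in% names(dat)) mods <- union(mods, "diet_low_bin")
  for (m in mods) {
    covs <- setdiff(adj, c("prs_z", m))
    inter[[paste0("fpg:", m)]] <-
      fit_interaction("fpg", "prs_z", m, covs, dat, "linear")$interaction
    inter[[paste0("gdm:", m)]] <-
      fit_interaction("gdm", "prs_z", m, covs, dat, "logistic")$interaction
  }

  paf <- list()
  paf_adj <- intersect(c("age_29_31", "age_32_plus", "bmi_high", "edu_post",
                         "born_sa_bin", "parental", "parity_ge1",
                         "diet_low_bin",
                         paste0("PC", seq_len(k_pcs))), names(dat))
  for (ex in intersect(paf_exposures, names(dat))) {
    f <- stats::as.formula(paste("gdm ~", paste(unique(c(ex, paf_adj)),
                                                collapse = " + ")))
    paf[[ex]] <- af_model_based(f, dat, ex, B = paf_B, seed = seed)
  }

  structure(
    list(study = study, data = dat, descriptives = desc, models = models,
         interactions = inter, paf = paf, selection_log = sel$log,
         filter_ledger = ledger, pca = pca,
         manifest = list(study = study, seed = seed,
                         p_threshold = p_threshold, k_pcs = k_pcs,
                         gdm_col = gdm_col, rows = nrow(dat),
                         timestamp_free = TRUE)),
    class = "study_bundle"
  )
}

tidy_of <- function(fit) fit$tidy

#' Meta-analyse two study bundles
#'
#' Pools every regression coefficient shared by the two bundles (identity
#' scale for linear betas, log scale for logistic odds ratios), each shared
#' interaction term, and each shared attributable fraction (identity scale),
#' attaching Cochran's Q, its p-value and I-squared to every pooled row.
#'
#' @param bundle1,bundle2 `study_bundle`s from [run_study()].
#' @return List with data.frames `coefficients`, `interactions`, `paf`.
#' @export
run_meta <- function(bundle1, bundle2) {
  pool_rows <- function(t1, t2, logistic) {
    shared <- intersect(t1$term, t2$term)
    out <- lapply(shared, function(tm) {
      r1 <- t1[t1$term == tm, ]; r2 <- t2[t2$term == tm, ]
      res <- pool_fixed(data.frame(estimate = c(r1$estimate, r2$estimate),
                                   se = c(r1$se, r2$se)))
      data.frame(term = tm,
                 estimate = if (logistic) exp(res$estimate) else res$estimate,
                 ci_lo = if (logistic) exp(res$ci_lo) else res$ci_lo,
                 ci_hi = if (logistic) exp(res$ci_hi) else res$ci_hi,
                 p = res$p, Q = res$Q, het_p = res$het_p,
                 I2 = round(res$I2))
    })
    do.call(rbind, out)
  }
  coefs <- list()
  for (outc in intersect(names(bundle1$models), names(bundle2$models))) {
    logistic <- bundle1$models[[outc]]$family == "logistic"
    tab <- pool_rows(tidy_of(bundle1$models[[outc]]),
                     tidy_of(bundle2$models[[outc]]), logistic)
    if (!is.null(tab)) { tab$outcome <- outc; coefs[[outc]] <- tab }
  }
  inters <- list()
  for (nm in intersect(names(bundle1$interactions),
                       names(bundle2$interactions))) {
    logistic <- grepl("^gdm", nm)
    tab <- pool_rows(bundle1$interactions[[nm]], bundle2$interactions[[nm]],
                     logistic)
    if (!is.null(tab) && nrow(tab)) { tab$model <- nm; inters[[nm]] <- tab }
  }
  pafs <- list()
  for (ex in intersect(names(bundle1$paf), names(bundle2$paf))) {
    p1 <- bundle1$paf[[ex]]; p2 <- bundle2$paf[[ex]]
    res <- pool_fixed(data.frame(estimate = c(p1$af, p2$af),
                                 se = c(p1$se, p2$se)))
    pafs[[ex]] <- data.frame(exposure = ex, af = res$estimate,
                             ci_lo = res$ci_lo, ci_hi = res$ci_hi,
                             p = res$p, Q = res$Q, het_p = res$het_p,
                             I2 = round(res$I2))
  }
  list(coefficients = do.call(rbind, coefs),
       interactions = do.call(rbind, inters),
       paf = do.call(rbind, pafs))
}

#' End-to-end run on a simulated two-study cohort
#'
#' Generates genotypes, weights and the two-study cohort under `config`, runs
#' [run_study()] per study and [run_meta()] across them.
#'
#' @param config A [cohort_config()].
#' @param n_variants Number of simulated variants.
#' @param seed Integer seed governing every random draw.
#' @param ... Passed to [run_study()].
#' @return List with `genotypes`, `weights`, `sim`, `bundles` (per study),
#'   and `meta`.
#' @export
run_simulated_analysis <- function(config = cohort_config(),
                                   n_variants = 200L, seed = 1L, ...) {
  genotypes <- generate_genotypes(sum(config$n_mothers), n_variants,
                                  seed = seed)
  weights <- generate_weights(n_variants, prop_nonzero = 0.3,
                              weight_sd = 0.05, seed = seed + 1L,
                              genotypes = genotypes)
  sim <- simulate_cohort(config, genotypes, weights, seed = seed + 2L)
  bundles <- list()
  for (s in seq_along(config$study_labels)) {
    bundles[[config$study_labels[s]]] <-
      run_study(sim$cohort, genotypes, weights, config$study_labels[s],
                edu_scheme = config$edu_scheme[s], seed = seed + 10L + s, ...)
  }
  meta <- run_meta(bundles[[1]], bundles[[2]])
  list(genotypes = genotypes, weights = weights, sim = sim,
       bundles = bundles, meta = meta)
}
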