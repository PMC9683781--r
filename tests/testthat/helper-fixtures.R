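# Small fixtures built in code; every test that needs randomness sets its
# own seed.

tiny_genotypes <- function(n = 50, m = 20, seed = 42) {
  generate_genotypes(n, m, maf_low = 0.1, maf_high = 0.4, seed = seed)
}

tiny_weights <- function(g, prop = 0.5, seed = 43) {
  generate_weights(length(g$variant_ids), prop_nonzero = prop,
                   weight_sd = 0.1, seed = seed, genotypes = g)
}

small_config <- function(n1 = 150L, n2 = 250L, ...) {
  cohort_config(n_mothers = c(n1, n2), ...)
}

small_sim <- function(seed = 7, n1 = 150L, n2 = 250L, n_var = 60, ...) {
  cfg <- small_config(n1, n2, ...)
  g <- generate_genotypes(n1 + n2, n_var, seed = seed)
  w <- generate_weights(n_var, prop_nonzero = 0.4, weight_sd = 0.05,
                        seed = seed + 1, genotypes = g)
  sim <- simulate_cohort(cfg, g, w, seed = seed + 2)
  list(cfg = cfg, g = g, w = w, sim = sim)
}

# one-mother pregnancy table for selection-rule tests
preg_rows <- function(years, gdm, miss = 0L) {
  k <- length(years)
  df <- data.frame(
    mother_id = "M1",
    pregnancy_id = paste0("M1_P", seq_len(k)),
    preg_year = years, gdm = gdm,
    cov_a = 1, cov_b = 2
  )
  if (any(miss > 0)) {
    for (i in which(miss >= 1)) df$cov_a[i] <- NA
    for (i in which(miss >= 2)) df$cov_b[i] <- NA
  }
  df
}
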