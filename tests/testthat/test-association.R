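test_that("chi-squared matches a permutation null and degenerate cases", {
  tab <- rbind(c(240, 206, 190), c(39, 73, 89))
  cs <- chi_squared_independence(tab)
  expect_equal(cs$df, 2)
  # perfectly proportional table: statistic 0, p 1
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  cs0 <- chi_squared_independence(prop)
  expect_equal(cs0$statistic, 0, tolerance = 1e-12)
  expect_equal(cs0$p, 1)
  # moderate 2x2: p within Monte-Carlo error of a permutation-null estimate
  t22 <- rbind(c(60, 48), c(45, 62))
  cs22 <- chi_squared_independence(t22)
  set.seed(2)
  nulls <- r2dtable(4000, rowSums(t22), colSums(t22))
  stat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  perm_p <- mean(vapply(nulls, stat, 0) >= cs22$statistic - 1e-9)
  expect_lt(abs(cs22$p - perm_p), 3 * sqrt(perm_p * (1 - perm_p) / 4000) +
              0.01)
  expect_error(chi_squared_independence(rbind(c(0, 0), c(1, 2))),
               "degenerate")
})

test_that("pooled t-test matches the closed form and is antisymmetric", {
  x <- c(1.2, 2.4, 3.1); y <- c(2.0, 2.2, 4.5)
  r <- two_sample_t(x, y)
  sp2 <- ((2) * var(x) + (2) * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  r0 <- two_sample_t(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # swapping groups flips the sign, p unchanged
  r2 <- two_sample_t(y, x)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # summary-statistic interface agrees with the raw interface
  rs <- two_sample_t(m1 = mean(x), s1 = sd(x), n1 = 3,
                     m2 = mean(y), s2 = sd(y), n2 = 3)
  expect_equal(rs$t, r$t)
  # Welch option matches t.test
  rw <- two_sample_t(x, c(y, 9.9), welch = TRUE)
  tw <- t.test(x, c(y, 9.9))
  expect_equal(rw$t, unname(tw$statistic), tolerance = 1e-10)
  expect_equal(rw$df, unname(tw$parameter), tolerance = 1e-8)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("linear fit equals the normal-equations oracle", {
  set.seed(21)
  n <- 40
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1 + 0.5 * d$x1 - 0.2 * d$x2 + rnorm(n, 0, 0.3)
  fit <- fit_linear(y ~ x1 + x2, d)
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(fit$tidy$estimate, drop(beta), tolerance = 1e-8)
  sigma2 <- sum((d$y - X %*% beta)^2) / (n - 3)
  se <- sqrt(diag(sigma2 * solve(crossprod(X))))
  expect_equal(fit$tidy$se, unname(se), tolerance = 1e-8)
  # Wald CI self-consistency
  expect_equal(fit$tidy$ci_hi - fit$tidy$estimate,
               qnorm(0.975) * fit$tidy$se, tolerance = 1e-12)
  # exact linear outcome: exact coefficients
  d$z <- 2 + 3 * d$x1
  fz <- suppressWarnings(fit_linear(z ~ x1, d))  # exact fit, sigma ~ 0
  expect_equal(fz$tidy$estimate, c(2, 3), tolerance = 1e-10)
  # collinearity is reported with the aliased column
  d$x3 <- d$x1
  expect_error(fit_linear(y ~ x1 + x3, d), "aliased")
  # complete-case n
  d$x1[1:3] <- NA
  expect_equal(fit_linear(y ~ x1 + x2, d)$n, n - 3L)
})

test_that("logistic fit matches the 2x2 closed form and saturated log-odds", {
  d <- data.frame(
    exposed = rep(c(0, 1), c(1000, 1000)),
    y = c(rep(1, 50), rep(0, 950), rep(1, 100), rep(0, 900))
  )
  fit <- fit_logistic(y ~ exposed, d)
  b <- fit$tidy[fit$tidy$term == "exposed", ]
  expect_equal(b$estimate, log((100 * 950) / (50 * 900)), tolerance = 1e-8)
  expect_equal(b$se, sqrt(1 / 50 + 1 / 950 + 1 / 100 + 1 / 900),
               tolerance = 1e-4)
  expect_equal(b$or, exp(b$estimate))
  # intercept-only: logit of the case fraction
  f0 <- fit_logistic(y ~ 1, d)
  expect_equal(f0$tidy$estimate, qlogis(mean(d$y)), tolerance = 1e-8)
  # saturated binary design reproduces empirical log-odds exactly
  set.seed(4)
  d2 <- data.frame(a = rbinom(400, 1, 0.5), b = rbinom(400, 1, 0.5))
  d2$y <- rbinom(400, 1, plogis(-1 + 0.8 * d2$a - 0.5 * d2$b +
                                  0.3 * d2$a * d2$b))
  fs <- fit_logistic(y ~ a * b, d2)
  cell_logit <- function(a, b) {
    qlogis(mean(d2$y[d2$a == a & d2$b == b]))
  }
  pred00 <- fs$tidy$estimate[1]
  expect_equal(pred00, cell_logit(0, 0), tolerance = 1e-8)
  expect_equal(sum(fs$tidy$estimate), cell_logit(1, 1), tolerance = 1e-8)
  # separation raises an informative error
  ds <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                   y = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_logistic(y ~ x, ds), "separation")
  expect_error(fit_logistic(y ~ x, data.frame(x = 1:5, y = rep(1, 5))),
               "single class")
})

test_that("null logistic slopes are covered at the nominal rate", {
  set.seed(31)
  cover <- 0L
  for (r in 1:40) {
    d <- data.frame(x = rnorm(300))
    d$y <- rbinom(300, 1, 0.3)
    fit <- fit_logistic(y ~ x, d)
    row <- fit$tidy[2, ]
    if (row$ci_lo <= 0 && 0 <= row$ci_hi) cover <- cover + 1L
  }
  expect_gte(cover, 33L)  # >= 90% of replicates, with binomial slack
})

test_that("interaction fits recover a built-in product effect", {
  set.seed(41)
  n <- 1500
  d <- data.frame(prs_z = rnorm(n), diet = rbinom(n, 1, 0.3))
  d$fpg <- 4.4 + 0.08 * d$prs_z + 0.1 * d$diet +
    0.141 * d$prs_z * d$diet + rnorm(n, 0, 0.45)
  fit <- fit_interaction("fpg", "prs_z", "diet", data = d,
                         family = "linear")
  expect_equal(nrow(fit$interaction), 1L)
  expect_lt(abs(fit$interaction$estimate - 0.141),
            2 * fit$interaction$se)
  # null interaction p-values are approximately uniform
  set.seed(42)
  ps <- replicate(60, {
    d0 <- data.frame(x = rnorm(300), m = rbinom(300, 1, 0.5))
    d0$y <- 0.2 * d0$x + 0.1 * d0$m + rnorm(300)
    fit_interaction("y", "x", "m", data = d0,
                    family = "linear")$interaction$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # centering the inputs reduces design collinearity
  set.seed(43)
  x <- rnorm(200, 5); m <- rnorm(200, 3)
  raw <- cbind(1, x, m, x * m)
  cen <- cbind(1, scale(x, scale = FALSE), scale(m, scale = FALSE),
               scale(x, scale = FALSE) * scale(m, scale = FALSE))
  expect_lt(kappa(crossprod(cen)), kappa(crossprod(raw)))
})

test_that("stratified predictions follow the link and the interaction", {
  set.seed(51)
  n <- 3000
  d <- data.frame(prs_z = rnorm(n),
                  bmi_grp = sample(1:3, n, replace = TRUE))
  # negative PRS-by-BMI-group interaction on the log-odds scale
  d$gdm <- rbinom(n, 1, plogis(-1.5 + 0.8 * d$prs_z + 0.1 * d$bmi_grp -
                                 0.25 * d$prs_z * d$bmi_grp))
  fit <- fit_interaction("gdm", "prs_z", "bmi_grp", data = d,
                         family = "logistic")
  pr <- stratified_predictions(fit, d, "prs_z", "bmi_grp",
                               grid = seq(-1.5, 1.5, length.out = 11))
  expect_true(all(pr$fit >= pr$lo & pr$fit <= pr$hi))
  expect_true(all(pr$fit > 0 & pr$fit < 1))
  # slope over the PRS grid is flatter in the top stratum
  slope <- function(s) {
    sub <- pr[pr$stratum == s, ]
    diff(range(qlogis(sub$fit))) * sign(sub$fit[11] - sub$fit[1])
  }
  expect_lt(slope(3), slope(1))
  # prediction at covariate means equals expit of the linear predictor
  dlin <- data.frame(x = rnorm(500), s = rep(1, 500))
  dlin$y <- rbinom(500, 1, plogis(0.5 * dlin$x))
  flin <- fit_logistic(y ~ x, dlin)
  p0 <- stratified_predictions(flin, dlin, "x", "s",
                               grid = mean(dlin$x))
  eta <- sum(coef(flin$fit) * c(1, mean(dlin$x)))
  expect_equal(p0$fit, plogis(eta), tolerance = 1e-10)
  # bands widen toward the grid edges for a single-predictor model
  dband <- data.frame(x = rnorm(400), s = rep(1, 400))
  dband$y <- 1 + 0.5 * dband$x + rnorm(400)
  fb <- fit_linear(y ~ x, dband)
  gg <- seq(quantile(dband$x, 0.05), quantile(dband$x, 0.95),
            length.out = 21)
  pb <- stratified_predictions(fb, dband, "x", "s", grid = gg)
  widths <- pb$hi - pb$lo
  expect_lt(widths[11], widths[1])
  expect_lt(widths[11], widths[21])
  expect_warning(
    stratified_predictions(fb, dband, "x", "s",
                           grid = max(dband$x) + 1),
    "extrapolat")
})
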