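test_that("homogeneous fit reproduces ordinary least squares exactly", {
  set.seed(21)
  d <- simulate_region_data(10, means = c(0, 1, 2, 0, -1), sds = rep(1.5, 5),
                            beta_x = 0.7)
  f <- fit_gls(d, y ~ region + x, variance = "homogeneous")
  ols <- stats::lm(y ~ region + x, data = d)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-12)
  expect_equal(unname(f$se), unname(sqrt(diag(stats::vcov(ols)))), tolerance = 1e-12)
})

test_that("per-group fit collapses to OLS when group variances are exactly equal", {
  # symmetric residuals per group force identical REML variance estimates,
  # so the weighted and unweighted fits coincide exactly
  d <- tibble::tibble(
    region = rep(c("A", "B", "C"), each = 4),
    y = c(0, 2, 0, 2, 10, 12, 10, 12, -5, -3, -5, -3)
  )
  f_het <- fit_gls(d, y ~ region, variance = "per_group")
  f_hom <- fit_gls(d, y ~ region, variance = "homogeneous")
  expect_equal(f_het$coefficients, f_hom$coefficients, tolerance = 1e-12)
  expect_equal(unname(f_het$sigma2), rep(unname(f_hom$sigma2), 3), tolerance = 1e-12)
  expect_equal(f_het$logLik_reml, f_hom$logLik_reml, tolerance = 1e-10)
  cmp <- compare_variance_models(f_hom, f_het)
  expect_equal(cmp$lr_stat, 0, tolerance = 1e-10)
  expect_equal(cmp$delta_aic, 2 * (3 - 1), tolerance = 1e-8)
})

test_that("single-region per-group fit is the homogeneous fit", {
  set.seed(22)
  d <- simulate_region_data(20, means = 1, sds = 2, regions = "OnlyOne")
  f1 <- fit_gls(d, y ~ region, variance = "per_group")
  f2 <- fit_gls(d, y ~ region, variance = "homogeneous")
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(unname(f1$sigma2), unname(f2$sigma2))
})

test_that("per-group REML matches the reference varIdent implementation", {
  set.seed(23)
  d <- simulate_region_data(30, means = c(2, 2.5, 3, 1.5, 2.2),
                            sds = c(1, 1, 2, 2, 4), beta_x = 0.8)
  f <- fit_gls(d, y ~ region + x, variance = "per_group")
  ref <- nlme::gls(y ~ region + x, data = d,
                   weights = nlme::varIdent(form = ~1 | region), method = "REML")
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(f$logLik_reml, as.numeric(stats::logLik(ref)), tolerance = 1e-7)
  expect_equal(f$aic, stats::AIC(ref), tolerance = 1e-5)
  s2_ref <- (coef(ref$modelStruct$varStruct, unconstrained = FALSE,
                  allCoef = TRUE) * ref$sigma)^2
  expect_equal(unname(f$sigma2), unname(s2_ref[names(f$sigma2)]), tolerance = 1e-3)
})

test_that("REML log-likelihood trace is monotone within tolerance", {
  set.seed(24)
  for (i in 1:10) {
    d <- simulate_region_data(15, means = stats::rnorm(5), sds = c(1, 1, 2, 2, 4))
    f <- fit_gls(d, y ~ region, variance = "per_group")
    expect_true(all(diff(f$trace) >= -1e-6))
    expect_true(f$converged)
  }
})

test_that("parameter recovery: variances within 15%, 2-SE intervals behave nominally", {
  set.seed(25)
  means <- c(1, 2, 0.5, -1, 3)
  z <- numeric(0)
  s2 <- matrix(NA_real_, 20, 5)
  for (rep_i in 1:20) {
    d <- simulate_region_data(200, means = means, sds = c(1, 1, 2, 2, 4))
    f <- fit_gls(d, y ~ region, variance = "per_group")
    s2[rep_i, ] <- unname(f$sigma2)
    lsm <- ls_means(f)
    z <- c(z, (lsm$estimate - means) / lsm$se)
  }
  expect_equal(colMeans(s2), c(1, 1, 4, 4, 16), tolerance = 0.15)
  # ~95% of 2-SE intervals should cover the truth
  expect_gte(mean(abs(z) <= 2), 0.90)
  expect_lt(max(abs(z)), 4) # no estimator pathology
})

test_that("model comparison prefers heterogeneity when it is strong", {
  set.seed(26)
  d <- simulate_region_data(40, means = rep(0, 5), sds = c(1, 1, 1, 1, 4))
  f_het <- fit_gls(d, y ~ region, variance = "per_group")
  f_hom <- fit_gls(d, y ~ region, variance = "homogeneous")
  cmp <- compare_variance_models(f_hom, f_het)
  expect_lt(cmp$delta_aic, 0)
  expect_equal(cmp$df, 4)
  expect_lt(cmp$p_value, 0.01)
  d2 <- simulate_region_data(10, means = 0, sds = 1, regions = "One")
  f_single <- fit_gls(d2, y ~ region, variance = "per_group")
  expect_error(compare_variance_models(f_single, f_single),
               class = "cropdivr_validation_error")
})

test_that("per-group fits require 2 observations per group", {
  d <- tibble::tibble(region = c("A", "A", "B"), y = c(1, 2, 3))
  expect_error(fit_gls(d, y ~ region, variance = "per_group"),
               class = "cropdivr_validation_error")
})

test_that("ls-means equal raw group means without covariates and recover effects", {
  set.seed(27)
  d <- simulate_region_data(12, means = c(0, 1, 2, 3, 4), sds = c(1, 1, 2, 2, 4))
  f <- fit_gls(d, y ~ region, variance = "per_group")
  lsm <- ls_means(f)
  raw <- tapply(d$y, d$region, mean)[lsm$level]
  expect_equal(lsm$estimate, as.numeric(raw), tolerance = 1e-10)
  # unbalanced design with a covariate: truth recovered within 2 SE
  set.seed(28)
  reg <- rep(c("A", "B", "C"), times = c(30, 60, 90))
  x <- stats::rnorm(length(reg))
  mu <- c(A = 0, B = 2, C = -1)
  y <- mu[reg] + 1.5 * x + stats::rnorm(length(reg), 0, c(A = 1, B = 2, C = 1)[reg])
  f2 <- fit_gls(tibble::tibble(region = reg, x = x, y = y), y ~ region + x)
  lsm2 <- ls_means(f2)
  # adjusted means evaluated at the grand mean of x
  truth <- mu[lsm2$level] + 1.5 * mean(x)
  expect_true(all(abs(lsm2$estimate - truth) <= 2 * lsm2$se))
})

test_that("two-level Tukey reduces to the Welch t-test", {
  set.seed(29)
  d <- simulate_region_data(20, means = c(0, 1), sds = c(1, 3),
                            regions = c("A", "B"))
  f <- fit_gls(d, y ~ region, variance = "per_group")
  tk <- tukey_contrasts(f)
  expect_equal(tk$contrasts$p_adjusted, tk$contrasts$p_unadjusted, tolerance = 1e-9)
  welch <- stats::t.test(y ~ region, data = d)
  expect_equal(tk$contrasts$p_adjusted, welch$p.value, tolerance = 1e-6)
  expect_equal(tk$contrasts$df, unname(welch$parameter), tolerance = 1e-6)
})

test_that("Tukey adjustment never decreases a p-value; letters track separation", {
  set.seed(30)
  d_null <- simulate_region_data(60, means = rep(1, 5), sds = c(1, 1, 2, 2, 4))
  f_null <- fit_gls(d_null, y ~ region, variance = "per_group")
  tk_null <- tukey_contrasts(f_null)
  expect_true(all(tk_null$contrasts$p_adjusted >=
                    tk_null$contrasts$p_unadjusted - 1e-12))
  expect_true(all(tk_null$contrasts$p_adjusted > 0.2))
  expect_equal(length(unique(tk_null$letters$letters)), 1) # one shared letter

  # one group shifted far away gets its own letter
  set.seed(31)
  d_sep <- simulate_region_data(25, means = c(0, 0, 0, 0, 5), sds = rep(1, 5))
  f_sep <- fit_gls(d_sep, y ~ region, variance = "per_group")
  tk_sep <- tukey_contrasts(f_sep)
  lets <- tk_sep$letters
  out_letter <- lets$letters[lets$level == "Oceania"]
  expect_false(out_letter %in% lets$letters[lets$level != "Oceania"])
})

test_that("letter display is consistent with the adjusted significance matrix", {
  set.seed(32)
  for (i in 1:5) {
    d <- simulate_region_data(20, means = stats::rnorm(5, sd = 1.5),
                              sds = c(1, 1, 2, 2, 4))
    f <- fit_gls(d, y ~ region, variance = "per_group")
    tk <- tukey_contrasts(f, alpha = 0.05)
    lets <- setNames(strsplit(tk$letters$letters, ""), tk$letters$level)
    for (j in seq_len(nrow(tk$contrasts))) {
      shared <- length(intersect(lets[[tk$contrasts$level_1[j]]],
                                 lets[[tk$contrasts$level_2[j]]])) > 0
      if (tk$contrasts$p_adjusted[j] < 0.05) {
        expect_false(shared)
      } else {
        expect_true(shared)
      }
    }
  }
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(33)
  d <- simulate_region_data(10, means = c(0, 1, 2, 0, 1), sds = rep(1, 5))
  f <- fit_gls(d, y ~ region, variance = "per_group")
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 5)
  gl <- glance(f)
  expect_equal(gl$nobs, 50)
  expect_true(gl$converged)
})
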