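test_that("Kaplan-Meier estimate matches closed forms and the product oracle", {
  # single censored subject: survival stays 1 (no event rows at all)
  k0 <- km_estimate(10, 0)
  expect_equal(nrow(k0), 0)
  expect_equal(km_survival_at(k0, c(1, 100)), c(1, 1))
  # all events, no ties
  k1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k1$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(k1$at_risk, c(3, 2, 1))
  # random censored cohort against the brute-force product
  set.seed(15)
  for (rep in 1:5) {
    t <- rexp(40, 0.05); e <- rbinom(40, 1, 0.6)
    if (!any(e == 1)) next
    k <- km_estimate(t, e)
    expect_equal(k$survival, oracle_km(t, e), tolerance = 1e-12)
  }
  # no censoring: equals the empirical survival function
  t2 <- c(5, 1, 3, 3, 8)
  k2 <- km_estimate(t2, rep(1, 5))
  expect_equal(km_survival_at(k2, sort(unique(t2))),
               sapply(sort(unique(t2)), function(u) mean(t2 > u)))
  expect_error(km_estimate(numeric(0), numeric(0)))
})

test_that("survival lookups are right-continuous and monotone", {
  k <- km_estimate(c(2, 4, 6), c(1, 1, 0))
  expect_equal(km_survival_at(k, 2), 2 / 3)      # right-continuous at jump
  expect_equal(km_survival_at(k, 1.999), 1)
  grid <- km_survival_at(k, seq(0, 10, by = 0.5))
  expect_true(all(diff(grid) <= 0))
})

test_that("log-rank test matches the risk-set enumeration oracle", {
  # identical groups: statistic 0
  t <- c(1, 2, 3, 4); e <- c(1, 1, 0, 1)
  same <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  # 6-subject example against the hand enumeration
  t6 <- c(1, 3, 4, 5, 8, 9); e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- c("a", "a", "a", "b", "b", "b")
  got <- logrank_test(t6, e6, g6)
  want <- oracle_logrank(t6, e6, g6)
  expect_equal(got$chi_square, want$chi_square, tolerance = 1e-9)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
  # random instances
  set.seed(33)
  for (rep in 1:5) {
    t <- rexp(30, 0.1); e <- rbinom(30, 1, 0.7)
    g <- rep(c("x", "y"), 15)
    if (sum(e) == 0) next
    expect_equal(logrank_test(t, e, g)$chi_square,
                 oracle_logrank(t, e, g)$chi_square, tolerance = 1e-9)
  }
  expect_error(logrank_test(t6, e6, rep("a", 6)), "2 non-empty")
})

test_that("doubled hazard in the high-GRS group is detected with power", {
  set.seed(55)
  hits <- replicate(20, {
    n <- 1000
    grp <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.02 * 2^grp)
    cens <- runif(n, 10, 120)
    e <- as.integer(t <= cens)
    logrank_test(pmin(t, cens), e, grp)$p_value < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Cox coefficient matches grid-search partial-likelihood maximization", {
  # 8 subjects, two groups, no ties
  t <- c(2, 5, 7, 10, 3, 6, 11, 14)
  e <- c(1, 1, 1, 0, 1, 1, 1, 1)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit <- cox_fit(data.frame(x = x), t, e, ties_method = "breslow")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), x = x, times = t,
               events = e)
  beta_grid <- grid[which.max(ll)]
  expect_equal(fit$coefficients$coef, beta_grid, tolerance = 1e-4)
  # Efron and Breslow agree exactly without tied event times
  fit_e <- cox_fit(data.frame(x = x), t, e, ties_method = "efron")
  expect_equal(fit_e$coefficients$coef, fit$coefficients$coef,
               tolerance = 1e-9)
})

test_that("log-rank statistic equals the Cox score test for a binary covariate", {
  set.seed(65)
  t <- rexp(60, 0.05); e <- rbinom(60, 1, 0.8)
  x <- rep(0:1, 30)
  lr <- logrank_test(t, e, x)
  cx <- cox_fit(data.frame(x = x), t, e, ties_method = "breslow")
  expect_equal(lr$chi_square, cx$score_test, tolerance = 1e-6)
})

test_that("Cox fit recovers a generating hazard ratio and is null-calibrated", {
  set.seed(75)
  n <- 2000
  x <- rnorm(n)
  t <- rexp(n, 0.02 * exp(log(1.630) * x))
  cens <- runif(n, 5, 100)
  e <- as.integer(t <= cens)
  fit <- cox_fit(data.frame(x = pmin(t, cens) * 0 + x), pmin(t, cens), e)
  co <- fit$coefficients
  expect_lt(abs(co$coef - log(1.630)), 3 * co$se)
  # independent covariate: HR near 1, CI covers 1
  z <- rnorm(n)
  fit0 <- cox_fit(data.frame(z = z), pmin(t, cens), e)
  expect_true(fit0$coefficients$ci_low < 1 && 1 < fit0$coefficients$ci_high)
  # degenerate inputs
  expect_error(cox_fit(data.frame(c = rep(1, 10)), rexp(10), rep(1, 10)),
               "constant")
  expect_error(cox_fit(data.frame(a = x, b = 2 * x), pmin(t, cens), e),
               "collinear")
})

test_that("clinical and clinico-genetic Cox models fit the simulated cohort", {
  co <- simulate_cohort(simulation_config(seed = 19))
  panel <- bcr_snp_panel()
  model <- build_model(data.frame(variant_id = panel$variant_id,
                                  effect_allele = panel$effect_allele,
                                  or_estimate = panel$or_published))
  sc <- score_samples(co$genotypes, model)
  fits <- fit_paper_models(co$phenotypes, sc)
  expect_equal(fits$clinical$coefficients$term,
               c("age", "psa", "gleason", "ece", "svi", "psm"))
  expect_equal(fits$clinico_genetic$coefficients$term,
               c("age", "psa", "gleason", "ece", "svi", "psm", "grs"))
  expect_equal(fits$clinical$n, fits$clinico_genetic$n)
  grs_row <- fits$clinico_genetic$coefficients[
    fits$clinico_genetic$coefficients$term == "grs", ]
  expect_gt(grs_row$hr, 1)          # simulated GRS hazard is positive
  expect_gt(grs_row$ci_low, 1)
  # null GRS effect: CI covers 1
  cfg0 <- simulation_config(seed = 19, grs_log_hazard = 0,
                            clinical_log_odds = c(age = 0),
                            clinical_log_hazard = c(age = 0))
  co0 <- simulate_cohort(cfg0)
  sc0 <- score_samples(co0$genotypes, model)
  # break the genotype-outcome link: scores permuted
  sc0$grs <- sample(sc0$grs)
  fits0 <- fit_paper_models(co0$phenotypes, sc0)
  g0 <- fits0$clinico_genetic$coefficients[
    fits0$clinico_genetic$coefficients$term == "grs", ]
  expect_true(g0$ci_low < 1 && 1 < g0$ci_high)
})
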