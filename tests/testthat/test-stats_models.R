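test_that("one-sample t against chance matches the closed form", {
  expect_error(one_sample_t_vs_chance(rep(25, 30)), "zero variance")

  r <- one_sample_t_vs_chance(c(35, 15, 35, 15))
  expect_equal(r$statistic, 0)
  expect_equal(r$d, 0)

  # seeded vectors against stats::t.test and the textbook formula
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = 40, sd = 20)
    r <- one_sample_t_vs_chance(x)
    ref <- t.test(x, mu = 25)
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    expect_equal(r$statistic, (mean(x) - 25) / (sd(x) / sqrt(length(x))),
                 tolerance = 1e-12)
    expect_equal(r$d, (mean(x) - 25) / sd(x), tolerance = 1e-12)
    # the d interval inverts the noncentral t at 2.5% in each tail
    n <- length(x)
    expect_equal(suppressWarnings(pt(r$statistic, n - 1,
                                     ncp = r$d_ci[1] * sqrt(n))), 0.975,
                 tolerance = 1e-8)
    expect_equal(suppressWarnings(pt(r$statistic, n - 1,
                                     ncp = r$d_ci[2] * sqrt(n))), 0.025,
                 tolerance = 1e-8)
    expect_true(r$d_ci[1] <= r$d && r$d <= r$d_ci[2])
  }
})

test_that("a sample at M = 53.75, SD = 24.82, n = 30 gives t = 6.34 vs 25%", {
  # construct a vector with those exact moments
  base <- scale(rnorm(30))  # mean 0, sd 1 exactly
  x <- as.numeric(base) * 24.82 + 53.75
  r <- one_sample_t_vs_chance(x, chance = 25)
  expect_equal(round(r$statistic, 2), 6.34)
  expect_equal(round(r$d, 2), 1.16)
  # against 0 the same sample gives the much larger statistic
  r0 <- one_sample_t_vs_chance(x, chance = 0)
  expect_equal(round(r0$statistic, 2), 11.86)
  expect_equal(round(r0$d, 2), 2.17)
})

test_that("paired t matches the direct formula and guards degeneracy", {
  a <- c(1, 2, 3, 4)
  expect_equal(paired_t(a, a + c(0.5, -0.5, 0.5, -0.5))$statistic, 0)
  expect_error(paired_t(a, a), "zero variance of differences")
  expect_error(paired_t(a, a + 2), "zero variance of differences")
  expect_error(paired_t(a, a[1:3]), "unequal lengths")

  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    r <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    expect_equal(r$d_diff, mean(x - y) / sd(x - y), tolerance = 1e-12)
    expect_equal(r$d_pooled,
                 mean(x - y) / sqrt((var(x) + var(y)) / 2),
                 tolerance = 1e-12)
  }
})

test_that("success GLMM with no pair heterogeneity matches plain logistic", {
  set.seed(43)
  n <- 400
  rows <- data.frame(pair = rep(sprintf("P%02d", 1:20), each = n / 20),
                     prop_correct_showing = runif(n))
  rows$success <- runif(n) < plogis(-2 + 5 * rows$prop_correct_showing)
  fit <- fit_success_glmm(rows, success ~ prop_correct_showing)
  glm_ref <- glm(success ~ prop_correct_showing, data = rows,
                 family = binomial())
  # random-intercept variance collapses to ~0, estimates equal plain ML
  expect_lt(fit$random$pair_intercept_var, 1e-4)
  expect_equal(fit$coefficients$estimate, unname(coef(glm_ref)),
               tolerance = 1e-5)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$logLik, tolerance = 1e-10)
})

test_that("GLMM rejects singular designs and centers on logit of the rate", {
  rows <- data.frame(pair = rep(c("A", "B"), 50),
                     prop_correct_showing = 0.4,
                     success = rep(c(TRUE, FALSE), 50))
  expect_error(fit_success_glmm(rows, success ~ prop_correct_showing),
               "singular")

  set.seed(44)
  n <- 480
  rows <- data.frame(pair = rep(sprintf("P%02d", 1:30), each = 16),
                     success = rep(c(TRUE, FALSE), n / 2))
  null_fit <- fit_success_glmm(rows, success ~ 1)
  expect_lt(abs(null_fit$coefficients$estimate[1]), 0.1)
})

test_that("effort LMM recovers a within-pair effect with plausible Satterthwaite df", {
  set.seed(45)
  sim <- simulate_observation_rows(sim_config(n_pairs = 30),
                                   effort_beta_phase = -0.05)
  fit <- fit_effort_lmm(sim$rows, effort ~ phase_s1 + phase_s2)
  co <- fit$coefficients
  expect_true(all(is.finite(co$df)))
  # phase dummies are within-pair contrasts: df near the residual dimension
  n <- fit$nobs; J <- 30
  expect_gt(min(co$df[-1]), 0.75 * (n - J))
  expect_lte(max(co$df), n - nrow(co))
  expect_error(fit_effort_lmm(transform(sim$rows, effort = 0.5),
                              effort ~ phase_s1 + phase_s2),
               "zero-variance response")
})

test_that("REML log-likelihood is at an optimum of the criterion", {
  set.seed(46)
  sim <- simulate_observation_rows(sim_config(n_pairs = 12))
  fit <- fit_effort_lmm(sim$rows, effort ~ phase_s1 + phase_s2)
  m <- fit$model
  y <- lme4::getME(m, "y"); X <- lme4::getME(m, "X")
  groups <- split(seq_along(y), lme4::getME(m, "flist")[[1]])
  tau2 <- fit$random$pair_intercept_var
  sig2 <- fit$random$residual_sd^2
  at <- function(t2, s2) canishow:::.ri_crit(y, X, groups, t2, s2)$m2l
  base <- at(tau2, sig2)
  for (f in c(0.7, 1.3)) {
    expect_gte(at(tau2 * f + 1e-6, sig2), base - 1e-8)
    expect_gte(at(tau2, sig2 * f), base - 1e-8)
  }
})

test_that("AIC selection picks the minimum with first-on-tie and valid LRT", {
  set.seed(47)
  sim <- simulate_observation_rows(sim_config(n_pairs = 15))
  f0 <- fit_effort_lmm(sim$rows, effort ~ 1, REML = FALSE)
  f1 <- fit_effort_lmm(sim$rows, effort ~ phase_s1 + phase_s2, REML = FALSE)
  cmp <- select_model_aic(list(null = f0, phase = f1),
                          nested = list(c("null", "phase")))
  expect_equal(cmp$selected,
               cmp$table$model[which.min(cmp$table$AIC)])
  expect_equal(cmp$lrt$chisq, 2 * (f1$logLik - f0$logLik))
  expect_equal(cmp$lrt$df, f1$k - f0$k)
  # AIC arithmetic and tie rule
  expect_equal(f0$AIC, 2 * f0$k - 2 * f0$logLik)
  tie <- select_model_aic(list(first = f0, second = f0))
  expect_equal(tie$selected, "first")
  # differing row sets are not comparable
  sim2 <- simulate_observation_rows(sim_config(n_pairs = 14))
  f2 <- fit_effort_lmm(sim2$rows, effort ~ 1, REML = FALSE)
  expect_error(select_model_aic(list(a = f0, b = f2)), "not comparable")
})

test_that("accuracy-time correlation matches the direct formula", {
  r <- accuracy_time_correlation(c(0, 1, 1), c(0, 10, 10))
  expect_equal(r$r, 1.0)

  flat <- accuracy_time_correlation(c(1, 1, 1, 1), 1:4)
  expect_false(flat$defined)
  expect_true(is.na(flat$r))

  set.seed(48)
  for (i in 1:10) {
    n <- sample(10:500, 1)
    acc <- rbinom(n, 1, 0.4)
    sec <- runif(n, 0, 120)
    if (sd(acc) == 0) next
    r <- accuracy_time_correlation(acc, sec)
    rr <- cor(acc, sec)
    expect_equal(r$r, rr, tolerance = 1e-12)
    expect_equal(r$statistic, rr * sqrt((n - 2) / (1 - rr^2)),
                 tolerance = 1e-12)
    ref <- cor.test(acc, sec)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
    expect_equal(r$ci, as.numeric(ref$conf.int), tolerance = 1e-10)
  }
})

test_that("per-type condition comparison is a paired t over matched cells", {
  set.seed(49)
  cells <- expand.grid(pair = sprintf("P%02d", 1:10), trial = 1:4,
                       phase = 1:2, condition = c("close", "far"),
                       stringsAsFactors = FALSE)
  for (k in 1:15) cells[[paste0("n_type_", k)]] <- rpois(nrow(cells), 3)
  cells$n_type_15 <- 0L  # a type that never occurs
  cmp <- compare_type_frequencies(cells)
  expect_equal(nrow(cmp), 15L)
  expect_false(cmp$defined[15])
  far <- cells[cells$condition == "far", ]
  close <- cells[cells$condition == "close", ]
  close <- close[match(paste(far$pair, far$trial, far$phase),
                       paste(close$pair, close$trial, close$phase)), ]
  ref <- t.test(far$n_type_1, close$n_type_1, paired = TRUE)
  expect_equal(cmp$t[1], unname(ref$statistic), tolerance = 1e-12)
})
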