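test_that("outlier removal is strict at 3 SD and leaves ties alone", {
  v <- c(rnorm(50), 100)
  out <- remove_outliers(v)
  expect_true(is.na(out[51]))
  expect_equal(sum(is.na(out)), 1)
  expect_equal(remove_outliers(rep(2, 10)), rep(2, 10))
  # borderline exactly at 3 SD is retained (strict >)
  z <- c(-1, -1, 1, 1)
  z <- z / sd(z) * 3
  expect_false(anyNA(remove_outliers(c(z, 0))))
})

test_that("logistic group test agrees with glm and recovers injected effects", {
  set.seed(81)
  n <- 100
  x <- rnorm(n); age <- rnorm(n, 33, 7); sexn <- rbinom(n, 1, 0.4) + 1
  y <- rbinom(n, 1, plogis(0.4 * x))
  X <- cbind(1, x, age, sexn)
  co <- sleepmicro:::cpp_logit_fit(X, y)
  g <- glm(y ~ x + age + sexn, binomial())
  expect_equal(as.numeric(co$coef), unname(coef(g)), tolerance = 1e-8)
  expect_equal(as.numeric(co$p), unname(summary(g)$coefficients[, 4]),
               tolerance = 1e-6)
  cs <- cohort_spec(60, 60, effect_sizes = c(m = 1), seed = 82)
  sim <- simulate_cohort_metrics(cs)
  r <- group_diff_logistic(sim$metrics$m[, 1], sim$covariates$group,
                           sim$covariates$age, sim$covariates$sex)
  expect_equal(r$effect_size, 1, tolerance = 0.25)
  expect_lt(r$p, 0.01)
  expect_error(group_diff_logistic(rep(1, 120), sim$covariates$group,
                                   sim$covariates$age, sim$covariates$sex),
               "constant")
})

test_that("null p-values are calibrated and age-only differences do not inflate them", {
  set.seed(83)
  rej <- rej_age <- logical(200)
  for (i in 1:200) {
    cs <- cohort_spec(50, 50, effect_sizes = c(m = 0), seed = 2000 + i)
    sim <- simulate_cohort_metrics(cs, age_slopes = c(m = 0.5))
    r <- group_diff_logistic(sim$metrics$m[, 1], sim$covariates$group,
                             sim$covariates$age, sim$covariates$sex)
    rej_age[i] <- r$p < 0.05
  }
  # groups differ in age and the metric tracks age; adjustment keeps the
  # metric rejection rate near nominal
  expect_lt(mean(rej_age), 0.11)
  expect_gt(mean(rej_age), 0.005)
})

test_that("permutation adjustment collapses to the single-channel case and is monotone", {
  cs <- cohort_spec(40, 40, effect_sizes = c(m = 0.8), seed = 84)
  sim <- simulate_cohort_metrics(cs, n_channels = 5)
  pa <- permutation_adjust(sim$metrics$m, sim$covariates$group,
                           sim$covariates$age, sim$covariates$sex,
                           R = 500, seed = 85)
  # adjusted p ordering follows asymptotic p ordering
  expect_true(all(diff(pa$adj_p[order(pa$p)]) >= 0))
  expect_true(all(pa$adj_p >= 1 / 501 & pa$adj_p <= 1))
  # single channel: adjusted p ~ its own permutation p
  pa1 <- permutation_adjust(sim$metrics$m[, 1, drop = FALSE],
                            sim$covariates$group, sim$covariates$age,
                            sim$covariates$sex, R = 500, seed = 86)
  emp <- (sum(pa1$min_p <= pa1$p[1]) + 1) / 501
  expect_equal(pa1$adj_p[1], emp)
  expect_warning(permutation_adjust(sim$metrics$m, sim$covariates$group,
                                    sim$covariates$age, sim$covariates$sex,
                                    R = 50, seed = 87), "100")
})

test_that("duplicated channels barely change the min-p adjustment", {
  cs <- cohort_spec(50, 50, effect_sizes = c(m = 0.7), seed = 88)
  sim <- simulate_cohort_metrics(cs, n_channels = 1)
  v <- sim$metrics$m[, 1]
  dup <- matrix(rep(v, 57), ncol = 57)
  pa_dup <- permutation_adjust(dup, sim$covariates$group,
                               sim$covariates$age, sim$covariates$sex,
                               R = 500, seed = 89)
  pa_one <- permutation_adjust(cbind(v), sim$covariates$group,
                               sim$covariates$age, sim$covariates$sex,
                               R = 500, seed = 89)
  # perfectly correlated copies: the max-statistic sees one effective test
  expect_equal(pa_dup$adj_p[1], pa_one$adj_p[1], tolerance = 0.02)
})

test_that("cross-metric and clinical associations behave on constructed data", {
  set.seed(90)
  n <- 80
  group <- factor(rep(c("control", "case"), each = n / 2),
                  levels = c("control", "case"))
  age <- rnorm(n, 33, 7); sex <- factor(rbinom(n, 1, 0.5), labels = c("M", "F"))
  a <- rnorm(n)
  self <- crossmetric_corr(a, a, group, age, sex)
  expect_equal(self$r, 1, tolerance = 1e-9)
  # a disorder-only shared effect vanishes after residualizing
  b <- 2 * (group == "case") + rnorm(n)
  c_ <- 2 * (group == "case") + rnorm(n)
  res <- crossmetric_corr(b, c_, group, age, sex)
  expect_lt(abs(res$r), 0.3)
  cl <- clinical_assoc(a, a, age, sex)
  expect_lt(cl$p, 1e-10)
  expect_error(clinical_assoc(a[1:3], a[1:3], age[1:3], sex[1:3]), "4")
})
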