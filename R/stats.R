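#' Remove 3-SD outliers from a metric vector
#'
#' Values more than `sd_thresh` SD from the (pooled-group) mean — strictly
#' greater — are set to NA; mean and SD are computed once on the input.
#'
#' @param values numeric vector (one metric, one channel).
#' @param sd_thresh SD threshold (default 3).
#' @return `values` with outliers replaced by NA.
#' @export
remove_outliers <- function(values, sd_thresh = 3) {
  ok <- is.finite(values)
  if (sum(ok) < 3) stop("need at least 3 finite values")
  mu <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (s == 0) return(values)
  values[ok][abs(values[ok] - mu) > sd_thresh * s] <- NA_real_
  values
}

#' Covariate-adjusted case/control test for one metric
#'
#' Logistic regression of group on metric + age + sex; the p-value is the
#' Wald test of the metric coefficient. The effect size is the
#' covariate-adjusted standardized mean difference: the metric is
#' residualized on age and sex by least squares, then Cohen's d of the
#' residuals (case minus control, pooled SD).
#'
#' @param metric numeric vector (NA allowed; complete cases used).
#' @param group factor with levels control, case (or coercible).
#' @param age numeric, years.
#' @param sex factor (M/F) or numeric.
#' @return list: p, effect_size, n, separation flag.
#' @export
group_diff_logistic <- function(metric, group, age, sex) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have two levels")
  df <- data.frame(y = as.integer(group == levels(group)[2]),
                   metric = metric, age = age,
                   sex = as.numeric(as.factor(sex)))
  df <- df[stats::complete.cases(df), ]
  if (min(table(df$y)) < 2) stop("each group needs at least 2 subjects")
  if (stats::sd(df$metric) == 0) stop("metric is constant")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ metric + age + sex, binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation || !fit$converged) {
    # ridge-stabilized fallback
    X <- stats::model.matrix(~ metric + age + sex, df)
    co <- cpp_logit_fit(X, df$y, ridge = 1e-2)
    p <- co$p[2]
  } else {
    p <- summary(fit)$coefficients["metric", 4]
  }
  res <- stats::resid(stats::lm(metric ~ age + sex, data = df))
  g <- df$y == 1
  n1 <- sum(g); n0 <- sum(!g)
  sp <- sqrt(((n1 - 1) * stats::var(res[g]) + (n0 - 1) * stats::var(res[!g])) /
               (n1 + n0 - 2))
  d <- if (sp > 0) (mean(res[g]) - mean(res[!g])) / sp else NA_real_
  list(p = p, effect_size = d, n = nrow(df), separation = separation)
}

#' Min-p permutation adjustment across channels
#'
#' For one metric measured on many channels, observed Wald p-values (from
#' the logistic group model) are compared with the null distribution of
#' the minimum p across channels under random permutation of group labels
#' (age and sex stay with the individual). The adjusted p for channel C is
#' `(R_C + 1) / (R + 1)` with `R_C` the number of null min-p values at or
#' below the observed p; this controls the family-wise error rate while
#' respecting inter-channel correlation.
#'
#' @param values subject x channel matrix (NA = removed outlier).
#' @param group,age,sex covariates as in [group_diff_logistic()].
#' @param R permutation count (3000 in the full pipeline).
#' @param seed RNG seed (one permutation set shared by all channels).
#' @return list: p (observed, per channel), adj_p, min_p (null draws).
#' @export
permutation_adjust <- function(values, group, age, sex, R = 3000, seed = 1) {
  if (R < 100) warning("fewer than 100 permutations; adjusted p unstable")
  values <- as.matrix(values)
  group <- as.factor(group)
  y <- as.numeric(group == levels(group)[2])
  covar <- cbind(age = age, sex = as.numeric(as.factor(sex)))
  n <- length(y)
  perms <- with_seed(seed,
                     vapply(seq_len(R), function(r) sample.int(n), integer(n)))
  out <- cpp_perm_minp(values, y, covar, perms)
  obs <- as.numeric(out$obs_p)
  minp <- as.numeric(out$min_p)
  adj <- vapply(obs, function(p)
    if (is.na(p)) NA_real_ else (sum(minp <= p) + 1) / (R + 1), 0)
  list(p = obs, adj_p = adj, min_p = minp)
}

#' Residualized cross-metric correlation
#'
#' Pearson correlation between two metrics after regressing out disorder,
#' age and sex from each and removing 3-SD outliers of the residuals.
#'
#' @param metric_a,metric_b numeric vectors.
#' @param group,age,sex covariates.
#' @return list: r, p, n.
#' @export
crossmetric_corr <- function(metric_a, metric_b, group, age, sex) {
  df <- data.frame(a = metric_a, b = metric_b, group = as.factor(group),
                   age = age, sex = as.factor(sex))
  df <- df[stats::complete.cases(df), ]
  ra <- stats::resid(stats::lm(a ~ group + age + sex, data = df))
  rb <- stats::resid(stats::lm(b ~ group + age + sex, data = df))
  ra <- remove_outliers(ra)
  rb <- remove_outliers(rb)
  ok <- is.finite(ra) & is.finite(rb)
  ct <- stats::cor.test(ra[ok], rb[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Association between an EEG metric and a clinical variable
#'
#' Ordinary least squares: metric ~ clinical + age + sex (within one
#' group); reports the clinical slope and its t-test p-value.
#'
#' @param metric,clinical numeric vectors.
#' @param age,sex covariates.
#' @return list: coef, p, n.
#' @export
clinical_assoc <- function(metric, clinical, age, sex) {
  df <- data.frame(metric = metric, clinical = clinical, age = age,
                   sex = as.factor(sex))
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 4) stop("need at least 4 complete observations")
  fit <- stats::lm(metric ~ clinical + age + sex, data = df)
  sm <- summary(fit)$coefficients
  list(coef = sm["clinical", 1], p = sm["clinical", 4], n = nrow(df))
}
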