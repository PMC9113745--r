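#' Principal-spectral-component (SVD) model
#'
#' Columns of the subject x feature matrix are mean-centered and the
#' matrix decomposed as `A = U D V'`. Component scores are the columns of
#' `U`; variance explained per component is `d^2 / sum(d^2)`. Components
#' explaining at least `var_thresh` percent of total variance are marked
#' retained. Each component is oriented so its largest-magnitude loading
#' is positive (the decomposition leaves the sign free).
#'
#' @param A subject x feature numeric matrix (no NA).
#' @param var_thresh retention threshold, percent of total variance.
#' @return list of class `psc_model`: center, d (singular values), V
#'   (loadings), scores (U), variance_explained (percent), retained
#'   (logical), feature_names.
#' @export
psc_fit <- function(A, var_thresh = 1) {
  A <- as.matrix(A)
  if (nrow(A) < 3) stop("need at least 3 subjects")
  if (anyNA(A) || !all(is.finite(A))) stop("A must be finite (impute upstream)")
  center <- colMeans(A)
  Ac <- sweep(A, 2, center)
  sv <- svd(Ac)
  # orient: largest-|loading| positive
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  ve <- 100 * sv$d^2 / sum(sv$d^2)
  structure(list(center = center, d = sv$d, V = sv$v, scores = sv$u,
                 variance_explained = ve, retained = ve >= var_thresh,
                 feature_names = colnames(A)),
            class = "psc_model")
}

#' @export
print.psc_model <- function(x, ...) {
  cat(sprintf("<psc_model> %d features, %d components (%d retained >= 1%% var)\n",
              length(x$center), length(x$d), sum(x$retained)))
  invisible(x)
}

#' Project a new feature matrix onto fitted components
#'
#' Out-of-sample scores: `U_B = (B - center) V D^-1`, centering with the
#' TRAINING means so scores are on the training scale.
#'
#' @param B new subject x feature matrix (same features, same order).
#' @param model a [psc_fit()] model.
#' @return subject x component score matrix.
#' @export
psc_project <- function(B, model) {
  B <- as.matrix(B)
  if (ncol(B) != length(model$center))
    stop("feature count mismatch with training model")
  if (!is.null(model$feature_names) && !is.null(colnames(B)) &&
      !identical(colnames(B), model$feature_names))
    stop("feature names/order differ from training model")
  pos <- model$d > model$d[1] * 1e-12
  sc <- sweep(B, 2, model$center) %*% model$V[, pos, drop = FALSE] %*%
    diag(1 / model$d[pos], sum(pos))
  sc
}

#' Select group-associated components
#'
#' Keeps components that (1) explain at least the retention threshold of
#' variance and (2) show a group difference at `p_thresh` in a logistic
#' model with age and sex as covariates, after residualizing age and sex
#' from the scores.
#'
#' @param model a [psc_fit()] model.
#' @param group,age,sex cohort covariates (training subjects).
#' @param p_thresh nominal significance threshold (0.01 in the pipeline).
#' @return integer component indices.
#' @export
select_components <- function(model, group, age, sex, p_thresh = 0.01) {
  sel <- integer(0)
  for (k in which(model$retained)) {
    sc <- residualize_age_sex(model$scores[, k], age, sex)
    res <- group_diff_logistic(sc, group, age, sex)
    if (is.finite(res$p) && res$p < p_thresh) sel <- c(sel, k)
  }
  sel
}

#' Residualize a score on age and sex
#'
#' @param score numeric vector.
#' @param age,sex covariates.
#' @return residuals (same length).
#' @export
residualize_age_sex <- function(score, age, sex) {
  stats::resid(stats::lm(score ~ age + as.factor(sex)))
}

#' AUC by the rank (Mann-Whitney) statistic
#'
#' @param labels binary vector (1 = case).
#' @param scores predicted probabilities or scores.
#' @return area under the ROC curve.
#' @export
auc_rank <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Joint logistic classifier on component scores
#'
#' Multivariable logistic fit of case/control status on the selected
#' component scores; posterior case probabilities for the training set and
#' (optionally) an independently projected test set, with rank-statistic
#' AUCs.
#'
#' @param train_scores subject x component matrix (training).
#' @param labels binary/factor labels (training).
#' @param test_scores optional test matrix (same columns).
#' @param test_labels optional test labels (for test AUC).
#' @return list: coef, prob_train, auc_train, prob_test, auc_test,
#'   separation flag.
#' @export
joint_fit_predict <- function(train_scores, labels, test_scores = NULL,
                              test_labels = NULL) {
  train_scores <- as.matrix(train_scores)
  y <- if (is.factor(labels)) as.integer(labels == levels(labels)[2])
  else as.integer(labels)
  df <- data.frame(y = y, train_scores)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (separation) {
    # ridge-stabilized coefficients keep probabilities usable
    X <- cbind(1, train_scores)
    beta <- as.numeric(cpp_logit_fit(X, y, ridge = 1e-2)$coef)
    names(beta) <- names(stats::coef(fit))
  }
  lin <- function(S) as.numeric(cbind(1, as.matrix(S)) %*% beta)
  prob_train <- stats::plogis(lin(train_scores))
  out <- list(coef = beta, prob_train = prob_train,
              auc_train = auc_rank(y, prob_train), separation = separation)
  if (!is.null(test_scores)) {
    out$prob_test <- stats::plogis(lin(test_scores))
    if (!is.null(test_labels)) {
      yt <- if (is.factor(test_labels))
        as.integer(test_labels == levels(test_labels)[2])
      else as.integer(test_labels)
      out$auc_test <- auc_rank(yt, out$prob_test)
    }
  }
  out
}

#' Bootstrap optimism correction of AUC and Nagelkerke R^2
#'
#' Harrell's procedure: refit the logistic model on bootstrap resamples,
#' measure each refit's performance on its own resample and on the
#' original data, average the difference (optimism, floored at zero) and
#' subtract it from the apparent performance.
#'
#' @param scores subject x component matrix.
#' @param labels binary labels.
#' @param B bootstrap replicates (>= 100 recommended; error if < 1).
#' @param seed RNG seed.
#' @return list: auc_apparent, auc_corrected, r2_apparent, r2_corrected,
#'   optimism_auc, optimism_r2.
#' @export
bootstrap_optimism <- function(scores, labels, B = 200, seed = 1) {
  if (B < 1) stop("B must be at least 1")
  scores <- as.matrix(scores)
  y <- if (is.factor(labels)) as.integer(labels == levels(labels)[2])
  else as.integer(labels)
  n <- length(y)
  apparent <- joint_fit_predict(scores, y)
  auc_app <- apparent$auc_train
  r2_app <- nagelkerke_r2(y, apparent$prob_train)
  opt_auc <- opt_r2 <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
      }
      fb <- joint_fit_predict(scores[idx, , drop = FALSE], y[idx],
                              test_scores = scores, test_labels = y)
      opt_auc[b] <- fb$auc_train - fb$auc_test
      opt_r2[b] <- nagelkerke_r2(y[idx], fb$prob_train) -
        nagelkerke_r2(y, fb$prob_test)
    }
  })
  o_auc <- max(mean(opt_auc), 0)
  o_r2 <- max(mean(opt_r2), 0)
  list(auc_apparent = auc_app, auc_corrected = auc_app - o_auc,
       r2_apparent = r2_app, r2_corrected = r2_app - o_r2,
       optimism_auc = o_auc, optimism_r2 = o_r2)
}

#' Nagelkerke R^2 of predicted probabilities
#'
#' @param y binary outcomes.
#' @param prob predicted probabilities.
#' @return Nagelkerke pseudo-R^2.
#' @export
nagelkerke_r2 <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  n <- length(y)
  ll <- sum(y * log(prob) + (1 - y) * log(1 - prob))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  r2cs <- 1 - exp(2 * (ll0 - ll) / n)
  r2cs / (1 - exp(2 * ll0 / n))
}
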