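#' Configuration for repeated cross-validated ridge prediction
#'
#' Defaults follow the reference analysis design: ridge penalty 1, 100
#' repeats of 10-fold cross-validation, principal components retained when
#' they individually explain at least 1% of training-fold variance, and
#' age/sex nuisance regression of the target fitted on training folds only.
#' `n_permutations` defaults to a desk-scale 1,000 (the full design used
#' 100,000); raise it for final analyses.
#'
#' @param ridge_penalty ridge regularization strength (alpha).
#' @param n_repeats repeats of k-fold cross-validation.
#' @param k_folds folds per repeat.
#' @param pc_variance_threshold percent variance a component must explain
#'   to be retained, in (0, 100].
#' @param n_components_override fixed component count overriding the
#'   threshold (used to give raw-volume runs the same input dimensionality
#'   as deviation runs).
#' @param n_permutations permutations for the significance test.
#' @param nuisance_covariates cohort columns regressed out of the target
#'   (training-fold fit applied to test folds). Extend with e.g. `"t1_qa"`,
#'   `"t1_snr"` for sensitivity analyses.
#' @param seed base seed; repeat r uses `seed + r` for fold shuffling, so
#'   two feature kinds run with the same config share fold structure and
#'   their per-repeat scores are paired.
#' @return object of class `prediction_config`.
#' @export
prediction_config <- function(ridge_penalty = 1, n_repeats = 100,
                              k_folds = 10, pc_variance_threshold = 1,
                              n_components_override = NULL,
                              n_permutations = 1000,
                              nuisance_covariates = c("age", "sex"),
                              seed = 1) {
  stopifnot(ridge_penalty > 0, n_repeats >= 1, k_folds >= 2,
            n_permutations >= 1)
  if (pc_variance_threshold <= 0 || pc_variance_threshold > 100)
    stop("pc_variance_threshold must be in (0, 100]")
  structure(list(ridge_penalty = ridge_penalty, n_repeats = n_repeats,
                 k_folds = k_folds,
                 pc_variance_threshold = pc_variance_threshold,
                 n_components_override = n_components_override,
                 n_permutations = n_permutations,
                 nuisance_covariates = nuisance_covariates, seed = seed),
            class = "prediction_config")
}

#' Leakage-safe nuisance residualization of a target variable
#'
#' Fits ordinary least squares of y on the covariates using training rows
#' only and returns residuals for both training and test rows, so no test
#' information enters the nuisance fit.
#'
#' @param y_train,y_test numeric target vectors.
#' @param covars_train,covars_test covariate matrices with matching columns.
#' @return list with `train` and `test` residual vectors.
#' @export
nuisance_residualize <- function(y_train, y_test, covars_train, covars_test) {
  covars_train <- as.matrix(covars_train)
  covars_test <- as.matrix(covars_test)
  if (ncol(covars_train) != ncol(covars_test))
    stop("covariate matrices must have matching columns")
  X <- cbind(`(Intercept)` = 1, covars_train)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance covariates; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  b <- qr.coef(qx, y_train)
  list(train = y_train - drop(X %*% b),
       test = y_test - drop(cbind(1, covars_test) %*% b))
}

#' Train-fold PCA dimensionality reduction
#'
#' Principal components are estimated on (and centered by) the training
#' rows only; test rows are projected onto the training loadings.
#' Components individually explaining at least `threshold` percent of
#' training variance are retained, unless `n_override` fixes the count.
#'
#' @param train_features,test_features numeric matrices (same columns).
#' @param threshold percent explained-variance cutoff per component.
#' @param n_override optional fixed number of components.
#' @return list with `train`, `test` score matrices, `n_components`, and
#'   the `explained_variance` percentages.
#' @export
pca_reduce <- function(train_features, test_features, threshold = 1,
                       n_override = NULL) {
  p <- prcomp(train_features, center = TRUE, scale. = FALSE)
  ev <- 100 * p$sdev^2 / sum(p$sdev^2)
  ncomp <- if (!is.null(n_override)) as.integer(n_override)
           else sum(ev >= threshold)
  if (ncomp < 1)
    stop("no principal component explains >= ", threshold,
         "% variance; set n_override to fix a component count")
  ncomp <- min(ncomp, ncol(p$rotation))
  rot <- p$rotation[, seq_len(ncomp), drop = FALSE]
  test_c <- sweep(as.matrix(test_features), 2, p$center)
  list(train = p$x[, seq_len(ncomp), drop = FALSE],
       test = test_c %*% rot,
       n_components = ncomp,
       explained_variance = ev)
}

# Closed-form ridge with unpenalized intercept: center X and y on the
# training data, solve (X'X + alpha I) b = X'y.
ridge_fit <- function(X, y, alpha) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  b <- solve(crossprod(Xc) + diag(alpha, ncol(X)), crossprod(Xc, y - ym))
  list(coef = drop(b), intercept = ym - sum(xm * b), x_center = xm)
}

ridge_predict <- function(fit, X) {
  drop(X %*% fit$coef) + fit$intercept
}

# One full k-fold pass: residualize y within folds, PCA + ridge per fold,
# score, average over folds. Returns c(neg_rmse, neg_mae, corr) and the
# component counts used.
cv_pass <- function(features, y, covars, folds, config) {
  k <- max(folds)
  rmse <- mae <- cc <- numeric(k)
  ncomp <- integer(k)
  for (fold in seq_len(k)) {
    te <- folds == fold
    if (sum(te) < 3) stop("fold with fewer than 3 test subjects")
    res <- nuisance_residualize(y[!te], y[te],
                                covars[!te, , drop = FALSE],
                                covars[te, , drop = FALSE])
    pc <- pca_reduce(features[!te, , drop = FALSE],
                     features[te, , drop = FALSE],
                     threshold = config$pc_variance_threshold,
                     n_override = config$n_components_override)
    fit <- ridge_fit(pc$train, res$train, config$ridge_penalty)
    pred <- ridge_predict(fit, pc$test)
    err <- res$test - pred
    rmse[fold] <- sqrt(mean(err^2))
    mae[fold] <- mean(abs(err))
    cc[fold] <- if (sd(pred) < 1e-12 || sd(res$test) < 1e-12) 0
                else cor(res$test, pred)
    ncomp[fold] <- pc$n_components
  }
  list(scores = c(neg_rmse = -mean(rmse), neg_mae = -mean(mae),
                  corr_true_pred = mean(cc)),
       n_components = ncomp)
}

fold_assignment <- function(n, k, seed) {
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Repeated cross-validated ridge prediction of a psychopathology dimension
#'
#' Runs `n_repeats` repeats of `k_folds`-fold cross-validation. Within each
#' fold the target is residualized for nuisance covariates (training-fold
#' fit), features are reduced by training-fold PCA, and a ridge model is
#' fit and scored out of fold by RMSE, MAE, and the correlation between
#' true and predicted targets. Error metrics are sign-flipped so that
#' higher is better for every metric; scores are averaged over folds,
#' giving one value per metric per repeat.
#'
#' @param features subjects x regions feature matrix (deviations or raw).
#' @param y numeric target (one factor-score column).
#' @param cohort matching cohort table supplying nuisance covariates.
#' @param config a [prediction_config()].
#' @param dimension label for the predicted dimension (metadata).
#' @return object of class `score_distribution`: list with `scores` (data
#'   frame of per-repeat neg_rmse, neg_mae, corr_true_pred), `dimension`,
#'   `feature_kind`, `n_components` (modal count across folds) and the
#'   config.
#' @export
repeated_cv_predict <- function(features, y, cohort, config,
                                dimension = "overall") {
  stopifnot(inherits(config, "prediction_config"))
  check_aligned(features, cohort)
  if (!all(is.finite(y))) stop("non-finite values in target y")
  if (length(y) != nrow(features)) stop("y length does not match features")
  covars <- covariate_matrix(cohort, config$nuisance_covariates)
  n <- nrow(features)
  out <- matrix(NA_real_, config$n_repeats, 3,
                dimnames = list(NULL, c("neg_rmse", "neg_mae",
                                        "corr_true_pred")))
  comp <- integer(0)
  for (r in seq_len(config$n_repeats)) {
    folds <- fold_assignment(n, config$k_folds, config$seed + r)
    pass <- cv_pass(features, y, covars, folds, config)
    out[r, ] <- pass$scores
    comp <- c(comp, pass$n_components)
  }
  ncomp_modal <- as.integer(names(which.max(table(comp))))
  structure(list(scores = as.data.frame(out), dimension = dimension,
                 feature_kind = feature_kind(features),
                 n_components = ncomp_modal, config = config),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("Prediction scores: %s from %s (%d repeats, %d PCs)\n",
              x$dimension, x$feature_kind, nrow(x$scores), x$n_components))
  print(round(colMeans(x$scores), 4))
  invisible(x)
}

#' Permutation test of prediction performance
#'
#' Compares the observed point estimate (mean over repeats) of a scoring
#' metric against a null distribution built by permuting the target and
#' re-running the cross-validation pipeline, one pass per permutation.
#' All permutations share one fixed fold partition (the first repeat's),
#' which permits caching of the target-independent computations - the
#' fold-wise PCA and the ridge prediction operator - since permuting `y`
#' leaves the feature side untouched. The p-value is the plain proportion
#' of permuted scores greater than or equal to the observed point
#' estimate; no add-one smoothing, so the granularity floor is
#' `1/n_permutations` and a p of exactly 0 is possible.
#'
#' @param observed a `score_distribution` from [repeated_cv_predict()].
#' @param features,y,cohort the same inputs that produced `observed`.
#' @param config a [prediction_config()]; `n_permutations` controls the
#'   null size (a warning is issued below 100).
#' @param metric which scoring metric to test.
#' @return list with `p_value`, `observed` point estimate, the `null`
#'   scores, and `metric`.
#' @export
permutation_test <- function(observed, features, y, cohort, config,
                             metric = c("corr_true_pred", "neg_rmse",
                                        "neg_mae")) {
  metric <- match.arg(metric)
  stopifnot(inherits(observed, "score_distribution"))
  if (config$n_permutations < 100)
    warning("fewer than 100 permutations: p-value granularity is ",
            signif(1 / config$n_permutations, 3))
  obs <- mean(observed$scores[[metric]])
  covars <- covariate_matrix(cohort, config$nuisance_covariates)
  n <- nrow(features)
  folds <- fold_assignment(n, config$k_folds, config$seed + 1)
  cache <- lapply(seq_len(config$k_folds), function(fold) {
    te <- folds == fold
    pc <- pca_reduce(features[!te, , drop = FALSE],
                     features[te, , drop = FALSE],
                     threshold = config$pc_variance_threshold,
                     n_override = config$n_components_override)
    Xtr <- sweep(pc$train, 2, colMeans(pc$train))
    Xte <- sweep(pc$test, 2, colMeans(pc$train))
    M <- crossprod(Xtr) + diag(config$ridge_penalty, ncol(Xtr))
    # linear operator: centered test scores %*% M^-1 %*% t(centered train)
    A <- Xte %*% solve(M, t(Xtr))
    Ctr <- cbind(1, covars[!te, , drop = FALSE])
    Cte <- cbind(1, covars[te, , drop = FALSE])
    list(te = te, A = A, Ctr = Ctr, Cte = Cte)
  })
  score_pass <- function(yp) {
    vals <- vapply(cache, function(fc) {
      b <- qr.coef(qr(fc$Ctr), yp[!fc$te])
      rtr <- yp[!fc$te] - drop(fc$Ctr %*% b)
      rte <- yp[fc$te] - drop(fc$Cte %*% b)
      pred <- drop(fc$A %*% (rtr - mean(rtr))) + mean(rtr)
      err <- rte - pred
      c(-sqrt(mean(err^2)), -mean(abs(err)),
        if (sd(pred) < 1e-12 || sd(rte) < 1e-12) 0 else cor(rte, pred))
    }, numeric(3))
    rowMeans(vals)[c(1, 2, 3)[match(metric, c("neg_rmse", "neg_mae",
                                              "corr_true_pred"))]]
  }
  null_scores <- vapply(seq_len(config$n_permutations), function(b) {
    yp <- with_seed(config$seed + 104729 + b, sample(y))
    score_pass(yp)
  }, numeric(1))
  p <- mean(null_scores >= obs - 1e-12)
  list(p_value = p, observed = obs, null = null_scores, metric = metric)
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up false discovery rate control at rate `q`: rejects the hypotheses
#' with the `i*` smallest p-values, where `i*` is the largest `i` with
#' `p_(i) <= i q / m`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param q target FDR rate.
#' @return logical vector of rejection decisions, same order as input.
#' @export
fdr_correct <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH") <= q
}

#' Paired sign-flip exact test of score differences
#'
#' Tests whether two paired distributions of cross-validation scores (one
#' per feature kind, paired by repeat index through shared fold structure)
#' differ, by the permutation distribution of the mean difference under
#' random sign flips of the per-repeat differences. With 20 or fewer pairs
#' all `2^n` flips are enumerated; otherwise a Monte-Carlo sample of flips
#' (including the identity flip, so the smallest attainable p is
#' `1/n_flips`) approximates the two-sided p-value.
#'
#' @param scores_a,scores_b equal-length numeric vectors of paired scores.
#' @param n_flips Monte-Carlo sample size when enumeration is infeasible.
#' @param seed integer seed for the Monte-Carlo flips.
#' @param method `"auto"` (enumerate up to 20 pairs, Monte-Carlo above),
#'   or force `"enumeration"` / `"monte_carlo"`.
#' @return list with `statistic` (mean difference a - b), `p_value`, and
#'   `method` (`"enumeration"` or `"monte_carlo"`).
#' @export
exact_test_of_differences <- function(scores_a, scores_b, n_flips = 10000,
                                      seed = 1,
                                      method = c("auto", "enumeration",
                                                 "monte_carlo")) {
  method <- match.arg(method)
  if (length(scores_a) != length(scores_b))
    stop("paired score vectors must have equal length")
  d <- scores_a - scores_b
  n <- length(d)
  stat <- mean(d)
  if (all(d == 0)) return(list(statistic = 0, p_value = 1,
                               method = "degenerate"))
  if (method == "auto") method <- if (n <= 20) "enumeration" else "monte_carlo"
  if (method == "enumeration") {
    if (n > 25) stop("enumeration infeasible beyond 25 pairs")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- as.vector(signs %*% d) / n
  } else {
    null <- with_seed(seed, {
      S <- matrix(sample(c(-1, 1), (n_flips - 1) * n, replace = TRUE),
                  n_flips - 1, n)
      c(stat, as.vector(S %*% d) / n)   # identity flip included
    })
  }
  p <- mean(abs(null) >= abs(stat) - 1e-12)
  list(statistic = stat, p_value = p, method = method)
}
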