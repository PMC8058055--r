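#' Split a cohort into a healthy normative training set and a test set
#'
#' All clinical subjects go to the test set; `n_healthy_to_test` randomly
#' chosen healthy subjects join them (so the test set spans normal through
#' clinical variation); the remaining healthy subjects form the normative
#' training set. With 381 healthy and 890 clinical subjects and
#' `n_healthy_to_test = 100` this yields the canonical 281-train /
#' 990-test design.
#'
#' @param cohort cohort table with a `group` column.
#' @param n_healthy_to_test number of healthy subjects to move to the test
#'   set (must be smaller than the number of healthy subjects).
#' @param seed integer seed controlling which healthy subjects move.
#' @return object of class `split_spec` with `train_ids`, `test_ids`,
#'   `n_healthy_in_test`.
#' @export
split_cohort <- function(cohort, n_healthy_to_test, seed = 1) {
  stop_if_not_cohort(cohort)
  if (is.null(cohort$group)) stop("cohort has no 'group' column")
  healthy <- sort(as.character(cohort$subject_id[cohort$group == "healthy"]))
  clinical <- as.character(cohort$subject_id[cohort$group != "healthy"])
  if (n_healthy_to_test >= length(healthy))
    stop("n_healthy_to_test (", n_healthy_to_test,
         ") must be smaller than the number of healthy subjects (",
         length(healthy), ")")
  to_test <- if (n_healthy_to_test > 0)
    with_seed(seed, sample(healthy, n_healthy_to_test)) else character(0)
  structure(list(train_ids = setdiff(healthy, to_test),
                 test_ids = c(clinical, to_test),
                 n_healthy_in_test = n_healthy_to_test),
            class = "split_spec")
}

#' Fit per-region Gaussian-process normative models
#'
#' For each region, fits a GP regression of the feature on (age, sex) in
#' healthy training subjects. The kernel sums a radial-basis term over
#' standardized age, a linear term over (age, sex), and a white-noise term;
#' hyperparameters are set by marginal-likelihood maximization with random
#' restarts. The learned noise standard deviation is the region's normative
#' variance (`sigma_n`); the posterior latent standard deviation at a test
#' point is its predictive uncertainty. Features are centered and scaled
#' per region on the training subset only; deviation z-scores are invariant
#' to this standardization.
#'
#' @param train_features subjects x regions feature matrix (training rows).
#' @param train_cohort matching cohort table; every subject must be healthy
#'   when a `group` column is present.
#' @param n_restarts random restarts for hyperparameter optimization.
#' @param seed integer seed for the restart draws.
#' @param min_subjects smallest acceptable training size. The default of
#'   20 guards against meaningless normative fits; internal refits (e.g.,
#'   leave-one-out cross-validation on small fixtures) may lower it.
#' @return object of class `normative_model_set`.
#' @export
fit_normative <- function(train_features, train_cohort, n_restarts = 5,
                          seed = 1, min_subjects = 20) {
  stop_if_not_cohort(train_cohort)
  check_aligned(train_features, train_cohort)
  if (!is.null(train_cohort$group) && any(train_cohort$group != "healthy"))
    stop("normative training subjects must all be healthy")
  if (nrow(train_features) < min_subjects)
    stop("need at least ", min_subjects, " training subjects, got ",
         nrow(train_features))
  if (!all(is.finite(train_features)))
    stop("non-finite feature values in training matrix")
  if (anyNA(train_cohort$age) || anyNA(train_cohort$sex))
    stop("missing covariates in training cohort")

  # sort by subject id so the fit is invariant to input row order
  ord <- order(as.character(train_cohort$subject_id))
  train_cohort <- train_cohort[ord, , drop = FALSE]
  train_features <- train_features[ord, , drop = FALSE]

  age_center <- mean(train_cohort$age)
  age_scale <- sd(train_cohort$age)
  X <- cbind((train_cohort$age - age_center) / age_scale,
             sex_to_male01(train_cohort$sex))

  region_ids <- colnames(train_features)
  models <- lapply(seq_along(region_ids), function(j) {
    y <- train_features[, j]
    ym <- mean(y); ys <- sd(y)
    if (ys < .Machine$double.eps^0.5)
      stop("feature is constant in region ", region_ids[j])
    ystd <- (y - ym) / ys
    fit <- gpr_fit(X, ystd, n_restarts = n_restarts, seed = seed)
    list(region_id = region_ids[j], theta = fit$theta, nll = fit$nll,
         jitter = fit$jitter, y_center = ym, y_scale = ys, y_std = ystd,
         sigma_n = exp(fit$theta[4]) * ys)
  })
  names(models) <- region_ids
  structure(list(models = models, region_ids = region_ids,
                 subject_ids = as.character(train_cohort$subject_id),
                 X = X, age_center = age_center, age_scale = age_scale,
                 age_range = range(train_cohort$age),
                 n_restarts = n_restarts, seed = seed),
            class = "normative_model_set")
}

#' @export
print.normative_model_set <- function(x, ...) {
  cat(sprintf("Normative model set: %d regions, %d training subjects\n",
              length(x$region_ids), nrow(x$X)))
  cat(sprintf("  training ages %.1f-%.1f; sigma_n range %.3g-%.3g\n",
              x$age_range[1], x$age_range[2],
              min(vapply(x$models, `[[`, 0, "sigma_n")),
              max(vapply(x$models, `[[`, 0, "sigma_n"))))
  invisible(x)
}

#' Normative predictions and variance components for new subjects
#'
#' Returns, per subject and region, the predicted feature value, the
#' predictive uncertainty `sigma` (posterior latent sd on the feature
#' scale), and the per-region normative sd `sigma_n`.
#'
#' @param models a `normative_model_set`.
#' @param cohort cohort table for the subjects to predict.
#' @return list with matrices `yhat` and `sigma` (subjects x regions) and
#'   vector `sigma_n` (per region).
#' @export
predict_normative <- function(models, cohort) {
  stopifnot(inherits(models, "normative_model_set"))
  stop_if_not_cohort(cohort)
  Xnew <- cbind((cohort$age - models$age_center) / models$age_scale,
                sex_to_male01(cohort$sex))
  J <- length(models$region_ids)
  yhat <- sigma <- matrix(NA_real_, nrow(cohort), J,
                          dimnames = list(as.character(cohort$subject_id),
                                          models$region_ids))
  sigma_n <- numeric(J); names(sigma_n) <- models$region_ids
  for (j in seq_len(J)) {
    m <- models$models[[j]]
    pr <- gpr_predict(m[c("theta", "jitter")], models$X, m$y_std, Xnew)
    yhat[, j] <- pr$mean * m$y_scale + m$y_center
    sigma[, j] <- pr$sd_latent * m$y_scale
    sigma_n[j] <- m$sigma_n
  }
  list(yhat = yhat, sigma = sigma, sigma_n = sigma_n)
}

#' Deviation z-scores against a fitted normative model set
#'
#' Applies `z = (y - yhat) / sqrt(sigma^2 + sigma_n^2)` per subject and
#' region: the observed feature minus the normative prediction, scaled by
#' the root sum of squared predictive uncertainty and normative variance.
#' Negative z means lower-than-normative volume.
#'
#' @param models a `normative_model_set`.
#' @param features subjects x regions feature matrix (same regions as the
#'   models).
#' @param cohort matching cohort table (ages and sex for every scored
#'   subject).
#' @return deviation matrix (subjects x regions) with attributes
#'   `feature_kind = "deviation_z"` and `provenance = "direct_test"`.
#' @export
deviation_scores <- function(models, features, cohort) {
  stopifnot(inherits(models, "normative_model_set"))
  check_aligned(features, cohort)
  if (!identical(colnames(features), models$region_ids))
    stop("region mismatch between models and feature matrix")
  pr <- predict_normative(models, cohort)
  z <- z_score_components(features, pr$yhat,
                          pr$sigma, matrix(pr$sigma_n, nrow(features),
                                           ncol(features), byrow = TRUE))
  as_feature_matrix(z, rownames(features), colnames(features),
                    "deviation_z", provenance = "direct_test")
}

# The deviation z-score equation: observed minus predicted, over the root
# sum of squared predictive uncertainty and normative variance.
z_score_components <- function(y, yhat, sigma, sigma_n) {
  (y - yhat) / sqrt(sigma^2 + sigma_n^2)
}

#' Cross-validated deviation z-scores within the training subset
#'
#' Splits the (healthy) training subjects into `k` folds; each fold is
#' scored by normative models refit on the other folds, so every training
#' subject is scored exactly once by models not trained on them. Fold
#' membership is a seeded assignment over sorted subject ids, so it is
#' invariant to the row order of the input.
#'
#' @param train_features subjects x regions training feature matrix.
#' @param train_cohort matching cohort table (all healthy).
#' @param k number of folds (>= 2, <= number of subjects).
#' @param seed integer seed for fold assignment.
#' @param n_restarts restarts per refit (refits often use fewer than the
#'   final model; the optimum is stable across folds).
#' @return deviation matrix (n_train x regions), rows in the input order,
#'   `provenance = "crossval_train"`.
#' @export
crossval_deviations <- function(train_features, train_cohort, k = 10,
                                seed = 1, n_restarts = 2) {
  stop_if_not_cohort(train_cohort)
  check_aligned(train_features, train_cohort)
  n <- nrow(train_cohort)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of training subjects (",
                  n, ")")
  ids_sorted <- sort(as.character(train_cohort$subject_id))
  fold_of <- with_seed(seed, {
    # contiguous blocks over a shuffled ordering of the sorted ids
    perm <- sample(n)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    f <- integer(n)
    f[perm] <- rep(seq_len(k), times = sizes)
    f
  })
  names(fold_of) <- ids_sorted
  Z <- matrix(NA_real_, n, ncol(train_features),
              dimnames = list(rownames(train_features),
                              colnames(train_features)))
  for (fold in seq_len(k)) {
    held_ids <- ids_sorted[fold_of == fold]
    held <- as.character(train_cohort$subject_id) %in% held_ids
    m <- fit_normative(train_features[!held, , drop = FALSE],
                       train_cohort[!held, , drop = FALSE],
                       n_restarts = n_restarts, seed = seed,
                       min_subjects = 3)
    Z[held, ] <- deviation_scores(m, train_features[held, , drop = FALSE],
                                  train_cohort[held, , drop = FALSE])
  }
  as_feature_matrix(Z, rownames(train_features), colnames(train_features),
                    "deviation_z", provenance = "crossval_train")
}
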