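test_that("nuisance residualization is leakage-safe and matches normal equations", {
  set.seed(11)
  n_tr <- 120; n_te <- 40
  C_tr <- cbind(age = runif(n_tr, 8, 22), sex = rbinom(n_tr, 1, 0.5))
  C_te <- cbind(age = runif(n_te, 8, 22), sex = rbinom(n_te, 1, 0.5))
  y_tr <- rnorm(n_tr); y_te <- rnorm(n_te)
  res <- nuisance_residualize(y_tr, y_te, C_tr, C_te)
  # oracle: explicit normal-equations solve applied out-of-sample
  X <- cbind(1, C_tr)
  b <- solve(t(X) %*% X, t(X) %*% y_tr)
  expect_equal(res$train, y_tr - drop(X %*% b), tolerance = 1e-10)
  expect_equal(res$test, y_te - drop(cbind(1, C_te) %*% b), tolerance = 1e-10)
  # y exactly linear in age: training residuals vanish
  y_lin <- 2 + 0.5 * C_tr[, "age"]
  res_lin <- nuisance_residualize(y_lin, y_te, C_tr, C_te)
  expect_lt(max(abs(res_lin$train)), 1e-10)
  # y independent of covariates: residuals ~ y minus its training mean
  y_ind <- rnorm(n_tr)
  res_ind <- nuisance_residualize(y_ind, y_te, C_tr * 0 + rnorm(n_tr * 2),
                                  C_te * 0 + rnorm(n_te * 2))
  expect_equal(res_ind$train, y_ind - mean(y_ind), tolerance = 0.2)
  # changing test-side y touches only its own residuals (no leakage back)
  res2 <- nuisance_residualize(y_tr, y_te + 1, C_tr, C_te)
  expect_identical(res2$train, res$train)
  # collinear covariates are named in the error
  C_bad <- cbind(age = C_tr[, 1], age2 = 2 * C_tr[, 1])
  expect_error(nuisance_residualize(y_tr, y_te, C_bad, C_bad[1:n_te, ]),
               "age2")
})

test_that("PCA reduction uses training statistics only and honours the threshold", {
  set.seed(12)
  # exactly 3 nonzero-variance directions
  B <- matrix(rnorm(60), 20, 3)
  X3 <- matrix(rnorm(100 * 3), 100, 3) %*% t(B)
  pc3 <- pca_reduce(X3, X3[1:10, ], threshold = 1)
  expect_identical(pc3$n_components, 3L)
  # oracle: eigendecomposition of the training covariance
  X <- matrix(rnorm(100 * 20), 100, 20)
  Xte <- matrix(rnorm(30 * 20), 30, 20)
  pc <- pca_reduce(X, Xte, threshold = 1e-9)
  E <- eigen(cov(X))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  scores_oracle <- Xc %*% E$vectors
  for (j in seq_len(ncol(pc$train)))  # eigenvector sign is arbitrary
    expect_lt(min(max(abs(pc$train[, j] - scores_oracle[, j])),
                  max(abs(pc$train[, j] + scores_oracle[, j]))), 1e-8)
  # override wins over threshold
  expect_identical(pca_reduce(X, Xte, threshold = 1, n_override = 5)$n_components,
                   5L)
  expect_error(pca_reduce(X, Xte, threshold = 100), "n_override")
})

test_that("repeated CV is null-calibrated and finds planted low-rank signal", {
  set.seed(13)
  coh <- make_cohort(500, seed = 13)
  X <- make_features(500, 30, seed = 13)
  cfg <- prediction_config(n_repeats = 5, k_folds = 5, seed = 2)
  # pure-noise targets: mean correlation near zero (averaged over a few
  # independent null draws to damp single-sample noise)
  null_means <- sapply(1:4, function(s) {
    set.seed(100 + s)
    r0 <- repeated_cv_predict(X, rnorm(500), coh, cfg, "overall")
    expect_true(all(r0$scores$neg_rmse <= 0))
    expect_true(all(r0$scores$neg_mae <= 0))
    expect_true(all(abs(r0$scores$corr_true_pred) <= 1))
    mean(r0$scores$corr_true_pred)
  })
  expect_lt(abs(mean(null_means)), 0.05)
  y0 <- rnorm(500)
  # noiseless target from 2 latent feature directions: near-perfect recovery
  P <- prcomp(X)
  y1 <- drop(P$x[, 1:2] %*% c(1, -0.5))
  r1 <- repeated_cv_predict(X, y1, coh, cfg, "overall")
  expect_gt(mean(r1$scores$corr_true_pred), 0.95)
  expect_error(repeated_cv_predict(X, c(y0[-1], NA), coh, cfg), "non-finite")
})

test_that("fold-level scores reproduce a hand-stepped pipeline on a fixture", {
  set.seed(14)
  n <- 20
  coh <- make_cohort(n, seed = 14)
  X <- make_features(n, 6, seed = 14)
  y <- rnorm(n)
  cfg <- prediction_config(n_repeats = 2, k_folds = 2, seed = 7,
                           pc_variance_threshold = 1)
  run <- repeated_cv_predict(X, y, coh, cfg, "overall")
  # oracle: walk the folds by hand for each repeat
  covars <- cbind(age = coh$age, sex = as.numeric(coh$sex == "M"))
  for (r in 1:2) {
    folds <- normdev:::fold_assignment(n, 2, 7 + r)
    per_fold <- sapply(1:2, function(fold) {
      te <- folds == fold
      Xb <- cbind(1, covars[!te, ]); b <- qr.solve(Xb, y[!te])
      rtr <- y[!te] - drop(Xb %*% b)
      rte <- y[te] - drop(cbind(1, covars[te, ]) %*% b)
      p <- prcomp(X[!te, ], center = TRUE, scale. = FALSE)
      ev <- 100 * p$sdev^2 / sum(p$sdev^2)
      nc <- sum(ev >= 1)
      Str <- p$x[, 1:nc, drop = FALSE]
      Ste <- sweep(X[te, ], 2, p$center) %*% p$rotation[, 1:nc, drop = FALSE]
      xm <- colMeans(Str); ym <- mean(rtr)
      bb <- solve(crossprod(sweep(Str, 2, xm)) + diag(1, nc),
                  crossprod(sweep(Str, 2, xm), rtr - ym))
      pred <- drop(sweep(Ste, 2, xm) %*% bb) + ym
      c(-sqrt(mean((rte - pred)^2)), -mean(abs(rte - pred)),
        cor(rte, pred))
    })
    expect_equal(unlist(run$scores[r, ]), rowMeans(per_fold),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("the permutation rule reports plain proportions with extremes", {
  coh <- make_cohort(60, seed = 15)
  X <- make_features(60, 5, seed = 15)
  y <- rnorm(60)
  cfg <- prediction_config(n_repeats = 1, k_folds = 5, n_permutations = 40,
                           seed = 3)
  obs <- repeated_cv_predict(X, y, coh, cfg, "overall")
  # observed worse than every permutation => p = 1
  obs_bad <- obs; obs_bad$scores$corr_true_pred[] <- -1e9
  expect_equal(suppressWarnings(
    permutation_test(obs_bad, X, y, coh, cfg))$p_value, 1)
  # observed better than every permutation => p = 0 (granularity 1/N)
  obs_good <- obs; obs_good$scores$corr_true_pred[] <- 1e9
  expect_warning(pt_good <- permutation_test(obs_good, X, y, coh, cfg),
                 "granularity")
  expect_equal(pt_good$p_value, 0)
  expect_length(pt_good$null, 40)
})

test_that("BH-FDR decisions match a hand-run step-up rule", {
  # hand-run step-up: largest i with p_(i) <= i q / m decides the cut.
  # For p = (.01,.02,.03,.04,.2,.9), every p_(i) exceeds i*.05/6, so
  # nothing is rejected; scaling the small ones by 10 rejects the first 4.
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2, 0.9)
  expect_identical(fdr_correct(p, q = 0.05), rep(FALSE, 6))
  p2 <- c(0.001, 0.002, 0.003, 0.004, 0.2, 0.9)
  expect_identical(fdr_correct(p2, q = 0.05),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(fdr_correct(rep(0.001, 8), q = 0.05)))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  # property: agreement with a brute-force step-up implementation
  brute_bh <- function(p, q) {
    m <- length(p); o <- order(p)
    ok <- which(p[o] <= q * seq_len(m) / m)
    rej <- logical(m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  set.seed(16)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    pv <- runif(m)^sample(c(1, 2, 0.5), 1)
    expect_identical(fdr_correct(pv, 0.05), brute_bh(pv, 0.05))
  }
})

test_that("exact test of differences: identity, separation, enumeration", {
  a <- rnorm(30)
  expect_equal(exact_test_of_differences(a, a),
               list(statistic = 0, p_value = 1, method = "degenerate"))
  # complete separation over 100 repeats: Monte-Carlo floor
  b <- a - 0.5
  out <- exact_test_of_differences(c(a, rnorm(70)), c(b, rnorm(70) - 0.5),
                                   n_flips = 2000, seed = 1)
  expect_lte(out$p_value, 1 / 2000 + 1e-12)
  expect_identical(out$method, "monte_carlo")
  # n = 10 mixed signs: Monte-Carlo agrees with full 2^10 enumeration
  set.seed(17)
  d10a <- rnorm(10, 0.3); d10b <- rnorm(10)
  full <- exact_test_of_differences(d10a, d10b)
  expect_identical(full$method, "enumeration")
  d <- d10a - d10b
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  p_manual <- mean(abs(signs %*% d / 10) >= abs(mean(d)) - 1e-12)
  expect_equal(full$p_value, p_manual)
  # Monte-Carlo agrees with the enumeration within 3 Monte-Carlo SE
  se <- sqrt(p_manual * (1 - p_manual) / 4000)
  for (s in 1:3) {
    p_mc <- exact_test_of_differences(d10a, d10b, n_flips = 4000, seed = s,
                                      method = "monte_carlo")$p_value
    expect_lt(abs(p_mc - p_manual), 3 * se + 1 / 4000)
  }
})

test_that("feature kinds share fold structure so scores are paired", {
  coh <- make_cohort(80, seed = 18)
  A <- make_features(80, 6, seed = 18)
  B <- make_features(80, 6, seed = 19)
  y <- rnorm(80)
  cfg <- prediction_config(n_repeats = 3, k_folds = 4, seed = 5)
  rA <- repeated_cv_predict(A, y, coh, cfg, "overall")
  rB <- repeated_cv_predict(B, y, coh, cfg, "overall")
  # identical features => identical per-repeat scores (same folds)
  rA2 <- repeated_cv_predict(A, y, coh, cfg, "overall")
  expect_identical(rA$scores, rA2$scores)
  expect_false(identical(rA$scores, rB$scores))
})
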