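# 381 healthy + 890 clinical subjects, the full-scale design
design_cohort <- function(seed = 1) {
  make_cohort(1271, seed = seed,
              groups = c(rep("healthy", 381), rep("other_clinical", 890)))
}

test_that("split_cohort reproduces the 281-train / 990-test design", {
  coh <- design_cohort()
  sp <- split_cohort(coh, 100, seed = 4)
  expect_length(sp$train_ids, 281)
  expect_length(sp$test_ids, 990)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_true(all(coh$group[match(sp$train_ids, coh$subject_id)] == "healthy"))
  # all clinical subjects are tested
  clin <- coh$subject_id[coh$group != "healthy"]
  expect_true(all(clin %in% sp$test_ids))
})

test_that("split_cohort is seed-deterministic and validates its input", {
  coh <- design_cohort()
  sp1 <- split_cohort(coh, 100, seed = 9)
  sp2 <- split_cohort(coh, 100, seed = 9)
  expect_identical(sp1, sp2)
  sp3 <- split_cohort(coh, 100, seed = 10)
  expect_false(setequal(sp1$train_ids, sp3$train_ids))
  sp0 <- split_cohort(coh, 0, seed = 1)
  expect_true(all(coh$group[match(sp0$test_ids, coh$subject_id)] != "healthy"))
  expect_error(split_cohort(coh, 381, seed = 1), "smaller than")
})

test_that("normative fit recovers the generating trajectory when noise vanishes", {
  cfg <- generator_config(n_subjects = 300, n_regions = 2, seed = 41,
                          normative_sd = 1e-3,
                          diagnosis_rules = all_healthy_rules())
  syn <- generate_cohort(cfg)
  m <- fit_normative(syn$volumes, syn$cohort, n_restarts = 3, seed = 1)
  pr <- predict_normative(m, syn$cohort)
  male <- as.numeric(syn$cohort$sex == "M")
  tru <- vapply(1:2, function(j)
    eval_trajectory(syn$trajectory_params[j, ], syn$cohort$age, male),
    numeric(300))
  rng <- diff(range(syn$volumes))
  expect_lt(max(abs(pr$yhat - tru)), 0.01 * rng)
})

test_that("flat pure-noise regions give a flat mean and honest sigma_n", {
  n <- 281
  tp <- data.frame(baseline = c(5, 5), amplitude = 0, midpoint = 14,
                   width = 2, slope = 0, sex_offset = 0)
  cfg <- generator_config(n_subjects = n, n_regions = 2, seed = 43,
                          trajectory_params = tp, normative_sd = c(0.6, 0.9),
                          diagnosis_rules = all_healthy_rules())
  syn <- generate_cohort(cfg)
  m <- fit_normative(syn$volumes, syn$cohort, n_restarts = 3, seed = 1)
  pr <- predict_normative(m, syn$cohort)
  # mean function approximately constant
  expect_lt(max(apply(pr$yhat, 2, sd)), 0.15)
  # sigma_n close to the sample sd of the training residuals (the oracle)
  resid_sd <- apply(syn$volumes - pr$yhat, 2, sd)
  expect_true(all(abs(pr$sigma_n - resid_sd) / resid_sd < 0.15))
})

test_that("duplicated region columns give identical fitted models", {
  cfg <- generator_config(n_subjects = 120, n_regions = 2, seed = 44,
                          diagnosis_rules = all_healthy_rules())
  syn <- generate_cohort(cfg)
  vols <- syn$volumes
  vols[, 2] <- vols[, 1]
  m <- fit_normative(vols, syn$cohort, n_restarts = 2, seed = 5)
  expect_identical(m$models[[1]]$theta, m$models[[2]]$theta)
  pr <- predict_normative(m, syn$cohort)
  expect_identical(unname(pr$yhat[, 1]), unname(pr$yhat[, 2]))
})

test_that("fit_normative rejects bad input", {
  cfg <- generator_config(n_subjects = 60, n_regions = 2, seed = 45)
  syn <- generate_cohort(cfg)
  expect_error(fit_normative(syn$volumes, syn$cohort), "healthy")
  coh <- syn$cohort; coh$group <- factor(rep("healthy", 60))
  v <- syn$volumes; v[3, 1] <- NA
  expect_error(fit_normative(v, coh), "non-finite")
  expect_error(fit_normative(syn$volumes[1:10, ], coh[1:10, ]), "at least 20")
})

test_that("deviation z-scores apply the printed formula exactly", {
  # scalar oracle: hand evaluation of z = (y - yhat)/sqrt(s^2 + sn^2)
  expect_equal(normdev:::z_score_components(10, 8, 0, 2), 1.0)
  expect_equal(normdev:::z_score_components(10, 8, sqrt(5), 2), 2 / 3)
  # numerator zero => z zero regardless of the variances
  expect_equal(normdev:::z_score_components(4.2, 4.2, 0.3, 1.7), 0)

  cfg <- generator_config(n_subjects = 150, n_regions = 3, seed = 46,
                          diagnosis_rules = all_healthy_rules())
  syn <- generate_cohort(cfg)
  m <- fit_normative(syn$volumes[1:100, ], syn$cohort[1:100, ],
                     n_restarts = 2, seed = 1)
  te <- 101:150
  z <- deviation_scores(m, syn$volumes[te, ], syn$cohort[te, ])
  pr <- predict_normative(m, syn$cohort[te, ])
  manual <- matrix(NA_real_, 50, 3)
  for (i in 1:50) for (j in 1:3)
    manual[i, j] <- (syn$volumes[te[i], j] - pr$yhat[i, j]) /
      sqrt(pr$sigma[i, j]^2 + pr$sigma_n[j]^2)
  expect_equal(unname(unclass(z))[, 1:3], manual, tolerance = 1e-12)
  expect_identical(attr(z, "feature_kind"), "deviation_z")
  # region mismatch is an error
  expect_error(deviation_scores(m, syn$volumes[te, c(2, 1, 3)],
                                syn$cohort[te, ]), "region mismatch")
})

test_that("z is strictly increasing in the observed feature", {
  cfg <- generator_config(n_subjects = 80, n_regions = 1, seed = 47,
                          diagnosis_rules = all_healthy_rules())
  syn <- generate_cohort(cfg)
  m <- fit_normative(syn$volumes, syn$cohort, n_restarts = 2, seed = 1)
  probe <- syn$cohort[1:5, ]
  vals <- seq(5, 20, length.out = 12)
  zs <- vapply(vals, function(v) {
    feats <- matrix(v, 5, 1, dimnames = list(probe$subject_id, "ROI_001"))
    deviation_scores(m, feats, probe)[1, 1]
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("held-out healthy z-scores are calibrated (standard-normal per region)", {
  cfg <- generator_config(n_subjects = 330, n_regions = 8, seed = 48,
                          diagnosis_rules = all_healthy_rules())
  syn <- generate_cohort(cfg)
  tr <- 1:180; te <- 181:330
  m <- fit_normative(syn$volumes[tr, ], syn$cohort[tr, ],
                     n_restarts = 2, seed = 1)
  z <- deviation_scores(m, syn$volumes[te, ], syn$cohort[te, ])
  ks <- apply(z, 2, function(col) ks.test(col, "pnorm")$statistic)
  crit_1pct <- 1.6276 / sqrt(length(te))  # asymptotic 1% KS critical value
  expect_gte(mean(ks < crit_1pct), 0.95)
})

test_that("cross-validated deviations match an explicit leave-one-out refit", {
  cfg <- generator_config(n_subjects = 12, n_regions = 2, seed = 49,
                          diagnosis_rules = all_healthy_rules())
  syn <- generate_cohort(cfg)
  zcv <- crossval_deviations(syn$volumes, syn$cohort, k = 12, seed = 2,
                             n_restarts = 2)
  # oracle: refit without each subject, score that subject
  for (i in c(1, 5, 12)) {
    m <- fit_normative(syn$volumes[-i, ], syn$cohort[-i, ],
                       n_restarts = 2, seed = 2, min_subjects = 3)
    zi <- deviation_scores(m, syn$volumes[i, , drop = FALSE],
                           syn$cohort[i, , drop = FALSE])
    expect_equal(unname(unclass(zcv))[i, ], unname(unclass(zi))[1, ],
                 tolerance = 1e-10)
  }
  expect_identical(attr(zcv, "provenance"), "crossval_train")
})

test_that("cross-validation folds are balanced and order-invariant", {
  cfg <- generator_config(n_subjects = 61, n_regions = 2, seed = 50,
                          diagnosis_rules = all_healthy_rules())
  syn <- generate_cohort(cfg)
  zcv <- crossval_deviations(syn$volumes, syn$cohort, k = 10, seed = 3,
                             n_restarts = 1)
  expect_identical(dim(zcv), c(61L, 2L))
  # shuffled input rows give the same per-subject scores
  set.seed(99); perm <- sample(61)
  zcv2 <- crossval_deviations(syn$volumes[perm, ], syn$cohort[perm, ],
                              k = 10, seed = 3, n_restarts = 1)
  expect_equal(unclass(zcv2)[rownames(zcv), ], unclass(zcv)[, ],
               tolerance = 1e-10)
  expect_error(crossval_deviations(syn$volumes, syn$cohort, k = 70, seed = 1),
               "exceeds")
  expect_error(crossval_deviations(syn$volumes, syn$cohort, k = 1, seed = 1),
               "at least 2")
})

test_that("fold sizes at the full design are 28 or 29", {
  # 281 training subjects in 10 folds
  n <- 281; k <- 10
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  expect_setequal(unique(sizes), c(28, 29))
  expect_equal(sum(sizes), 281)
})
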