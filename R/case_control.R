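#' Match healthy controls to a case group
#'
#' Greedy 1:1 nearest-neighbour matching without replacement: sex is
#' matched exactly; continuous covariates are standardized (over cases and
#' pool jointly) and controls minimize Euclidean distance. Cases are
#' processed in a seeded random order. Standardized mean differences (SMD)
#' per covariate are reported as balance diagnostics.
#'
#' @param cases cohort table of case subjects.
#' @param healthy_pool cohort table of candidate controls (healthy only;
#'   when matching several disorder groups, remove already-used controls
#'   from the pool so the control sets stay disjoint).
#' @param covariates matching covariates; defaults to age, sex, T1 QA and
#'   T1 SNR.
#' @param seed integer seed for the case processing order.
#' @return object of class `match_spec`: `case_ids`, `control_ids`
#'   (parallel order), `covariates`, `balance` (named SMD vector).
#' @export
match_controls <- function(cases, healthy_pool,
                           covariates = c("age", "sex", "t1_qa", "t1_snr"),
                           seed = 1) {
  stop_if_not_cohort(cases); stop_if_not_cohort(healthy_pool)
  if (!is.null(healthy_pool$group) && any(healthy_pool$group != "healthy"))
    stop("control pool must contain only healthy subjects")
  n_cases <- nrow(cases)
  if (nrow(healthy_pool) < n_cases)
    stop("control pool (", nrow(healthy_pool),
         ") is smaller than the case group (", n_cases, ")")
  exact_sex <- "sex" %in% covariates
  cont <- setdiff(covariates, "sex")
  Xc <- covariate_matrix(cases, cont) %||% matrix(0, n_cases, 0)
  Xp <- covariate_matrix(healthy_pool, cont) %||%
    matrix(0, nrow(healthy_pool), 0)
  mu <- colMeans(rbind(Xc, Xp)); sdv <- apply(rbind(Xc, Xp), 2, sd)
  sdv[sdv < 1e-12] <- 1
  Zc <- sweep(sweep(Xc, 2, mu), 2, sdv, `/`)
  Zp <- sweep(sweep(Xp, 2, mu), 2, sdv, `/`)
  sex_c <- sex_to_male01(cases$sex); sex_p <- sex_to_male01(healthy_pool$sex)

  order_idx <- with_seed(seed, sample(n_cases))
  available <- rep(TRUE, nrow(healthy_pool))
  control_of <- integer(n_cases)
  for (i in order_idx) {
    ok <- available
    if (exact_sex) ok <- ok & (sex_p == sex_c[i])
    if (!any(ok)) {
      deficit <- sum(control_of == 0L)
      stop("control pool exhausted: ", deficit,
           " case(s) could not be matched",
           if (exact_sex) " (exact sex matching)" else "")
    }
    cand <- which(ok)
    dist2 <- rowSums((Zp[cand, , drop = FALSE] -
                        matrix(Zc[i, ], length(cand), ncol(Zc),
                               byrow = TRUE))^2)
    pick <- cand[which.min(dist2)]
    control_of[i] <- pick
    available[pick] <- FALSE
  }
  ctrl <- healthy_pool[control_of, , drop = FALSE]

  smd <- vapply(covariates, function(cv) {
    a <- covariate_matrix(cases, cv)[, 1]
    b <- covariate_matrix(ctrl, cv)[, 1]
    if (cv == "sex") {
      p1 <- mean(a); p2 <- mean(b)
      denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
      if (denom < 1e-12) 0 else (p1 - p2) / denom
    } else {
      denom <- sqrt((var(a) + var(b)) / 2)
      if (denom < 1e-12) 0 else (mean(a) - mean(b)) / denom
    }
  }, numeric(1))

  structure(list(case_ids = as.character(cases$subject_id),
                 control_ids = as.character(ctrl$subject_id),
                 covariates = covariates, balance = smd),
            class = "match_spec")
}

#' @export
print.match_spec <- function(x, ...) {
  cat(sprintf("Matched case-control set: %d pairs\n", length(x$case_ids)))
  cat("  SMD:", paste(sprintf("%s=%.3f", names(x$balance), x$balance),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Regional Cohen's d effect-size map
#'
#' Per region, the standardized mean difference between two groups:
#' `d = (mean_a - mean_b) / s_pooled`, with the pooled sd using n - 1
#' weighting. For case-control deviation maps, group a are the cases and
#' group b the matched controls, so negative d means cases sit below their
#' normative expectation.
#'
#' @param deviations subjects x regions matrix (rownames are subject ids).
#' @param group_a_ids,group_b_ids disjoint subject id sets, each of size
#'   at least 3.
#' @param group optional group label stored in the map.
#' @param controlled_for optional name of a factor already residualized
#'   out of `deviations` (metadata).
#' @return object of class `effect_size_map`: named numeric vector `d`
#'   plus `group` and `controlled_for`.
#' @export
cohens_d_map <- function(deviations, group_a_ids, group_b_ids,
                         group = NULL, controlled_for = NULL) {
  if (length(intersect(group_a_ids, group_b_ids)))
    stop("groups must be disjoint")
  if (length(group_a_ids) < 3 || length(group_b_ids) < 3)
    stop("each group needs at least 3 subjects")
  A <- deviations[as.character(group_a_ids), , drop = FALSE]
  B <- deviations[as.character(group_b_ids), , drop = FALSE]
  if (anyNA(A) || anyNA(B)) stop("unknown subject ids or missing values")
  na <- nrow(A); nb <- nrow(B)
  va <- apply(A, 2, var); vb <- apply(B, 2, var)
  pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  if (any(pooled < 1e-12))
    stop("zero pooled sd in region(s): ",
         paste(colnames(deviations)[pooled < 1e-12], collapse = ", "))
  d <- (colMeans(A) - colMeans(B)) / pooled
  structure(list(d = d, group = group, controlled_for = controlled_for),
            class = "effect_size_map")
}

#' Residualize deviations on a psychopathology factor within a scope
#'
#' Removes, per region, the OLS fit on one factor score computed over the
#' scoped subjects only (e.g., one patient group plus its matched
#' controls), so group-difference analyses can be re-run controlling for
#' that factor. Control must be applied independently per patient-group
#' analysis.
#'
#' @param deviations subjects x regions deviation matrix.
#' @param cohort cohort table with `f_*` columns.
#' @param factor factor name (e.g., `"overall"`).
#' @param scope_ids subject ids defining the residualization scope;
#'   defaults to all rows of `deviations`.
#' @return deviation matrix restricted to `scope_ids`, residualized, with
#'   attribute `controlled_for`.
#' @export
control_for_factor <- function(deviations, cohort, factor,
                               scope_ids = rownames(deviations)) {
  if (!factor %in% FACTOR_NAMES) stop("unknown factor: ", factor)
  scope_ids <- as.character(scope_ids)
  idx <- match(scope_ids, as.character(cohort$subject_id))
  if (anyNA(idx)) stop("factor scores unavailable for some scoped subjects")
  f <- cohort[[paste0("f_", factor)]][idx]
  if (sd(f) < 1e-12) stop("factor '", factor, "' is constant within scope")
  D <- deviations[scope_ids, , drop = FALSE]
  R <- residualize(D, matrix(f, ncol = 1))
  out <- as_feature_matrix(R, scope_ids, colnames(deviations), "deviation_z")
  attr(out, "controlled_for") <- factor
  out
}

#' Spatial correlation between two effect-size maps
#'
#' Pearson correlation across regions between two region-indexed maps
#' (e.g., depression and ADHD Cohen's d maps), with the parametric
#' two-sided p-value.
#'
#' @param map_a,map_b `effect_size_map` objects (or named numeric vectors)
#'   over the same regions in the same order.
#' @return list with `r` and `p`.
#' @export
spatial_correlation <- function(map_a, map_b) {
  da <- if (inherits(map_a, "effect_size_map")) map_a$d else map_a
  db <- if (inherits(map_b, "effect_size_map")) map_b$d else map_b
  if (!identical(names(da), names(db)))
    stop("effect-size maps cover different regions")
  ct <- cor.test(da, db)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Test for a shift of the Cohen's d distribution toward zero
#'
#' Paired t-test over regions of `sign(d_before) * (d_before - d_after)`:
#' a positive statistic means the d values moved toward zero after
#' controlling for a factor (shrinkage of the group effect).
#'
#' @param map_before,map_after `effect_size_map` objects over the same
#'   regions.
#' @return list with `t` and `p`. A degenerate all-zero difference returns
#'   `t = 0, p = 1`.
#' @export
d_shift_test <- function(map_before, map_after) {
  db <- if (inherits(map_before, "effect_size_map")) map_before$d else map_before
  da <- if (inherits(map_after, "effect_size_map")) map_after$d else map_after
  if (!identical(names(db), names(da)))
    stop("effect-size maps cover different regions")
  if (length(db) < 10)
    warning("fewer than 10 regions; the shift test has little power")
  s <- sign(db) * (db - da)
  if (sd(s) < 1e-15) {
    if (abs(mean(s)) < 1e-15) return(list(t = 0, p = 1))
    return(list(t = sign(mean(s)) * Inf, p = 0))
  }
  tt <- t.test(s)
  list(t = unname(tt$statistic), p = tt$p.value)
}
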