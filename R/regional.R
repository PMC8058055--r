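#' Average deviations over named regions of interest
#'
#' Unweighted mean of the member parcels per subject, one column per ROI
#' (e.g., vmPFC/mOFC, inferior temporal, daCC, insula defined as unions of
#' atlas parcels).
#'
#' @param deviations subjects x regions deviation matrix.
#' @param roi_map named list mapping ROI name to a character vector of
#'   region ids (see [read_roi_map()]).
#' @return subjects x ROIs matrix, `feature_kind = "deviation_z"`.
#' @export
roi_average <- function(deviations, roi_map) {
  if (length(roi_map) == 0) stop("roi_map is empty")
  if (any(lengths(roi_map) == 0)) stop("ROIs may not be empty")
  unknown <- setdiff(unlist(roi_map), colnames(deviations))
  if (length(unknown))
    stop("unknown region id(s) in roi_map: ", paste(unknown, collapse = ", "))
  out <- vapply(roi_map, function(regs)
    rowMeans(deviations[, regs, drop = FALSE]), numeric(nrow(deviations)))
  out <- matrix(out, nrow = nrow(deviations),
                dimnames = list(rownames(deviations), names(roi_map)))
  attr(out, "feature_kind") <- attr(deviations, "feature_kind")
  out
}

#' Residualized Pearson correlation
#'
#' Pearson correlation between the OLS residuals of `x` and of `y` on the
#' covariates (both residualized on the full sample), with a two-sided
#' p-value from the t distribution on `n - 2 - k` degrees of freedom
#' (k = number of covariates; the partial-correlation convention).
#'
#' @param x,y aligned numeric vectors.
#' @param covars optional covariate matrix (e.g., T1 QA and T1 SNR);
#'   `NULL` gives the plain Pearson correlation.
#' @return list with `r`, `p`, `n`, `df`.
#' @export
residualized_correlation <- function(x, y, covars = NULL) {
  if (length(x) != length(y)) stop("x and y must be aligned")
  n <- length(x)
  k <- if (is.null(covars)) 0L else ncol(as.matrix(covars))
  rx <- drop(residualize(x, covars))
  ry <- drop(residualize(y, covars))
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
    stop("residual vector is constant; correlation undefined")
  r <- cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), n = n, df = df)
}

#' Bootstrap difference in correlation effect sizes against the general factor
#'
#' For an ROI's average deviation, compares the absolute (residualized)
#' correlation with overall psychopathology against the absolute
#' correlation with one specific dimension. In each bootstrap sample
#' (subjects resampled with replacement; residualization recomputed on the
#' resampled rows), records `|r_overall| - |r_specific|`; the percentile
#' confidence interval at `ci_level` decides significance: the general
#' factor's effect is called stronger when the lower CI bound exceeds 0.
#'
#' @param deviation_roi numeric vector, the ROI-average deviation per
#'   subject.
#' @param factors cohort table carrying the `f_*` factor-score columns.
#' @param specific_dim specific dimension name (e.g., `"anxious_misery"`).
#' @param covars optional covariate matrix for residualization.
#' @param n_boot number of bootstrap samples (10,000 in the full design;
#'   at least 1,000 recommended).
#' @param ci_level confidence level in percent (99 by default; the lower
#'   bound of the 99% interval corresponds to a Bonferroni-style p < 0.01
#'   decision).
#' @param seed integer seed.
#' @param roi_name label stored in the result.
#' @return object of class `bootstrap_delta`: `delta` (the bootstrap
#'   distribution of the effect-size difference), `ci`, `significant`,
#'   `n_degenerate` (resampled draws discarded for a constant ROI vector).
#' @export
bootstrap_delta_r <- function(deviation_roi, factors, specific_dim,
                              covars = NULL, n_boot = 10000, ci_level = 99,
                              seed = 1, roi_name = NULL) {
  if (!specific_dim %in% FACTOR_NAMES)
    stop("unknown dimension: ", specific_dim)
  yp <- factors[[paste0("f_", "overall")]]
  ys <- factors[[paste0("f_", specific_dim)]]
  if (is.null(yp) || is.null(ys))
    stop("factors table lacks required f_* columns")
  x <- as.numeric(deviation_roi)
  n <- length(x)
  if (length(yp) != n) stop("factors and deviation_roi are not aligned")
  covars <- if (!is.null(covars)) as.matrix(covars)
  M <- cbind(x, yp, ys)
  delta <- numeric(n_boot)
  n_degenerate <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(x[idx]) > 1e-12) break
        n_degenerate <- n_degenerate + 1L
        if (n_degenerate > 1000L)
          stop("too many degenerate bootstrap draws (constant ROI values)")
      }
      X <- if (is.null(covars)) matrix(1, n, 1)
           else cbind(1, covars[idx, , drop = FALSE])
      R <- .lm.fit(X, M[idx, , drop = FALSE])$residuals
      delta[b] <- abs(cor(R[, 1], R[, 2])) - abs(cor(R[, 1], R[, 3]))
    }
  })
  alpha <- (100 - ci_level) / 200
  ci <- unname(quantile(delta, c(alpha, 1 - alpha)))
  if (n_degenerate > 0L)
    message(n_degenerate, " degenerate bootstrap draw(s) were redrawn")
  structure(list(roi_name = roi_name, specific_dimension = specific_dim,
                 delta = delta, ci = ci, ci_level = ci_level,
                 significant = ci[1] > 0, n_boot = n_boot,
                 n_degenerate = n_degenerate),
            class = "bootstrap_delta")
}

#' @export
print.bootstrap_delta <- function(x, ...) {
  cat(sprintf(
    "Bootstrap delta-r (%s vs overall%s): mean %.3f, %d%% CI [%.3f, %.3f]%s\n",
    x$specific_dimension,
    if (!is.null(x$roi_name)) paste0(", ", x$roi_name) else "",
    mean(x$delta), x$ci_level, x$ci[1], x$ci[2],
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Whole-brain mass-univariate correlation analysis
#'
#' Pearson correlations between every parcel's deviations and every one of
#' the six psychopathology dimensions, optionally residualized for
#' covariates, with one Benjamini-Hochberg FDR family across all
#' parcel-by-dimension tests jointly (400 parcels x 6 dimensions = 2400
#' tests in the full design).
#'
#' @param deviations subjects x regions deviation matrix.
#' @param factors cohort table with all six `f_*` columns.
#' @param covars optional covariate matrix; residualization applies to
#'   both deviations and factor scores.
#' @param q FDR rate.
#' @return data frame with `region_id`, `dimension`, `r`, `p`,
#'   `significant`; one row per test.
#' @export
mass_univariate <- function(deviations, factors, covars = NULL, q = 0.05) {
  fcols <- factor_columns()
  if (!all(fcols %in% names(factors)))
    stop("missing dimension column(s): ",
         paste(setdiff(fcols, names(factors)), collapse = ", "))
  F <- as.matrix(factors[, fcols])
  colnames(F) <- FACTOR_NAMES
  n <- nrow(deviations)
  k <- if (is.null(covars)) 0L else ncol(as.matrix(covars))
  D <- residualize(deviations, covars)
  Fr <- residualize(F, covars)
  R <- cor(D, Fr)
  df <- n - 2L - k
  P <- 2 * pt(-abs(R * sqrt(df / (1 - R^2))), df)
  out <- data.frame(
    region_id = rep(rownames(R), times = ncol(R)),
    dimension = rep(colnames(R), each = nrow(R)),
    r = as.vector(R), p = as.vector(P),
    stringsAsFactors = FALSE)
  out$significant <- fdr_correct(out$p, q)
  out
}
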