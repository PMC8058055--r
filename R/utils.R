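`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical order of the six orthogonal psychopathology dimensions:
# one general factor plus five specific factors of the bifactor model.
FACTOR_NAMES <- c("overall", "anxious_misery", "externalizing",
                  "fear", "psychosis_pos", "psychosis_neg")

factor_columns <- function() paste0("f_", FACTOR_NAMES)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random stream set to `seed`, then restores the
#' previous `.Random.seed`, so package functions are reproducible without
#' disturbing the caller's stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || !all(c("subject_id", "age", "sex") %in% names(cohort)))
    stop("expected a cohort table with at least subject_id, age and sex columns")
  invisible(cohort)
}

# 0/1 numeric coding of sex (1 = male), from the factor stored in cohorts
sex_to_male01 <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex != 0))
  as.numeric(as.character(sex) %in% c("M", "1", "male", "Male"))
}

#' Build a numeric covariate matrix from cohort columns
#'
#' @param cohort cohort table.
#' @param covariates character vector of column names; `"sex"` is recoded
#'   to a 0/1 male indicator.
#' @return numeric matrix with one column per covariate.
#' @keywords internal
covariate_matrix <- function(cohort, covariates) {
  if (length(covariates) == 0L) return(NULL)
  missing_cols <- setdiff(covariates, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- sapply(covariates, function(cn) {
    v <- cohort[[cn]]
    if (cn == "sex") sex_to_male01(v) else as.numeric(v)
  })
  m <- matrix(m, nrow = nrow(cohort),
              dimnames = list(NULL, covariates))
  m
}

# Residualize the columns of y (vector or matrix) on covariates with an
# intercept, via one least-squares solve. covars = NULL just centers.
residualize <- function(y, covars = NULL) {
  y <- as.matrix(y)
  X <- cbind(`(Intercept)` = rep(1, nrow(y)), covars)
  fit <- lm.fit(X, y)
  r <- as.matrix(fit$residuals)
  dimnames(r) <- dimnames(y)
  r
}

as_feature_matrix <- function(values, subject_ids, region_ids,
                              feature_kind = c("raw_volume", "deviation_z"),
                              provenance = NULL) {
  feature_kind <- match.arg(feature_kind)
  values <- as.matrix(values)
  dimnames(values) <- list(subject_ids, region_ids)
  attr(values, "feature_kind") <- feature_kind
  if (!is.null(provenance)) attr(values, "provenance") <- provenance
  values
}

feature_kind <- function(x) attr(x, "feature_kind") %||% "raw_volume"

check_aligned <- function(features, cohort) {
  if (nrow(features) != nrow(cohort) ||
      !identical(rownames(features), as.character(cohort$subject_id)))
    stop("feature matrix rows are not aligned with the cohort table ",
         "(same subjects, same order, required)")
  invisible(TRUE)
}
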