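#' Configuration for the synthetic developmental cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' emulates the structure the downstream analyses assume: regional cortical
#' volumes following nonlinear, sex-dependent decline over ages 8-22 with
#' region-specific normative spread; six mutually orthogonal psychopathology
#' dimensions (one general factor plus five specific factors); deviation
#' effects planted as correlations between chosen factors and the latent
#' deviation component of chosen region sets; and deterministic diagnostic
#' labels derived from factor thresholds.
#'
#' @param n_subjects number of subjects (at least 10).
#' @param n_regions number of cortical parcels.
#' @param age_range numeric length-2, minimum and maximum age in years.
#' @param sex_ratio proportion of males.
#' @param trajectory_params optional data frame with one row per region and
#'   columns `baseline`, `amplitude`, `midpoint`, `width`, `slope`,
#'   `sex_offset` parameterizing the logistic-plus-linear age trajectory
#'   (see [eval_trajectory()]). When `NULL`, parameters are drawn once from
#'   region-level distributions governed by `seed`.
#' @param normative_sd per-region residual standard deviation of volume
#'   around the trajectory (scalar recycled, or length `n_regions`);
#'   `NULL` draws values uniformly in \[0.4, 0.8\].
#' @param effect_map list of effects, each a list with elements `regions`
#'   (integer indices or region ids), `factor` (name in
#'   `r paste(FACTOR_NAMES, collapse=", ")`, or index 1-6) and `r`, the
#'   target correlation between the factor score and the latent deviation
#'   component in those regions.
#' @param qa_params list with `qa_mean`, `qa_sd`, `snr_mean`, `snr_sd` for
#'   the T1 quality rating and signal-to-noise covariates.
#' @param diagnosis_rules rules from [diagnosis_rules()].
#' @param het_age_slope relative linear change of the residual sd across the
#'   age range (0 = homoscedastic, the default; 0.5 means the sd grows by
#'   50% of its midpoint value from the center to the upper age bound).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   cohort bit-for-bit.
#' @return object of class `generator_config`.
#' @seealso [generate_cohort()], [assign_groups()]
#' @export
generator_config <- function(n_subjects = 1271,
                             n_regions = 400,
                             age_range = c(8, 22),
                             sex_ratio = 0.474,
                             trajectory_params = NULL,
                             normative_sd = NULL,
                             effect_map = list(),
                             qa_params = list(qa_mean = 0, qa_sd = 1,
                                              snr_mean = 120, snr_sd = 15),
                             diagnosis_rules = NULL,
                             het_age_slope = 0,
                             seed = 1) {
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop("age_range must be (min, max) with min < max")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  if (!is.null(normative_sd) && any(normative_sd <= 0))
    stop("normative_sd must be strictly positive")
  if (is.null(diagnosis_rules)) diagnosis_rules <- normdev::diagnosis_rules()
  for (ef in effect_map) {
    if (!all(c("regions", "factor", "r") %in% names(ef)))
      stop("each effect_map entry needs elements regions, factor, r")
    if (abs(ef$r) > 1) stop("effect sizes must lie in [-1, 1]")
  }
  structure(list(n_subjects = n_subjects, n_regions = n_regions,
                 age_range = age_range, sex_ratio = sex_ratio,
                 trajectory_params = trajectory_params,
                 normative_sd = normative_sd, effect_map = effect_map,
                 qa_params = qa_params, diagnosis_rules = diagnosis_rules,
                 het_age_slope = het_age_slope, seed = seed),
            class = "generator_config")
}

#' Threshold rules that turn factor scores into diagnostic labels
#'
#' A subject meets a disorder rule when every named factor score exceeds its
#' threshold. Subjects meeting two or more disorder rules are labeled
#' `other_clinical` (comorbid cases are excluded from both case groups);
#' subjects meeting none are `healthy` when all six factor scores are below
#' `healthy_max` and `other_clinical` otherwise.
#'
#' The defaults give a roughly 30% healthy fraction and depression/ADHD
#' groups near 10% each of the cohort under standard-normal factor scores,
#' in line with a community-ascertained developmental sample.
#'
#' @param healthy_max upper bound on every factor score for a `healthy` label.
#' @param disorders named list; each element is a named numeric vector of
#'   lower thresholds over factor names (see `FACTOR_NAMES`).
#' @return object of class `diagnosis_rules`.
#' @export
diagnosis_rules <- function(healthy_max = 1.0,
                            disorders = list(
                              depression = c(overall = 0.25, anxious_misery = 0.75),
                              ADHD = c(overall = 0.25, externalizing = 0.75))) {
  for (d in disorders) {
    if (is.null(names(d)) || !all(names(d) %in% FACTOR_NAMES))
      stop("disorder rules must be named numeric vectors over: ",
           paste(FACTOR_NAMES, collapse = ", "))
  }
  structure(list(healthy_max = healthy_max, disorders = disorders),
            class = "diagnosis_rules")
}

region_id_labels <- function(n_regions) {
  sprintf("ROI_%0*d", max(3L, nchar(n_regions)), seq_len(n_regions))
}

#' Logistic-plus-linear normative age trajectory
#'
#' Expected regional volume at a given age and sex:
#' `baseline + amplitude * plogis(-(age - midpoint)/width) + slope * age +
#' sex_offset * male`. With positive `amplitude` and non-positive `slope`
#' this gives the robust global volume decline from childhood to adulthood,
#' with an additive sex offset.
#'
#' @param params one-row data frame (or list) with the trajectory fields.
#' @param age numeric vector of ages in years.
#' @param male 0/1 numeric vector (1 = male), recycled against `age`.
#' @return numeric vector of expected volumes.
#' @export
eval_trajectory <- function(params, age, male) {
  params$baseline +
    params$amplitude * plogis(-(age - params$midpoint) / params$width) +
    params$slope * age +
    params$sex_offset * male
}

# Resolve effect_map entries into an n_regions x 6 matrix of target
# factor-deviation correlations; reject conflicting assignments.
build_effect_beta <- function(config, region_ids) {
  J <- config$n_regions
  beta <- matrix(0, J, length(FACTOR_NAMES),
                 dimnames = list(region_ids, FACTOR_NAMES))
  assigned <- matrix(FALSE, J, length(FACTOR_NAMES))
  for (ef in config$effect_map) {
    regs <- ef$regions
    if (is.character(regs)) {
      idx <- match(regs, region_ids)
      if (anyNA(idx)) stop("unknown region id(s) in effect_map: ",
                           paste(regs[is.na(idx)], collapse = ", "))
    } else idx <- as.integer(regs)
    if (any(idx < 1 | idx > J)) stop("effect_map region index out of range")
    k <- if (is.character(ef$factor)) match(ef$factor, FACTOR_NAMES)
         else as.integer(ef$factor)
    if (is.na(k) || k < 1 || k > length(FACTOR_NAMES))
      stop("unknown factor in effect_map: ", ef$factor)
    clash <- assigned[idx, k] & beta[idx, k] != ef$r
    if (any(clash))
      stop("overlapping region sets assign conflicting effects to factor '",
           FACTOR_NAMES[k], "' in region(s) ",
           paste(region_ids[idx][clash], collapse = ", "))
    beta[idx, k] <- ef$r
    assigned[idx, k] <- TRUE
  }
  ssq <- rowSums(beta^2)
  if (any(ssq > 1))
    stop("combined squared effect sizes exceed 1 in region(s) ",
         paste(region_ids[ssq > 1], collapse = ", "),
         "; the deviation component cannot carry that much factor variance")
  beta
}

# Exactly orthogonal columns with mean 0 and sd 1, from Gram-Schmidt (QR)
# on a centered Gaussian draw.
orthogonal_factor_scores <- function(n, k) {
  M <- matrix(rnorm(n * k), n, k)
  M <- scale(M, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))
  # columns of Q lie in the centered column space, hence have mean ~0
  F <- Q * sqrt(n - 1)
  colnames(F) <- FACTOR_NAMES[seq_len(k)]
  F
}

#' Generate a synthetic developmental cohort
#'
#' Draws a cohort with covariates, orthogonal factor scores, diagnostic
#' labels, and a subjects-by-regions volume matrix constructed as
#' `trajectory(age, sex) + sd_region(age) * z`, where the latent deviation
#' `z` has unit variance and correlates with the configured factors at the
#' configured effect sizes in the configured region sets (and is pure noise
#' elsewhere). The latent deviation matrix is returned alongside the raw
#' volumes: it is exactly what a perfectly calibrated normative model would
#' recover, and serves as the ground-truth oracle in tests.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_cohort`: a list with elements
#'   `cohort` (data frame), `volumes` and `deviations` (subjects x regions
#'   matrices with `feature_kind` attributes `"raw_volume"` and
#'   `"deviation_z"`), `beta` (regions x factors matrix of planted
#'   correlations), `noise_scale`, `trajectory_params`, `normative_sd`,
#'   and the `config`.
#' @examples
#' cfg <- generator_config(n_subjects = 200, n_regions = 20, seed = 42)
#' syn <- generate_cohort(cfg)
#' dim(syn$volumes)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("config must come from generator_config()")
  n <- config$n_subjects; J <- config$n_regions
  if (n < 10) stop("n_subjects must be at least 10")
  region_ids <- region_id_labels(J)
  beta <- build_effect_beta(config, region_ids)
  with_seed(config$seed, {
    age <- runif(n, config$age_range[1], config$age_range[2])
    male <- rbinom(n, 1, config$sex_ratio)
    qa <- config$qa_params
    t1_qa <- rnorm(n, qa$qa_mean, qa$qa_sd)
    t1_snr <- rnorm(n, qa$snr_mean, qa$snr_sd)
    F <- orthogonal_factor_scores(n, length(FACTOR_NAMES))

    tp <- config$trajectory_params
    if (is.null(tp)) {
      tp <- data.frame(region_id = region_ids,
                       baseline = rnorm(J, 12, 2),
                       amplitude = runif(J, 1, 3),
                       midpoint = runif(J, 11, 16),
                       width = runif(J, 1.5, 3),
                       slope = runif(J, -0.05, 0),
                       sex_offset = rnorm(J, 0.5, 0.15))
    } else {
      tp <- as.data.frame(tp)
      if (nrow(tp) != J) stop("trajectory_params must have one row per region")
      if (is.null(tp$region_id)) tp$region_id <- region_ids
    }
    nsd <- config$normative_sd
    nsd <- if (is.null(nsd)) runif(J, 0.4, 0.8) else rep_len(nsd, J)

    noise_scale <- sqrt(pmax(0, 1 - rowSums(beta^2)))
    eps <- matrix(rnorm(n * J), n, J)
    z_lat <- F %*% t(beta) + sweep(eps, 2, noise_scale, `*`)

    mid <- mean(config$age_range); halfrange <- diff(config$age_range) / 2
    sd_scale <- 1 + config$het_age_slope * (age - mid) / halfrange
    sd_scale <- pmax(sd_scale, 0.05)
    traj <- vapply(seq_len(J), function(j) eval_trajectory(tp[j, ], age, male),
                   numeric(n))
    vol <- traj + sweep(sweep(z_lat, 1, sd_scale, `*`), 2, nsd, `*`)

    subject_id <- sprintf("S%0*d", max(4L, nchar(n)), seq_len(n))
    cohort <- data.frame(subject_id = subject_id,
                         age = age,
                         sex = factor(ifelse(male == 1, "M", "F"),
                                      levels = c("F", "M")),
                         t1_qa = t1_qa, t1_snr = t1_snr,
                         stringsAsFactors = FALSE)
    Fd <- as.data.frame(F); names(Fd) <- factor_columns()
    cohort <- cbind(cohort, Fd)
    cohort <- assign_groups(cohort, config$diagnosis_rules)

    structure(list(
      cohort = cohort,
      volumes = as_feature_matrix(vol, subject_id, region_ids, "raw_volume"),
      deviations = as_feature_matrix(z_lat, subject_id, region_ids,
                                     "deviation_z"),
      beta = beta,
      noise_scale = noise_scale,
      trajectory_params = tp,
      normative_sd = nsd,
      config = config), class = "synthetic_cohort")
  })
}

#' Assign diagnostic group labels from factor-score thresholds
#'
#' Deterministic labeling: each disorder rule is met when all of its named
#' factor scores exceed their thresholds; subjects meeting two or more
#' disorder rules are labeled `other_clinical` (mirroring the exclusion of
#' comorbid depression/ADHD cases from case-control analysis), subjects
#' meeting exactly one get that label, and the remainder are `healthy` if
#' every factor score is below `healthy_max`, else `other_clinical`.
#'
#' @param cohort cohort table with `f_*` factor-score columns.
#' @param rules a [diagnosis_rules()] object.
#' @return the cohort with a `group` factor column. Warns (does not fail)
#'   when a rule yields an empty group.
#' @export
assign_groups <- function(cohort, rules) {
  stop_if_not_cohort(cohort)
  fcols <- factor_columns()
  if (!all(fcols %in% names(cohort)))
    stop("cohort lacks factor score columns: ",
         paste(setdiff(fcols, names(cohort)), collapse = ", "))
  F <- as.matrix(cohort[, fcols])
  colnames(F) <- FACTOR_NAMES
  meets <- vapply(rules$disorders, function(thr) {
    ok <- rep(TRUE, nrow(F))
    for (nm in names(thr)) ok <- ok & F[, nm] > thr[[nm]]
    ok
  }, logical(nrow(cohort)))
  meets <- matrix(meets, nrow = nrow(cohort),
                  dimnames = list(NULL, names(rules$disorders)))
  n_met <- rowSums(meets)
  group <- rep("other_clinical", nrow(cohort))
  for (d in names(rules$disorders))
    group[n_met == 1 & meets[, d]] <- d
  is_sub <- n_met == 0 & apply(F < rules$healthy_max, 1, all)
  group[is_sub] <- "healthy"
  levels <- c("healthy", names(rules$disorders), "other_clinical")
  for (d in names(rules$disorders))
    if (!any(group == d))
      warning("diagnosis rule for '", d, "' matched no subjects")
  cohort$group <- factor(group, levels = levels)
  cohort
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of Blom fractional ranks,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties, the
#' standard way of enforcing normality on psychopathology factor scores.
#'
#' @param values numeric vector, length at least 2, not constant.
#' @return numeric vector of the same length; monotone in the input, with
#'   tied inputs mapped to equal outputs.
#' @examples
#' inverse_normal_transform(c(3, 1, 2))
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (anyNA(values) || !all(is.finite(values))) stop("values must be finite")
  if (diff(range(values)) == 0)
    stop("inverse normal transform is undefined for a constant vector")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Population correlation between an ROI-average deviation and a factor
#'
#' Closed-form value implied by the generator's construction: for an ROI
#' averaging regions `S`, `cor = mean(beta[S, k]) / sqrt(sum_k mean(beta[S,
#' k])^2 + sum(noise_scale[S]^2) / |S|^2)`. Used as the ground-truth oracle
#' for effect-recovery and bootstrap-coverage checks.
#'
#' @param object a `synthetic_cohort`.
#' @param regions region ids or indices comprising the ROI.
#' @param factor factor name or index.
#' @return the population correlation (a number in \[-1, 1\]).
#' @export
true_roi_correlation <- function(object, regions, factor) {
  stopifnot(inherits(object, "synthetic_cohort"))
  region_ids <- rownames(object$beta)
  idx <- if (is.character(regions)) match(regions, region_ids)
         else as.integer(regions)
  if (anyNA(idx)) stop("unknown region id(s)")
  k <- if (is.character(factor)) match(factor, FACTOR_NAMES)
       else as.integer(factor)
  if (is.na(k)) stop("unknown factor: ", factor)
  m <- length(idx)
  bbar <- colMeans(object$beta[idx, , drop = FALSE])
  v <- sum(bbar^2) + sum(object$noise_scale[idx]^2) / m^2
  unname(bbar[k] / sqrt(v))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic developmental cohort\n")
  cat(sprintf("  %d subjects x %d regions, ages %.1f-%.1f\n",
              nrow(x$cohort), ncol(x$volumes),
              min(x$cohort$age), max(x$cohort$age)))
  print(table(x$cohort$group))
  invisible(x)
}
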