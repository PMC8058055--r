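#' Configuration for the end-to-end pipeline
#'
#' Bundles per-stage settings for [run_pipeline()]. Two presets are
#' provided: `"paper"` carries the full-scale analysis defaults (100
#' repeats of 10-fold cross-validation, 100,000 permutations, 10,000
#' bootstraps, 99% CI, 5 GP restarts) and `"desk"` scales the stochastic
#' replication counts down (20 repeats, 200 permutations, 1,000
#' bootstraps, 2 GP restarts) for interactive use; all counts can be
#' overridden individually.
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param seed global seed; per-stage seeds derive from it.
#' @param preset `"desk"` or `"paper"`.
#' @param generator a [generator_config()] for the simulate stage, or
#'   `NULL` to start from existing `cohort.tsv` / `volumes.tsv` files in
#'   `out_dir`.
#' @param n_healthy_to_test healthy subjects moved to the test set.
#' @param dimensions psychopathology dimensions to predict.
#' @param prediction named list overriding [prediction_config()] fields.
#' @param regional named list: `n_boot`, `ci_level`, `roi_map` (named list
#'   or `NULL` for [default_roi_map()]).
#' @param case_control named list: `groups`, `control_factor`.
#' @param normative named list: `n_restarts`, `cv_k`, `cv_restarts`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            preset = c("desk", "paper"),
                            generator = NULL,
                            n_healthy_to_test = 100,
                            dimensions = "overall",
                            prediction = list(),
                            regional = list(),
                            case_control = list(),
                            normative = list()) {
  preset <- match.arg(preset)
  base <- if (preset == "paper") {
    list(prediction = list(ridge_penalty = 1, n_repeats = 100, k_folds = 10,
                           pc_variance_threshold = 1, n_permutations = 100000),
         regional = list(n_boot = 10000, ci_level = 99),
         normative = list(n_restarts = 5, cv_k = 10, cv_restarts = 2))
  } else {
    list(prediction = list(ridge_penalty = 1, n_repeats = 20, k_folds = 10,
                           pc_variance_threshold = 1, n_permutations = 200),
         regional = list(n_boot = 1000, ci_level = 99),
         normative = list(n_restarts = 2, cv_k = 10, cv_restarts = 1))
  }
  structure(list(
    out_dir = out_dir, seed = seed, preset = preset, generator = generator,
    n_healthy_to_test = n_healthy_to_test, dimensions = dimensions,
    prediction = modifyList(base$prediction, prediction),
    regional = modifyList(base$regional, regional),
    case_control = modifyList(list(groups = c("depression", "ADHD"),
                                   control_factor = "overall"),
                              case_control),
    normative = modifyList(base$normative, normative)),
    class = "pipeline_config")
}

#' Demonstration generator configuration
#'
#' A mid-size synthetic cohort (600 subjects, 100 regions) with a
#' general-factor deviation pattern planted over the default ROI parcels
#' and disorder-specific patterns planted in disjoint region blocks, the
#' structure the regional and case-control stages are designed to detect.
#'
#' @param n_subjects,n_regions cohort dimensions.
#' @param seed integer seed.
#' @return a [generator_config()].
#' @export
demo_generator_config <- function(n_subjects = 600, n_regions = 100,
                                  seed = 1) {
  generator_config(
    n_subjects = n_subjects, n_regions = n_regions, seed = seed,
    effect_map = list(
      list(regions = 1:36, factor = "overall", r = -0.2),
      list(regions = 41:50, factor = "anxious_misery", r = -0.2),
      list(regions = 51:60, factor = "externalizing", r = -0.2)))
}

pipeline_stage_files <- function(out_dir) {
  f <- function(...) file.path(out_dir, ...)
  list(simulate = c(f("cohort.tsv"), f("volumes.tsv"),
                    f("deviations_true.tsv")),
       split = f("split.json"),
       normative = c(f("deviations_test.tsv"), f("deviations_cv.tsv"),
                     f("normative_models.rds")),
       predict = c(f("prediction_scores.tsv"), f("prediction_summary.json")),
       regional = c(f("roi_map.tsv"), f("roi_correlations.tsv"),
                    f("delta_r_summary.tsv"), f("mass_univariate.tsv")),
       casecontrol = c(f("casecontrol_dmaps.tsv"),
                       f("casecontrol_summary.json")))
}

config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                           digits = NA, force = TRUE)), tmp)
  unname(md5sum(tmp))
}

#' Run the full normative-deviation analysis pipeline
#'
#' Executes the stages simulate (optional) -> split -> normative fitting
#' and deviation scoring (direct test-set z plus cross-validated training
#' z) -> prediction comparison (deviations vs raw features, with
#' permutation significance and a paired exact test) -> regional ROI /
#' mass-univariate analysis -> matched case-control Cohen's d analysis
#' with general-factor control. Every stage writes tab-separated (or JSON)
#' artifacts under `config$out_dir` and records them with md5 hashes in
#' `manifest.json`. On re-runs, stages whose outputs exist and whose
#' configuration hash matches are skipped; the first stale or missing
#' stage and everything downstream are recomputed.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_manifest` (invisibly written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- pipeline_stage_files(out)
  stage_names <- names(files)
  if (is.null(config$generator)) stage_names <- setdiff(stage_names, "simulate")
  chash <- config_hash(config)

  prev <- NULL
  manifest_path <- file.path(out, "manifest.json")
  if (file.exists(manifest_path))
    prev <- tryCatch(jsonlite::read_json(manifest_path),
                     error = function(e) NULL)
  prev_ok <- !is.null(prev) && identical(prev$config_hash, chash)

  # first stage that must re-run; everything downstream follows
  rerun_from <- length(stage_names) + 1L
  for (i in seq_along(stage_names)) {
    st <- stage_names[i]
    if (!prev_ok || !all(file.exists(files[[st]]))) { rerun_from <- i; break }
  }

  stages_run <- character(0)
  manifest_stages <- list()
  for (i in seq_along(stage_names)) {
    st <- stage_names[i]
    if (i >= rerun_from) {
      tryCatch(run_stage(st, config, out), error = function(e)
        stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
             call. = FALSE))
      stages_run <- c(stages_run, st)
    }
    manifest_stages[[st]] <- list(
      outputs = as.list(md5sum(files[[st]])),
      rerun = i >= rerun_from,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  }

  manifest <- structure(list(
    config_hash = chash, seed = config$seed, preset = config$preset,
    version = as.character(utils::packageVersion("normdev")),
    stages = manifest_stages, stages_run = stages_run),
    class = "run_manifest")
  writeLines(as.character(jsonlite::toJSON(unclass(manifest),
                                           auto_unbox = TRUE, digits = NA)),
             manifest_path)
  invisible(manifest)
}

run_stage <- function(stage, config, out) {
  f <- function(...) file.path(out, ...)
  switch(stage,
    simulate = {
      syn <- generate_cohort(config$generator)
      write_cohort_table(syn$cohort, f("cohort.tsv"))
      write_feature_matrix(syn$volumes, f("volumes.tsv"))
      write_feature_matrix(syn$deviations, f("deviations_true.tsv"))
    },
    split = {
      cohort <- read_cohort_table(f("cohort.tsv"))
      sp <- split_cohort(cohort, config$n_healthy_to_test,
                         seed = config$seed)
      writeLines(as.character(jsonlite::toJSON(unclass(sp),
                                               auto_unbox = FALSE)),
                 f("split.json"))
    },
    normative = {
      cohort <- read_cohort_table(f("cohort.tsv"))
      vols <- read_feature_matrix(f("volumes.tsv"))
      sp <- jsonlite::read_json(f("split.json"), simplifyVector = TRUE)
      tr <- match(sp$train_ids, cohort$subject_id)
      te <- match(sp$test_ids, cohort$subject_id)
      models <- fit_normative(vols[tr, , drop = FALSE], cohort[tr, ],
                              n_restarts = config$normative$n_restarts,
                              seed = config$seed)
      Z <- deviation_scores(models, vols[te, , drop = FALSE], cohort[te, ])
      Zcv <- crossval_deviations(vols[tr, , drop = FALSE], cohort[tr, ],
                                 k = config$normative$cv_k,
                                 seed = config$seed,
                                 n_restarts = config$normative$cv_restarts)
      write_feature_matrix(Z, f("deviations_test.tsv"))
      write_feature_matrix(Zcv, f("deviations_cv.tsv"))
      saveRDS(models, f("normative_models.rds"))
    },
    predict = {
      cohort <- read_cohort_table(f("cohort.tsv"))
      sp <- jsonlite::read_json(f("split.json"), simplifyVector = TRUE)
      te <- match(sp$test_ids, cohort$subject_id)
      test_cohort <- cohort[te, ]
      Z <- read_feature_matrix(f("deviations_test.tsv"), "deviation_z")
      vols <- read_feature_matrix(f("volumes.tsv"))[sp$test_ids, ,
                                                    drop = FALSE]
      vols <- as_feature_matrix(vols, rownames(vols), colnames(vols),
                                "raw_volume")
      pc <- config$prediction
      rows <- list(); summary <- list()
      for (dim in config$dimensions) {
        y <- test_cohort[[paste0("f_", dim)]]
        cfg_dev <- do.call(prediction_config,
                           c(pc, list(seed = config$seed)))
        dev_run <- repeated_cv_predict(Z, y, test_cohort, cfg_dev, dim)
        cfg_raw <- do.call(prediction_config,
                           c(pc, list(seed = config$seed,
                                      n_components_override =
                                        dev_run$n_components)))
        raw_run <- repeated_cv_predict(vols, y, test_cohort, cfg_raw, dim)
        p_dev <- permutation_test(dev_run, Z, y, test_cohort, cfg_dev)
        p_raw <- permutation_test(raw_run, vols, y, test_cohort, cfg_raw)
        ex <- exact_test_of_differences(dev_run$scores$corr_true_pred,
                                        raw_run$scores$corr_true_pred,
                                        seed = config$seed)
        rows[[dim]] <- rbind(
          data.frame(dimension = dim, feature_kind = "deviation_z",
                     repeat_ = seq_len(nrow(dev_run$scores)),
                     dev_run$scores),
          data.frame(dimension = dim, feature_kind = "raw_volume",
                     repeat_ = seq_len(nrow(raw_run$scores)),
                     raw_run$scores))
        summary[[dim]] <- list(
          n_components = dev_run$n_components,
          corr_deviation = mean(dev_run$scores$corr_true_pred),
          corr_raw = mean(raw_run$scores$corr_true_pred),
          perm_p_deviation = p_dev$p_value, perm_p_raw = p_raw$p_value,
          exact_test_statistic = ex$statistic, exact_test_p = ex$p_value)
      }
      ps <- unlist(lapply(summary, function(s)
        c(s$perm_p_deviation, s$perm_p_raw)))
      sig <- fdr_correct(ps, 0.05)
      write.table(do.call(rbind, rows), f("prediction_scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(as.character(jsonlite::toJSON(
        list(dimensions = summary, fdr_any = any(sig)),
        auto_unbox = TRUE, digits = NA)), f("prediction_summary.json"))
    },
    regional = {
      cohort <- read_cohort_table(f("cohort.tsv"))
      Z <- read_feature_matrix(f("deviations_test.tsv"), "deviation_z")
      test_cohort <- cohort[match(rownames(Z), cohort$subject_id), ]
      roi_map <- config$regional$roi_map %||% default_roi_map(colnames(Z))
      write_roi_map(roi_map, f("roi_map.tsv"))
      covars <- covariate_matrix(test_cohort, c("t1_qa", "t1_snr"))
      rois <- roi_average(Z, roi_map)
      cor_rows <- list(); delta_rows <- list()
      for (roi in colnames(rois)) {
        for (dim in FACTOR_NAMES) {
          rc <- residualized_correlation(rois[, roi],
                                         test_cohort[[paste0("f_", dim)]],
                                         covars)
          cor_rows[[paste(roi, dim)]] <-
            data.frame(roi = roi, dimension = dim, r = rc$r, p = rc$p)
        }
        for (dim in setdiff(FACTOR_NAMES, "overall")) {
          bd <- bootstrap_delta_r(rois[, roi], test_cohort, dim,
                                  covars = covars,
                                  n_boot = config$regional$n_boot,
                                  ci_level = config$regional$ci_level,
                                  seed = config$seed, roi_name = roi)
          delta_rows[[paste(roi, dim)]] <- data.frame(
            roi = roi, dimension = dim, mean_delta_r = mean(bd$delta),
            ci_low = bd$ci[1], ci_high = bd$ci[2],
            significant = bd$significant)
        }
      }
      mu <- mass_univariate(Z, test_cohort, covars = covars, q = 0.05)
      write.table(do.call(rbind, cor_rows), f("roi_correlations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(do.call(rbind, delta_rows), f("delta_r_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(mu, f("mass_univariate.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    casecontrol = {
      cohort <- read_cohort_table(f("cohort.tsv"))
      Z <- read_feature_matrix(f("deviations_test.tsv"), "deviation_z")
      Zcv <- read_feature_matrix(f("deviations_cv.tsv"), "deviation_z")
      ZZ <- rbind(Z, Zcv)  # deviations for test plus (cross-validated) train
      groups <- config$case_control$groups
      ctl_factor <- config$case_control$control_factor
      pool <- cohort[cohort$group == "healthy", ]
      maps <- list(); maps_ctl <- list(); shift <- list()
      dmap_df <- data.frame(region_id = colnames(ZZ))
      for (g in groups) {
        cases <- cohort[cohort$group == g, ]
        ms <- match_controls(cases, pool, seed = config$seed)
        pool <- pool[!pool$subject_id %in% ms$control_ids, ]
        maps[[g]] <- cohens_d_map(ZZ, ms$case_ids, ms$control_ids, group = g)
        scope <- c(ms$case_ids, ms$control_ids)
        Zc <- control_for_factor(ZZ, cohort, ctl_factor, scope)
        maps_ctl[[g]] <- cohens_d_map(Zc, ms$case_ids, ms$control_ids,
                                      group = g, controlled_for = ctl_factor)
        shift[[g]] <- d_shift_test(maps[[g]], maps_ctl[[g]])
        write.table(data.frame(case_id = ms$case_ids,
                               control_id = ms$control_ids),
                    f(paste0("match_", g, ".tsv")), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        dmap_df[[paste0("d_", g)]] <- unname(maps[[g]]$d)
        dmap_df[[paste0("d_", g, "_controlled")]] <- unname(maps_ctl[[g]]$d)
      }
      sc_before <- spatial_correlation(maps[[1]], maps[[2]])
      sc_after <- spatial_correlation(maps_ctl[[1]], maps_ctl[[2]])
      write.table(dmap_df, f("casecontrol_dmaps.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      writeLines(as.character(jsonlite::toJSON(list(
        spatial_r_before = sc_before$r, spatial_p_before = sc_before$p,
        spatial_r_after = sc_after$r, spatial_p_after = sc_after$p,
        d_shift = shift, control_factor = ctl_factor),
        auto_unbox = TRUE, digits = NA)), f("casecontrol_summary.json"))
    },
    stop("unknown stage: ", stage))
  invisible(NULL)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat("  config hash:", x$config_hash, "\n")
  cat("  stages run:",
      if (length(x$stages_run)) paste(x$stages_run, collapse = ", ")
      else "(all cached)", "\n")
  invisible(x)
}
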