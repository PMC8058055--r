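# Tab-separated text is the interchange format throughout: diff-able,
# language-neutral, and adequate at the 10^3 x 10^3 scale of regional
# feature matrices.

#' Read a cohort table from tab-separated text
#'
#' Requires `subject_id`, `age` and `sex` columns; accepts any of the
#' M/F, male/female, or 0/1 sex dialects (1 and M mean male) and maps them
#' to a common factor. Factor-score (`f_*`), QA and group columns are
#' carried through when present. Ages outside 5-95 years trigger a
#' warning; duplicate subject ids are an error.
#'
#' @param path file path.
#' @return cohort data frame.
#' @export
read_cohort_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "age", "sex")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort file is missing required column(s): ",
         paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id values in ", path)
  df$age <- as.numeric(df$age)
  if (any(df$age < 5 | df$age > 95, na.rm = TRUE))
    warning("ages outside the plausible 5-95 year range in ", path)
  sx <- as.character(df$sex)
  male <- sx %in% c("M", "m", "male", "Male", "1")
  female <- sx %in% c("F", "f", "female", "Female", "0")
  if (!all(male | female))
    stop("unrecognized sex coding: ",
         paste(unique(sx[!(male | female)]), collapse = ", "))
  df$sex <- factor(ifelse(male, "M", "F"), levels = c("F", "M"))
  if (!is.null(df$group)) df$group <- factor(df$group)
  df
}

#' Write a cohort table as tab-separated text
#'
#' @param cohort cohort data frame.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  stop_if_not_cohort(cohort)
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subjects-by-regions feature matrix from tab-separated text
#'
#' Expects a header row and a `subject_id` index column followed by one
#' column per region.
#'
#' @param path file path.
#' @param feature_kind `"raw_volume"` or `"deviation_z"`; stored as an
#'   attribute.
#' @return numeric matrix with subject ids as rownames.
#' @export
read_feature_matrix <- function(path, feature_kind = "raw_volume") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "subject_id")
    stop("feature matrix file must have a leading subject_id column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in feature matrix ", path)
  as_feature_matrix(m, ids, colnames(m), feature_kind)
}

#' Write a feature (or deviation) matrix as tab-separated text
#'
#' @param mat numeric matrix with subject-id rownames.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(subject_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parcel-to-ROI mapping file
#'
#' Two tab-separated columns, `parcel_id` and `roi_name`, one row per
#' member parcel (e.g., mapping Schaefer parcels into vmPFC_mOFC,
#' inferior_temporal, daCC and insula).
#'
#' @param path file path.
#' @return named list: ROI name to character vector of parcel ids.
#' @export
read_roi_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("parcel_id", "roi_name") %in% names(df)))
    stop("ROI map needs columns parcel_id and roi_name")
  split(as.character(df$parcel_id), df$roi_name)
}

#' Write a parcel-to-ROI mapping file
#'
#' @param roi_map named list of parcel id vectors.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_roi_map <- function(roi_map, path) {
  df <- data.frame(parcel_id = unlist(roi_map, use.names = FALSE),
                   roi_name = rep(names(roi_map), lengths(roi_map)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a factor-score table
#'
#' Tab-separated with `subject_id` plus the six `f_*` psychopathology
#' dimension columns.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_factor_scores <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", factor_columns())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("factor score file missing column(s): ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Merge externally supplied factor scores into a cohort table
#'
#' @param cohort cohort table.
#' @param factors data frame from [read_factor_scores()].
#' @return cohort with `f_*` columns replaced/added, original row order.
#' @export
merge_factor_scores <- function(cohort, factors) {
  idx <- match(as.character(cohort$subject_id), factors$subject_id)
  if (anyNA(idx)) stop("factor scores missing for some cohort subjects")
  for (cn in factor_columns()) cohort[[cn]] <- factors[[cn]][idx]
  cohort
}

#' Example 4-ROI mapping over the leading parcels
#'
#' A stand-in mapping that groups leading region ids into the four ROIs of
#' interest (vmPFC_mOFC, inferior_temporal, daCC, insula). Real atlas
#' parcel memberships are study-specific and should be supplied by the
#' user via [read_roi_map()].
#'
#' @param region_ids available region ids.
#' @return named list of parcel ids.
#' @export
default_roi_map <- function(region_ids) {
  roi_names <- c("vmPFC_mOFC", "inferior_temporal", "daCC", "insula")
  sizes <- c(8, 12, 6, 10)
  if (length(region_ids) < sum(sizes))
    sizes <- pmax(1, floor(sizes * length(region_ids) / sum(sizes)))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  out <- Map(function(s, e) region_ids[s:e], starts,
             pmin(ends, length(region_ids)))
  names(out) <- roi_names
  out
}
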