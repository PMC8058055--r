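# Shared fixture builders. Everything is generated in code; no stored data.

f_cols <- paste0("f_", c("overall", "anxious_misery", "externalizing",
                         "fear", "psychosis_pos", "psychosis_neg"))

# A bare cohort table with direct control over group labels and covariates.
make_cohort <- function(n, seed = 1, groups = NULL) {
  set.seed(seed)
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = runif(n, 8, 22),
    sex = factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M")),
    t1_qa = rnorm(n), t1_snr = rnorm(n, 120, 15),
    stringsAsFactors = FALSE)
  for (cn in f_cols) df[[cn]] <- rnorm(n)
  if (!is.null(groups)) df$group <- factor(groups)
  df
}

# All-healthy generator rules (disorder thresholds that never fire are
# exercised separately; here we want a clean normative population).
all_healthy_rules <- function()
  diagnosis_rules(healthy_max = Inf, disorders = list())

# Quick feature matrix with named dims.
make_features <- function(n, p, seed = 1, kind = "raw_volume") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n,
              dimnames = list(sprintf("S%04d", seq_len(n)),
                              sprintf("ROI_%03d", seq_len(p))))
  attr(m, "feature_kind") <- kind
  m
}
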