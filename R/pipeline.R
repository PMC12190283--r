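#' Preprocess a cohort to filtered recordings
#'
#' Resamples each recording to the target rate, applies the optional
#' artifact-removal hook, band-pass filters and trims the transient. The
#' result is the common starting point for every amplitude condition.
#'
#' @param cohort List of [recording()]s.
#' @param cfg A [preproc_config()].
#' @return List of filtered recordings.
#' @export
preprocess_cohort <- function(cohort, cfg = preproc_config()) {
  lapply(cohort, function(rec) {
    rec <- resample_polyphase(rec, cfg$target_fs, cfg$kaiser_fc_frac,
                              cfg$kaiser_df_frac)
    if (!is.null(cfg$artifact_hook)) rec <- cfg$artifact_hook(rec)
    bandpass_trim(rec, cfg)
  })
}

#' Amplitude condition, epoching and MFE for a preprocessed cohort
#'
#' Applies one amplitude condition to each filtered recording (transforms
#' are fitted per subject on the whole post-filter recording, before epoch
#' division), epochs it, and computes the MFE matrix.
#'
#' @param base_recs List of post-filter recordings from
#'   [preprocess_cohort()].
#' @param spec A [transform_spec()] or condition name.
#' @param cfg A [preproc_config()] (for the epoch length).
#' @param params An [mfe_params()].
#' @return List with `mfe` (list of `mfe_matrix`) and `features`
#'   (combined observation table).
#' @export
condition_mfe <- function(base_recs, spec = "reference",
                          cfg = preproc_config(), params = mfe_params()) {
  if (!inherits(spec, "transform_spec")) spec <- transform_spec(spec)
  mfe_list <- lapply(base_recs, function(rec) {
    tr <- apply_condition(rec, spec)
    compute_mfe(epoch_recording(tr, cfg$epoch_len), params)
  })
  list(condition = spec$condition, mfe = mfe_list,
       features = combine_features(lapply(mfe_list, extract_features)))
}

#' Run the full condition-by-classifier evaluation
#'
#' For each amplitude condition: preprocessed recordings are transformed,
#' epoched, reduced to long-scale MFE features, then each classifier family
#' is model-selected by LOSO grid search on the training subjects,
#' retrained, and evaluated on the test subjects. One split plan is used
#' for every (condition, classifier) cell so comparisons are paired.
#'
#' @param cohort List of [recording()]s.
#' @param conditions Character vector of condition names (default all
#'   five).
#' @param families Classifier families (default `c("svm", "rf", "knn")`).
#' @param grids Named list of per-family grids (default
#'   [grid_default()]); pass [grid_reduced()] grids for quick studies.
#' @param split A [split_plan()]; by default computed from the cohort with
#'   `seed`.
#' @param cfg A [preproc_config()].
#' @param params An [mfe_params()].
#' @param seed Integer seed.
#' @return An `mfe_eval_table`: list with `reports` (nested
#'   `[[condition]][[family]]` eval reports), the shared `split`, and a
#'   `summary` data frame.
#' @export
run_conditions <- function(cohort,
                           conditions = c("reference", "single_stand",
                                          "single_norm", "global_stand",
                                          "global_norm"),
                           families = c("svm", "rf", "knn"),
                           grids = NULL, split = NULL,
                           cfg = preproc_config(), params = mfe_params(),
                           seed = 1L) {
  if (is.null(grids))
    grids <- setNames(lapply(families, grid_default), families)
  base_recs <- preprocess_cohort(cohort, cfg)
  meta <- cohort_meta(cohort)
  if (is.null(split)) split <- split_plan(meta, seed = seed)
  reports <- list()
  rows <- list()
  for (cnd in conditions) {
    feats <- condition_mfe(base_recs, cnd, cfg, params)$features
    train_ft <- feats[feats$subject_id %in% split$train, , drop = FALSE]
    test_ft <- feats[feats$subject_id %in% split$test, , drop = FALSE]
    for (fam in families) {
      sel <- loso_select(train_ft, fam, grids[[fam]], seed = seed)
      rep <- fit_evaluate(train_ft, test_ft, fam, sel$params, seed = seed)
      rep$condition <- cnd
      reports[[cnd]][[fam]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cnd, family = fam,
        mean_accuracy = rep$mean_accuracy, uncertainty = rep$uncertainty,
        mcc = rep$mcc, cv_accuracy = sel$cv_accuracy,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(reports = reports, split = split,
                 summary = do.call(rbind, rows)),
            class = "mfe_eval_table")
}

#' @export
print.mfe_eval_table <- function(x, ...) {
  cat("<mfe_eval_table>\n")
  print(x$summary, digits = 3)
  invisible(x)
}
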