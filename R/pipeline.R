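#' Channel-selection decoding workflow
#'
#' The full per-subject pipeline: preprocess the HbO recording, build the
#' channel regression design, select informative channels on the LASSO
#' homotopy path by cross-validation, then estimate stratified k-fold CV
#' accuracy of each classifier on the per-sample HbO vectors of the
#' selected channels. Results are aggregated into a
#' [aggregate_report()] across subjects.
#'
#' @param cohort list of per-subject lists with elements `rec` (HbO
#'   [nirs_recording()]) and `paradigm` (e.g. from [generate_cohort()], or
#'   assembled from files).
#' @param spec a [filter_spec()] for preprocessing.
#' @param classifiers classifier kinds to evaluate (see
#'   [train_classifier()]).
#' @param folds CV folds for both selection and accuracy estimation.
#' @param seed fold-assignment seed (default 2575).
#' @param out_dir optional directory; when given, per-subject selection
#'   and accuracy tables plus a run manifest are written as delimited
#'   text.
#' @return list with `report` (a `classification_report`), `selections`
#'   (per-subject [select_channels()] results), and `accuracy`
#'   (subjects x classifiers matrix).
#' @export
run_selection_workflow <- function(cohort, spec = filter_spec(),
                                   classifiers = c("lda_diag", "logreg", "svm_rbf"),
                                   folds = 5, seed = 2575, out_dir = NULL) {
  selections <- vector("list", length(cohort))
  acc <- matrix(NA_real_, length(cohort), length(classifiers),
                dimnames = list(paste0("S", seq_along(cohort)), classifiers))
  for (s in seq_along(cohort)) {
    step <- "preprocess"
    res <- tryCatch({
      rec <- preprocess(cohort[[s]]$rec, cohort[[s]]$paradigm, spec)
      step <- "build_design"
      prob <- build_design(rec, cohort[[s]]$paradigm)
      step <- "select_channels"
      sel <- select_channels(prob, folds = folds, seed = seed + s)
      step <- "classify"
      labels <- ifelse(prob$y > 0, "task", "rest")
      Xsel <- prob$X[, sel$selected, drop = FALSE]
      a <- vapply(classifiers, kfold_accuracy, numeric(1),
                  features = Xsel, labels = labels, k = folds,
                  seed = seed + s)
      list(sel = sel, acc = a)
    }, error = function(e)
      stop("subject ", s, ", stage ", step, ": ", conditionMessage(e),
           call. = FALSE))
    selections[[s]] <- res$sel
    acc[s, ] <- res$acc
  }
  report <- aggregate_report(acc)
  if (!is.null(out_dir)) {
    write_workflow_outputs(out_dir, "selection", acc, selections,
                           seed = seed, folds = folds)
  }
  list(report = report, selections = selections, accuracy = acc)
}

#' Feature-extraction baseline workflow
#'
#' The comparison arm: preprocess, compute block-wise statistical features
#' of *all* channels (no selection), and estimate stratified k-fold CV
#' accuracy per classifier.
#'
#' @inheritParams run_selection_workflow
#' @param feature_set statistics to extract (see [build_feature_table()]):
#'   `c("mean", "peak", "variance")` or with `"skewness"` added.
#' @return list with `report` and `accuracy` (subjects x classifiers).
#' @export
run_feature_workflow <- function(cohort, spec = filter_spec(),
                                 feature_set = c("mean", "peak", "variance"),
                                 classifiers = c("lda_diag", "logreg", "svm_rbf"),
                                 folds = 5, seed = 2575, out_dir = NULL) {
  acc <- matrix(NA_real_, length(cohort), length(classifiers),
                dimnames = list(paste0("S", seq_along(cohort)), classifiers))
  for (s in seq_along(cohort)) {
    step <- "preprocess"
    acc[s, ] <- tryCatch({
      rec <- preprocess(cohort[[s]]$rec, cohort[[s]]$paradigm, spec)
      step <- "features"
      ft <- build_feature_table(rec, cohort[[s]]$paradigm, feature_set)
      step <- "classify"
      vapply(classifiers, kfold_accuracy, numeric(1),
             features = ft, k = folds, seed = seed + s)
    }, error = function(e)
      stop("subject ", s, ", stage ", step, ": ", conditionMessage(e),
           call. = FALSE))
  }
  report <- aggregate_report(acc)
  if (!is.null(out_dir)) {
    write_workflow_outputs(out_dir, "features", acc, NULL,
                           seed = seed, folds = folds,
                           feature_set = feature_set)
  }
  list(report = report, accuracy = acc)
}

# Internal: delimited-text outputs + manifest for a workflow run.
write_workflow_outputs <- function(out_dir, workflow, acc, selections,
                                   seed, folds, feature_set = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(subject = rownames(acc),
                              round(acc, 2), check.names = FALSE),
                   file.path(out_dir, paste0("accuracy_", workflow, ".csv")),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(selections)) {
    sel_df <- data.frame(
      subject = seq_along(selections),
      selected_channels = vapply(selections, function(s)
        paste(s$selected, collapse = " "), character(1)),
      lambda = vapply(selections, function(s) s$lambda_chosen, numeric(1)),
      cv_mse = vapply(selections, function(s)
        min(s$cv_curve$cv_mse), numeric(1)),
      fallback = vapply(selections, function(s) s$fallback, logical(1)))
    utils::write.csv(sel_df, file.path(out_dir, "channel_selection.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- c(
    paste0("workflow=", workflow),
    paste0("seed=", seed),
    paste0("folds=", folds),
    if (!is.null(feature_set))
      paste0("feature_set=", paste(feature_set, collapse = ",")),
    paste0("n_subjects=", nrow(acc)),
    paste0("mean_accuracy=", paste(sprintf("%s:%.4f", colnames(acc),
                                           colMeans(acc)), collapse = " ")))
  writeLines(manifest, file.path(out_dir, paste0("manifest_", workflow, ".txt")))
  invisible(out_dir)
}
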