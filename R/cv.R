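default_features <- function(features = NULL) {
  utils::modifyList(list(method = "pca", n_components = 100, k_best = 100,
                         variance_threshold = 0.001),
                    if (is.null(features)) list() else features)
}

assert_no_leakage <- function(train_subjects, test_subjects) {
  dup <- intersect(train_subjects, test_subjects)
  if (length(dup))
    stop("subject-level leakage: subject(s) ",
         paste(unique(dup), collapse = ", "),
         " appear in both train and test")
  invisible(TRUE)
}

# Row assignments per fold, with the leakage assertion baked in.
fold_assignments <- function(subject_ids, plan) {
  lapply(seq_len(plan$k), function(j) {
    test_sub <- names(plan$folds)[plan$folds == j]
    train_sub <- names(plan$folds)[plan$folds != j]
    assert_no_leakage(train_sub, test_sub)
    if (length(intersect(plan$holdout_subjects,
                         c(train_sub, test_sub))))
      stop("hold-out subjects must never enter cross-validation")
    list(train_subjects = train_sub, test_subjects = test_sub,
         rows_train = which(subject_ids %in% train_sub),
         rows_test = which(subject_ids %in% test_sub))
  })
}

target_vector <- function(cohort, target = c("rating", "cue")) {
  target <- match.arg(target)
  if (target == "rating") as.numeric(cohort$meta$rating)
  else as.numeric(cohort$meta$cue_type)
}

#' Subject-level k-fold cross-validation of the regression pipeline
#'
#' For each fold: fits the feature reducer and regressor on the in-fold
#' training subjects only, predicts the left-out fold, and records
#' rating-stratified RMSE/MAE per fold plus the pooled out-of-fold
#' predictions. Hold-out subjects in the plan are never touched; a
#' subject appearing on both sides of any fold aborts the run.
#'
#' @param cohort a `crave_cohort` (exclusions already applied).
#' @param plan a [make_split()] plan covering the fitting subjects.
#' @param target `"rating"` (craving regression) or `"cue"` (0/1 cue
#'   code regression).
#' @param spec a [regressor_spec()].
#' @param features list with `method` (`"pca"`/`"anova"`),
#'   `n_components` or `k_best`, and optionally `variance_threshold`.
#' @param seed seed for stochastic regressors (one child per fold).
#' @return List: `fold_metrics` (data frame fold / rmse / mae),
#'   `predictions` (data frame with subject, fold, y, yhat for every
#'   out-of-fold sample), `pooled` (stratified rmse/mae and pooled
#'   Pearson r over all out-of-fold predictions).
#' @export
run_cv <- function(cohort, plan, target = c("rating", "cue"),
                   spec = regressor_spec("ols"), features = NULL,
                   seed = 1L) {
  target <- match.arg(target)
  feat <- default_features(features)
  y <- target_vector(cohort, target)
  sid <- cohort$meta$subject_id
  folds <- fold_assignments(sid, plan)
  seeds <- child_seeds(seed, plan$k)
  preds <- vector("list", plan$k)
  fm <- data.frame(fold = seq_len(plan$k), rmse = NA_real_,
                   mae = NA_real_)
  for (j in seq_len(plan$k)) {
    fa <- folds[[j]]
    pipe <- fit_pipeline(cohort$X[fa$rows_train, , drop = FALSE],
                         y[fa$rows_train], spec = spec,
                         method = feat$method,
                         n_components = feat$n_components,
                         k_best = feat$k_best,
                         variance_threshold = feat$variance_threshold,
                         train_subjects = fa$train_subjects,
                         seed = seeds[j])
    yhat <- predict(pipe, cohort$X[fa$rows_test, , drop = FALSE])
    fm$rmse[j] <- stratified_metric(y[fa$rows_test], yhat, "rmse")
    fm$mae[j] <- stratified_metric(y[fa$rows_test], yhat, "mae")
    preds[[j]] <- data.frame(subject_id = sid[fa$rows_test],
                             fold = j, y = y[fa$rows_test], yhat = yhat,
                             stringsAsFactors = FALSE)
  }
  oof <- do.call(rbind, preds)
  list(fold_metrics = fm,
       predictions = oof,
       pooled = list(
         rmse = stratified_metric(oof$y, oof$yhat, "rmse"),
         mae = stratified_metric(oof$y, oof$yhat, "mae"),
         pearson = if (stats::var(oof$yhat) > 0)
           pearson_metric(oof$y, oof$yhat) else NA_real_))
}

#' One-shot out-of-sample evaluation on the hold-out subjects
#'
#' Fits a single final pipeline on every fitting subject of the plan
#' and scores the hold-out subjects once.
#'
#' @inheritParams run_cv
#' @return List: `pipeline` (the final fit), `predictions` (hold-out
#'   data frame), `metrics` (stratified rmse/mae, pooled Pearson r).
#' @export
evaluate_holdout <- function(cohort, plan, target = c("rating", "cue"),
                             spec = regressor_spec("ols"),
                             features = NULL, seed = 1L) {
  target <- match.arg(target)
  feat <- default_features(features)
  y <- target_vector(cohort, target)
  sid <- cohort$meta$subject_id
  fitting <- unique(names(plan$folds))
  assert_no_leakage(fitting, plan$holdout_subjects)
  rows_fit <- which(sid %in% fitting)
  rows_hold <- which(sid %in% plan$holdout_subjects)
  pipe <- fit_pipeline(cohort$X[rows_fit, , drop = FALSE], y[rows_fit],
                       spec = spec, method = feat$method,
                       n_components = feat$n_components,
                       k_best = feat$k_best,
                       variance_threshold = feat$variance_threshold,
                       train_subjects = fitting, seed = seed)
  yhat <- predict(pipe, cohort$X[rows_hold, , drop = FALSE])
  yh <- y[rows_hold]
  list(pipeline = pipe,
       predictions = data.frame(subject_id = sid[rows_hold], y = yh,
                                yhat = yhat, stringsAsFactors = FALSE),
       metrics = list(
         rmse = stratified_metric(yh, yhat, "rmse"),
         mae = stratified_metric(yh, yhat, "mae"),
         pearson = if (stats::var(yh) > 0 && stats::var(yhat) > 0)
           pearson_metric(yh, yhat) else NA_real_))
}

#' Metric distribution over repeated cross-validation
#'
#' Repeats the subject-level k-fold split with fresh fold deals (child
#' seeds of `seed`) over the fitting subjects and records the pooled
#' out-of-fold metrics of each repetition. The resulting vectors are
#' the "observed" distributions that permutation nulls are compared
#' against.
#'
#' @inheritParams run_cv
#' @param fitting_subjects subjects to cross-validate (e.g.,
#'   `names(plan$folds)` of an outer split); defaults to all subjects
#'   in the cohort.
#' @param n_reps repetitions.
#' @param k folds per repetition.
#' @return Data frame with one row per repetition: `rep`, `rmse`,
#'   `mae`, `pearson`.
#' @export
repeated_cv <- function(cohort, fitting_subjects = NULL, n_reps = 100,
                        k = 5, target = c("rating", "cue"),
                        spec = regressor_spec("ols"), features = NULL,
                        seed = 1L) {
  target <- match.arg(target)
  if (is.null(fitting_subjects))
    fitting_subjects <- cohort_subjects(cohort)
  keep <- cohort$meta$subject_id %in% fitting_subjects
  sub <- subset_cohort(cohort, keep)
  seeds <- child_seeds(seed, n_reps)
  rows <- lapply(seq_len(n_reps), function(r) {
    plan <- make_split(fitting_subjects, holdout_fraction = 0, k = k,
                       seed = seeds[r])
    cv <- run_cv(sub, plan, target = target, spec = spec,
                 features = features, seed = seeds[r])
    data.frame(rep = r, rmse = cv$pooled$rmse, mae = cv$pooled$mae,
               pearson = cv$pooled$pearson)
  })
  do.call(rbind, rows)
}

# Row-subset a cohort, keeping grid/mask metadata.
subset_cohort <- function(cohort, keep) {
  cohort$X <- cohort$X[keep, , drop = FALSE]
  cohort$meta <- cohort$meta[keep, , drop = FALSE]
  rownames(cohort$meta) <- NULL
  cohort
}
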