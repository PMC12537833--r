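TASKS <- c("regress", "classify_craving", "classify_cue")

# Task-specific defaults: component counts 100 (regression), 50
# (high/low craving, fewer samples), 100 (cue type).
task_features <- function(task, features = NULL) {
  base <- default_features(features)
  if (is.null(features$n_components))
    base$n_components <- switch(task, regress = 100,
                                classify_craving = 50,
                                classify_cue = 100)
  base
}

# Assemble the training target and evaluation labels of a task.
# regress:          y = rating, no labels
# classify_craving: extreme samples only; y = raw 1-4 rating of the
#                   extremes (the regressor is unchanged), labels = 0/1
#                   low/high; decision threshold F1-optimized per fold
# classify_cue:     y = labels = 0/1 cue code, fixed threshold 0.5
task_data <- function(cohort, task) {
  switch(task,
    regress = list(cohort = cohort,
                   y = as.numeric(cohort$meta$rating), labels = NULL),
    classify_craving = {
      bin <- binarize_craving(cohort)
      list(cohort = bin$cohort,
           y = as.numeric(bin$cohort$meta$rating), labels = bin$labels)
    },
    classify_cue = list(cohort = cohort,
                        y = as.numeric(cohort$meta$cue_type),
                        labels = cohort$meta$cue_type),
    stop("unknown task: ", task))
}

# Pooled out-of-fold metrics of a task from its prediction table.
task_pooled_metrics <- function(task, oof) {
  if (task == "regress") {
    c(rmse = stratified_metric(oof$y, oof$yhat, "rmse"),
      mae = stratified_metric(oof$y, oof$yhat, "mae"),
      pearson = if (stats::var(oof$yhat) > 0 && stats::var(oof$y) > 0)
        pearson_metric(oof$y, oof$yhat) else NA_real_)
  } else if (task == "classify_craving") {
    c(rmse = stratified_metric(oof$y, oof$yhat, "rmse"),
      accuracy = mean(oof$pred == oof$label),
      auc_roc = auc_roc_value(oof$label, oof$yhat))
  } else {
    cm_acc <- mean(oof$pred == oof$label)
    tp <- sum(oof$pred == 1L & oof$label == 1L)
    fp <- sum(oof$pred == 1L & oof$label == 0L)
    c(accuracy = cm_acc,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      auc_roc = auc_roc_value(oof$label, oof$yhat),
      auc_pr = auc_pr_value(oof$label, oof$yhat))
  }
}

#' Cross-validate one analysis task
#'
#' Runs the shared pipeline (variance filter, scaler, reduction,
#' regression) under subject-level k-fold CV for one of the three
#' tasks: craving regression, high/low-craving classification
#' (F1-optimized threshold re-fit on each fold's training predictions),
#' or cue-type classification (fixed threshold 0.5). All three tasks
#' share every upstream stage; only the target, the component-count
#' default and the threshold mapping differ.
#'
#' @param cohort a `crave_cohort` (exclusions applied).
#' @param plan a [make_split()] plan.
#' @param task one of `"regress"`, `"classify_craving"`,
#'   `"classify_cue"`.
#' @param spec a [regressor_spec()].
#' @param features optional feature-reduction overrides; defaults are
#'   task-specific (PCA with 100 / 50 / 100 components).
#' @param threshold fixed decision threshold for the cue task.
#' @param seed RNG seed.
#' @return List: `predictions` (out-of-fold table), `pooled` (named
#'   metric vector), `fold_thresholds` (high/low task only).
#' @export
run_task <- function(cohort, plan, task = TASKS,
                     spec = regressor_spec("ols"), features = NULL,
                     threshold = 0.5, seed = 1L) {
  task <- match.arg(task)
  feat <- task_features(task, features)
  td <- task_data(cohort, task)
  sid <- td$cohort$meta$subject_id
  folds <- fold_assignments(sid, plan)
  seeds <- child_seeds(seed, plan$k)
  preds <- vector("list", plan$k)
  thresholds <- rep(NA_real_, plan$k)
  for (j in seq_len(plan$k)) {
    fa <- folds[[j]]
    if (length(fa$rows_test) == 0L) next
    pipe <- fit_pipeline(td$cohort$X[fa$rows_train, , drop = FALSE],
                         td$y[fa$rows_train], spec = spec,
                         method = feat$method,
                         n_components = feat$n_components,
                         k_best = feat$k_best,
                         variance_threshold = feat$variance_threshold,
                         train_subjects = fa$train_subjects,
                         seed = seeds[j])
    yhat <- predict(pipe, td$cohort$X[fa$rows_test, , drop = FALSE])
    p <- data.frame(subject_id = sid[fa$rows_test], fold = j,
                    y = td$y[fa$rows_test], yhat = yhat,
                    stringsAsFactors = FALSE)
    if (task == "classify_craving") {
      yhat_train <- predict(pipe, td$cohort$X[fa$rows_train, , drop = FALSE])
      thr <- optimize_threshold(yhat_train, td$labels[fa$rows_train])
      thresholds[j] <- thr$threshold
      p$label <- td$labels[fa$rows_test]
      p$pred <- as.integer(yhat >= thr$threshold)
    } else if (task == "classify_cue") {
      p$label <- td$labels[fa$rows_test]
      p$pred <- classify_cue(yhat, threshold)
    }
    preds[[j]] <- p
  }
  oof <- do.call(rbind, preds)
  list(predictions = oof, pooled = task_pooled_metrics(task, oof),
       fold_thresholds = thresholds)
}

#' Hold-out (out-of-sample) evaluation of one task
#'
#' Fits a single final pipeline on all fitting subjects and scores the
#' hold-out subjects once. For the high/low task the decision threshold
#' is F1-optimized on the fitting-set predictions, never on the
#' hold-out.
#'
#' @inheritParams run_task
#' @return List: `pipeline`, `predictions` (hold-out table),
#'   `metrics` (named vector), `roc` (ROC points for the binary tasks),
#'   `threshold` (decision threshold used, if any).
#' @export
evaluate_holdout_task <- function(cohort, plan, task = TASKS,
                                  spec = regressor_spec("ols"),
                                  features = NULL, threshold = 0.5,
                                  seed = 1L) {
  task <- match.arg(task)
  feat <- task_features(task, features)
  td <- task_data(cohort, task)
  sid <- td$cohort$meta$subject_id
  fitting <- unique(names(plan$folds))
  assert_no_leakage(fitting, plan$holdout_subjects)
  rows_fit <- which(sid %in% fitting)
  rows_hold <- which(sid %in% plan$holdout_subjects)
  if (length(rows_hold) == 0L) stop("plan has no hold-out subjects")
  pipe <- fit_pipeline(td$cohort$X[rows_fit, , drop = FALSE],
                       td$y[rows_fit], spec = spec,
                       method = feat$method,
                       n_components = feat$n_components,
                       k_best = feat$k_best,
                       variance_threshold = feat$variance_threshold,
                       train_subjects = fitting, seed = seed)
  yhat <- predict(pipe, td$cohort$X[rows_hold, , drop = FALSE])
  oof <- data.frame(subject_id = sid[rows_hold], fold = 0L,
                    y = td$y[rows_hold], yhat = yhat,
                    stringsAsFactors = FALSE)
  thr_used <- NA_real_
  roc <- NULL
  if (task == "classify_craving") {
    yhat_fit <- predict(pipe, td$cohort$X[rows_fit, , drop = FALSE])
    thr_used <- optimize_threshold(yhat_fit, td$labels[rows_fit])$threshold
    oof$label <- td$labels[rows_hold]
    oof$pred <- as.integer(yhat >= thr_used)
    roc <- roc_points(oof$label, oof$yhat)
  } else if (task == "classify_cue") {
    thr_used <- threshold
    oof$label <- td$labels[rows_hold]
    oof$pred <- classify_cue(yhat, threshold)
    roc <- roc_points(oof$label, oof$yhat)
  }
  list(pipeline = pipe, predictions = oof,
       metrics = task_pooled_metrics(task, oof), roc = roc,
       threshold = thr_used)
}

#' Repeated-CV metric distributions for one task
#'
#' Repeats the subject-level k-fold deal with fresh child seeds and
#' records the pooled out-of-fold metrics of every repetition; these
#' are the "observed" distributions entering permutation inference.
#'
#' @inheritParams run_task
#' @param fitting_subjects subjects to cross-validate; defaults to all.
#' @param n_reps number of repetitions.
#' @param k folds.
#' @return Data frame, one row per repetition, columns = task metrics.
#' @export
repeated_task <- function(cohort, fitting_subjects = NULL,
                          task = TASKS, n_reps = 100, k = 5,
                          spec = regressor_spec("ols"), features = NULL,
                          threshold = 0.5, seed = 1L) {
  task <- match.arg(task)
  if (is.null(fitting_subjects))
    fitting_subjects <- cohort_subjects(cohort)
  sub <- subset_cohort(cohort,
                       cohort$meta$subject_id %in% fitting_subjects)
  seeds <- child_seeds(seed, n_reps)
  rows <- lapply(seq_len(n_reps), function(r) {
    plan <- make_split(fitting_subjects, holdout_fraction = 0, k = k,
                       seed = seeds[r])
    run_task(sub, plan, task = task, spec = spec, features = features,
             threshold = threshold, seed = seeds[r])$pooled
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$rep <- seq_len(n_reps)
  out
}
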