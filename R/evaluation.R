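#' Subject-level hold-out + k-fold split plan
#'
#' Partitions subjects (never individual samples) into a hold-out set
#' and k cross-validation folds, so that all samples of a subject share
#' one assignment and no subject can leak between train and test. The
#' hold-out size rounds up: `ceil(0.2 * 51) = 11` held-out subjects with
#' 40 left for fitting.
#'
#' @param subjects character vector of subject IDs.
#' @param holdout_fraction fraction of subjects set aside, rounded up.
#' @param k number of CV folds over the remaining (fitting) subjects.
#' @param seed shuffle seed.
#' @return Object of class `split_plan`: `holdout_subjects`, `folds`
#'   (named integer vector mapping each fitting subject to its fold),
#'   `k`, `seed`. Fold sizes differ by at most one.
#' @export
make_split <- function(subjects, holdout_fraction = 0.2, k = 5, seed = 1L) {
  n <- length(subjects)
  n_hold <- ceiling(holdout_fraction * n)
  if (k > n - n_hold)
    stop(sprintf("k = %d exceeds the %d fitting subjects", k, n - n_hold))
  shuffled <- with_seed(seed, sample(subjects))
  holdout <- shuffled[seq_len(n_hold)]
  fitting <- shuffled[setdiff(seq_len(n), seq_len(n_hold))]
  folds <- rep_len(seq_len(k), length(fitting))
  names(folds) <- fitting
  structure(list(holdout_subjects = holdout, folds = folds,
                 k = as.integer(k), seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d hold-out subjects, %d fitting subjects in %d folds\n",
              length(x$holdout_subjects), length(x$folds), x$k))
  invisible(x)
}

#' Rating-stratified error metrics
#'
#' Computes RMSE or MAE separately within each observed level of `y`
#' and averages the per-level values with equal weight, so that
#' imbalanced rating levels do not dominate the score.
#'
#' @param y true ratings (ordinal levels).
#' @param yhat predictions.
#' @param metric `"rmse"` or `"mae"`.
#' @return The stratified metric value.
#' @export
stratified_metric <- function(y, yhat, metric = c("rmse", "mae")) {
  metric <- match.arg(metric)
  if (length(y) == 0L || length(y) != length(yhat))
    stop("y and yhat must be equal-length and non-empty")
  err <- y - yhat
  per_level <- tapply(err, y, function(e) {
    if (metric == "rmse") sqrt(mean(e^2)) else mean(abs(e))
  })
  mean(per_level)
}

#' Pooled Pearson correlation between ratings and predictions
#'
#' Computed on the pooled pairs (not stratified: within a single rating
#' level the true values are constant and a within-level correlation is
#' undefined).
#'
#' @param y true values (non-constant).
#' @param yhat predictions (non-constant).
#' @return Pearson r.
#' @export
pearson_metric <- function(y, yhat) {
  if (stats::var(y) == 0 || stats::var(yhat) == 0)
    stop("Pearson correlation is undefined for a constant vector")
  stats::cor(y, yhat)
}

# Midrank (tie-aware) AUC-ROC: the normalized Mann-Whitney U statistic.
auc_roc_value <- function(labels, scores) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # average ranks on ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Step-integrated area under the precision-recall curve (average
# precision over unique score thresholds, descending).
auc_pr_value <- function(labels, scores) {
  n1 <- sum(labels == 1L)
  if (n1 == 0L || all(labels == 1L)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab == 1L)
  fp <- cumsum(lab == 0L)
  last <- !duplicated(sc, fromLast = TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Binary classification metric suite
#'
#' Accuracy, precision and F1 at a decision threshold (predicted
#' positive iff `score >= threshold`), plus threshold-free AUC-ROC
#' (midrank / Mann-Whitney) and AUC-PR (precision-recall step
#' integration). AUCs are reported as `NA` when only one class is
#' present.
#'
#' @param labels 0/1 vector (1 = positive class).
#' @param scores real-valued classifier scores.
#' @param threshold decision threshold.
#' @return Named list: `accuracy`, `precision`, `f1`, `auc_roc`,
#'   `auc_pr`, `n`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(accuracy = mean(pred == labels),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
       auc_roc = auc_roc_value(labels, scores),
       auc_pr = auc_pr_value(labels, scores),
       n = length(labels))
}

#' ROC curve points
#'
#' Staircase ROC coordinates over all score thresholds, from (0, 0) to
#' (1, 1), suitable for plotting or TSV export.
#'
#' @param labels 0/1 vector.
#' @param scores classifier scores.
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  last <- !duplicated(sc, fromLast = TRUE)
  tp <- cumsum(lab == 1L)[last]
  fp <- cumsum(lab == 0L)[last]
  data.frame(threshold = c(Inf, sc[last]),
             fpr = c(0, fp / n0),
             tpr = c(0, tp / n1))
}

#' Per-subject extreme-craving extraction
#'
#' For one subject's blocks, finds the first occurrence (in block
#' order) of the minimum self-reported rating and the first occurrence
#' of the maximum. Subjects whose ratings never vary are flagged
#' degenerate (both extremes point at the first block).
#'
#' @param rating the subject's ratings.
#' @param block_index 0-based block positions aligned with `rating`
#'   (defaults to input order).
#' @return List: `min_at`, `max_at` (indices into the input vectors),
#'   `min_rating`, `max_rating`, `degenerate`.
#' @export
extract_extremes <- function(rating,
                             block_index = seq_along(rating) - 1L) {
  if (length(rating) == 0L) stop("at least one sample required")
  ord <- order(block_index)
  r <- rating[ord]
  min_at <- ord[which(r == min(r))[1L]]
  max_at <- ord[which(r == max(r))[1L]]
  list(min_at = min_at, max_at = max_at,
       min_rating = rating[min_at], max_rating = rating[max_at],
       degenerate = rating[min_at] == rating[max_at])
}
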