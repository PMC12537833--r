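#' Reduce a cohort to per-subject extreme-craving samples
#'
#' Implements the high/low craving framing: for every subject, only the
#' first-occurring minimum-rating block (labeled low = 0) and the
#' first-occurring maximum-rating block (labeled high = 1) are kept.
#' Subjects whose ratings never vary are dropped entirely, so the
#' retained labels are exactly balanced by construction.
#'
#' @param cohort a `crave_cohort`.
#' @return List: `cohort` (the extreme-sample sub-cohort, two rows per
#'   retained subject, min before max), `labels` (0/1 aligned with its
#'   rows), `dropped_subjects` (degenerate subject IDs).
#' @export
binarize_craving <- function(cohort) {
  sid <- cohort$meta$subject_id
  rows <- integer(0)
  labels <- integer(0)
  dropped <- character(0)
  for (s in unique(sid)) {
    idx <- which(sid == s)
    ex <- extract_extremes(cohort$meta$rating[idx],
                           cohort$meta$block_index[idx])
    if (ex$degenerate) {
      dropped <- c(dropped, s)
    } else {
      rows <- c(rows, idx[ex$min_at], idx[ex$max_at])
      labels <- c(labels, 0L, 1L)
    }
  }
  if (length(rows) == 0L)
    stop("every subject has constant ratings; no extremes to classify")
  list(cohort = subset_cohort(cohort, rows), labels = labels,
       dropped_subjects = dropped)
}

#' F1-optimal decision threshold
#'
#' Scans all midpoints between consecutive sorted unique prediction
#' values (plus one candidate below the minimum and one above the
#' maximum) and returns the threshold maximizing the F1 score of the
#' positive class, with predicted positive defined as
#' `yhat >= threshold`. Ties resolve to the lowest threshold.
#'
#' @param yhat real-valued predictions (typically the regression output
#'   on training data of a CV iteration).
#' @param labels 0/1 labels; both classes must be present.
#' @return Object of class `threshold_result`: `threshold`,
#'   `f1_at_threshold`, `search_grid`.
#' @export
optimize_threshold <- function(yhat, labels) {
  stopifnot(length(yhat) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to optimize a threshold")
  u <- sort(unique(yhat))
  grid <- c(u[1L] - 1,
            if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
            u[length(u)] + 1)
  f1 <- vapply(grid, function(t)
    classification_metrics(labels, yhat, t)$f1, numeric(1))
  best <- which.max(f1)  # which.max takes the first (lowest) on ties
  structure(list(threshold = grid[best], f1_at_threshold = f1[best],
                 search_grid = grid),
            class = "threshold_result")
}

#' Map cue-type regression output to neutral/drug labels
#'
#' @param yhat regression predictions of the 0/1 cue code.
#' @param threshold decision threshold (default 0.5; a prediction
#'   exactly at the threshold maps to drug).
#' @return Integer labels, 0 = neutral, 1 = drug.
#' @export
classify_cue <- function(yhat, threshold = 0.5) {
  as.integer(yhat >= threshold)
}
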