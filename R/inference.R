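#' Pair an observed metric distribution with its permutation null
#'
#' @param metric metric name (e.g., `"rmse"`).
#' @param observed numeric vector of repeated-CV metric values.
#' @param null numeric vector of permutation-null metric values.
#' @param better `"lower"` (errors) or `"higher"` (correlations, AUCs,
#'   accuracy); defaults by metric name.
#' @return Object of class `metric_distribution`.
#' @export
metric_distribution <- function(metric, observed, null,
                                better = NULL) {
  if (is.null(better))
    better <- if (metric %in% c("rmse", "mae")) "lower" else "higher"
  better <- match.arg(better, c("lower", "higher"))
  observed <- observed[is.finite(observed)]
  null <- null[is.finite(null)]
  if (length(observed) == 0L || length(null) == 0L)
    stop("observed and null must be non-empty")
  structure(list(metric = metric, observed = observed, null = null,
                 better = better),
            class = "metric_distribution")
}

#' Permutation-null metric distribution for one task
#'
#' Repeatedly shuffles the target labels across all fitting samples
#' (features untouched), re-runs the full subject-level CV evaluation,
#' and records the pooled metrics of each permutation — the
#' distribution of outcomes under the null hypothesis of no
#' association between brain activity and the target.
#'
#' When the reducer is PCA the fold-wise variance filter, scaler and
#' projection do not depend on the target, so they are computed once
#' and only the regressor is refit per permutation (for plain least
#' squares via a precomputed QR decomposition); this is an exact
#' optimization, not an approximation. ANOVA reduction is re-fit per
#' permutation.
#'
#' @inheritParams run_task
#' @param fitting_subjects subjects entering the null CV; defaults to
#'   all cohort subjects.
#' @param n_perm number of permutations.
#' @param k folds.
#' @param within_subject if `TRUE`, shuffle labels within each
#'   subject's samples instead of across the whole fitting set.
#' @return Data frame, one row per permutation, columns = task
#'   metrics.
#' @export
permutation_null <- function(cohort, fitting_subjects = NULL,
                             task = TASKS, n_perm = 1000, k = 5,
                             spec = regressor_spec("ols"),
                             features = NULL, threshold = 0.5,
                             seed = 1L, within_subject = FALSE) {
  task <- match.arg(task)
  stopifnot(n_perm >= 1)
  if (is.null(fitting_subjects))
    fitting_subjects <- cohort_subjects(cohort)
  sub <- subset_cohort(cohort,
                       cohort$meta$subject_id %in% fitting_subjects)
  feat <- task_features(task, features)
  td <- task_data(sub, task)
  plan <- make_split(fitting_subjects, holdout_fraction = 0, k = k,
                     seed = seed)
  sid <- td$cohort$meta$subject_id
  folds <- fold_assignments(sid, td_plan_check(plan))
  n <- nrow(td$cohort$meta)
  fast <- feat$method == "pca"
  prep <- NULL
  if (fast) {
    prep <- lapply(folds, function(fa) {
      reducer <- fit_reducer(td$cohort$X[fa$rows_train, , drop = FALSE],
                             method = "pca",
                             n_components = feat$n_components,
                             variance_threshold = feat$variance_threshold)
      s_tr <- predict(reducer, td$cohort$X[fa$rows_train, , drop = FALSE])
      s_te <- predict(reducer, td$cohort$X[fa$rows_test, , drop = FALSE])
      list(s_tr = s_tr, s_te = s_te,
           qr = if (spec$family == "ols") qr(cbind(1, s_tr)))
    })
  }
  seeds <- child_seeds(seed, n_perm)
  out <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    perm <- with_seed(seeds[p], {
      if (within_subject) {
        idx <- seq_len(n)
        unlist(lapply(split(idx, sid), sample), use.names = FALSE)[
          order(unlist(split(idx, sid), use.names = FALSE))]
      } else sample(n)
    })
    yp <- td$y[perm]
    lp <- if (!is.null(td$labels)) td$labels[perm]
    oof <- vector("list", plan$k)
    for (j in seq_len(plan$k)) {
      fa <- folds[[j]]
      if (length(fa$rows_test) == 0L) next
      y_tr <- yp[fa$rows_train]
      if (fast) {
        pj <- prep[[j]]
        if (spec$family == "ols" && stats::var(y_tr) > 0) {
          cf <- qr.coef(pj$qr, y_tr)
          yhat_te <- drop(cbind(1, pj$s_te) %*% cf)
          yhat_tr <- if (task == "classify_craving")
            drop(cbind(1, pj$s_tr) %*% cf)
        } else {
          model <- fit_regressor(spec, pj$s_tr, y_tr, seed = seeds[p])
          yhat_te <- predict(model, pj$s_te)
          yhat_tr <- if (task == "classify_craving")
            predict(model, pj$s_tr)
        }
      } else {
        pipe <- fit_pipeline(td$cohort$X[fa$rows_train, , drop = FALSE],
                             y_tr, spec = spec, method = feat$method,
                             n_components = feat$n_components,
                             k_best = feat$k_best,
                             variance_threshold = feat$variance_threshold,
                             seed = seeds[p])
        yhat_te <- predict(pipe, td$cohort$X[fa$rows_test, , drop = FALSE])
        yhat_tr <- if (task == "classify_craving")
          predict(pipe, td$cohort$X[fa$rows_train, , drop = FALSE])
      }
      o <- data.frame(y = yp[fa$rows_test], yhat = yhat_te)
      if (task == "classify_craving") {
        thr <- optimize_threshold(yhat_tr, lp[fa$rows_train])$threshold
        o$label <- lp[fa$rows_test]
        o$pred <- as.integer(yhat_te >= thr)
      } else if (task == "classify_cue") {
        o$label <- lp[fa$rows_test]
        o$pred <- classify_cue(yhat_te, threshold)
      }
      oof[[j]] <- o
    }
    out[[p]] <- task_pooled_metrics(task, do.call(rbind, oof))
  }
  res <- as.data.frame(do.call(rbind, out))
  res$perm <- seq_len(n_perm)
  res
}

# permutation CV has no hold-out by construction; keep the assertion
# in fold_assignments honest by passing the plan through unchanged.
td_plan_check <- function(plan) plan

#' Permutation p-value (add-one rule)
#'
#' `p = (1 + #\{null at least as good as the observed mean\}) /
#' (1 + n_null)`, where "as good" respects the metric's better
#' direction. The add-one rule keeps p strictly positive.
#'
#' @param dist a [metric_distribution()].
#' @return The p-value.
#' @export
perm_p_value <- function(dist) {
  stopifnot(inherits(dist, "metric_distribution"))
  obs <- mean(dist$observed)
  hits <- if (dist$better == "lower") sum(dist$null <= obs)
          else sum(dist$null >= obs)
  (1 + hits) / (1 + length(dist$null))
}

#' Statistical power by counting from the null's critical value
#'
#' The critical value is the alpha-tail quantile of the null
#' distribution in the better direction; power is the fraction of the
#' observed distribution beyond it. When observed and null coincide,
#' power is approximately alpha by construction.
#'
#' @param dist a [metric_distribution()].
#' @param alpha significance level.
#' @return Power in `[0, 1]`.
#' @export
perm_power <- function(dist, alpha = 0.05) {
  stopifnot(inherits(dist, "metric_distribution"))
  if (dist$better == "lower") {
    crit <- stats::quantile(dist$null, alpha, names = FALSE)
    mean(dist$observed <= crit)
  } else {
    crit <- stats::quantile(dist$null, 1 - alpha, names = FALSE)
    mean(dist$observed >= crit)
  }
}

#' Cliff's delta effect size
#'
#' Net proportion of pairwise wins,
#' `(#\{a > b\} - #\{a < b\}) / (|A| * |B|)`, in `[-1, 1]`. Robust to
#' any strictly monotone transform of both samples.
#'
#' @param a,b numeric samples.
#' @return Cliff's delta.
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  sb <- sort(b)
  # #{b < a_i} and #{b <= a_i} via binary search on the sorted sample
  n_lt <- findInterval(a, sb, left.open = TRUE)
  n_le <- findInterval(a, sb)
  (sum(n_lt) - sum(length(b) - n_le)) / (length(a) * length(b))
}

#' Cohen's d effect size
#'
#' Mean difference standardized by the (n-1)-weighted pooled SD.
#'
#' @param a,b numeric samples.
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                   (na + nb - 2))
  if (!is.finite(pooled) || pooled == 0)
    stop("pooled SD is zero; Cohen's d undefined")
  (mean(a) - mean(b)) / pooled
}

#' Normality gate for the effect-size / CI method choice
#'
#' Shapiro-Wilk at alpha = 0.05: a normal-looking distribution gets
#' Cohen's d with a Student-t confidence interval; otherwise Cliff's
#' delta with a percentile-bootstrap interval.
#'
#' @param x numeric vector (3 to 5000 values).
#' @param alpha gate level.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3L) stop("need at least 3 values")
  if (stats::var(x) == 0) stop("normality undefined for a constant vector")
  if (length(x) > 5000L)
    x <- x[round(seq(1, length(x), length.out = 5000L))]
  if (stats::shapiro.test(x)$p.value >= alpha) "parametric"
  else "nonparametric"
}

#' Percentile bootstrap CI of the mean
#'
#' @param x numeric vector.
#' @param n_boot bootstrap resamples.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return Length-2 vector `(lo, hi)`.
#' @export
bootstrap_ci <- function(x, n_boot = 1000, level = 0.95, seed = 1L) {
  if (length(x) < 2L) stop("need at least 2 values")
  means <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    mean(x[sample.int(length(x), replace = TRUE)]), numeric(1)))
  unname(stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

t_ci <- function(x, level = 0.95) {
  se <- stats::sd(x) / sqrt(length(x))
  mean(x) + c(-1, 1) * stats::qt(1 - (1 - level) / 2, length(x) - 1) * se
}

#' Assemble one statistical report row
#'
#' Combines an observed/null metric pair into the full reporting row:
#' mean, SD, 95% CI, permutation p-value, effect size (Cohen's d with a
#' t CI if the observed distribution passes the Shapiro-Wilk gate,
#' otherwise Cliff's delta with a bootstrap CI), counting power, and
#' the out-of-sample value. Effect sizes are oriented so that a model
#' performing better than its null has positive sign, regardless of
#' whether the metric is lower- or higher-better.
#'
#' @param dist a [metric_distribution()].
#' @param out_of_sample hold-out value of the metric (or `NA`).
#' @param alpha significance level for power.
#' @param n_boot bootstrap resamples for the nonparametric CI.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `stat_report` (also a one-row data frame).
#' @export
stat_report <- function(dist, out_of_sample = NA_real_, alpha = 0.05,
                        n_boot = 1000, seed = 1L) {
  stopifnot(inherits(dist, "metric_distribution"))
  obs <- dist$observed
  gate <- tryCatch(normality_gate(obs), error = function(e) "nonparametric")
  if (gate == "parametric") {
    ci <- t_ci(obs)
    eff <- if (dist$better == "higher") cohens_d(obs, dist$null)
           else cohens_d(dist$null, obs)
    eff_type <- "cohens_d"
  } else {
    ci <- if (stats::var(obs) == 0) c(obs[1L], obs[1L])
          else bootstrap_ci(obs, n_boot = n_boot, seed = seed)
    eff <- if (dist$better == "higher") cliffs_delta(obs, dist$null)
           else cliffs_delta(dist$null, obs)
    eff_type <- "cliffs_delta"
  }
  out <- data.frame(
    metric = dist$metric, mean = mean(obs), sd = stats::sd(obs),
    ci_lo = ci[1], ci_hi = ci[2], p_value = perm_p_value(dist),
    effect_size = eff, effect_type = eff_type,
    power = perm_power(dist, alpha), out_of_sample = out_of_sample,
    stringsAsFactors = FALSE)
  class(out) <- c("stat_report", class(out))
  out
}

#' Statistical report table for a whole task
#'
#' One [stat_report()] row per metric, pairing the repeated-CV
#' observed distributions with the permutation null.
#'
#' @param observed data frame from [repeated_task()].
#' @param null data frame from [permutation_null()] (same task).
#' @param out_of_sample named metric vector from
#'   [evaluate_holdout_task()] (optional).
#' @param ... passed to [stat_report()].
#' @return Data frame with one row per metric.
#' @export
report_table <- function(observed, null, out_of_sample = NULL, ...) {
  metrics <- setdiff(intersect(names(observed), names(null)),
                     c("rep", "perm"))
  rows <- lapply(metrics, function(m) {
    dist <- metric_distribution(m, observed[[m]], null[[m]])
    oos <- if (!is.null(out_of_sample) && m %in% names(out_of_sample))
      unname(out_of_sample[[m]]) else NA_real_
    stat_report(dist, out_of_sample = oos, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
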