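REGRESSOR_FAMILIES <- c("ols", "ridge", "lasso", "elastic_net",
                        "random_forest", "gradient_boosting")

#' Specify a regression estimator
#'
#' The estimator menu spans a baseline multivariate linear regression,
#' the L2/L1/mixed penalized linear families, and two tree ensembles
#' (random forest and gradient-boosted trees). Penalized linear families
#' solve the usual elastic-net objective
#' `(1/2n)||y - b0 - S B||^2 + penalty * P_alpha(B)` with
#' `alpha = l1_ratio` (1 for lasso, 0 for ridge).
#'
#' @param family one of `"ols"`, `"ridge"`, `"lasso"`, `"elastic_net"`,
#'   `"random_forest"`, `"gradient_boosting"`.
#' @param penalty regularization strength (penalized linear families).
#' @param l1_ratio elastic-net mixing in `[0, 1]`.
#' @param n_estimators trees in an ensemble.
#' @param max_depth tree depth; `NULL` lets the ensemble grow freely
#'   (random forest) or uses the booster default (gradient boosting).
#' @param learning_rate shrinkage for gradient boosting.
#' @return An object of class `regressor_spec`.
#' @export
regressor_spec <- function(family = REGRESSOR_FAMILIES,
                           penalty = 1, l1_ratio = 0.5,
                           n_estimators = 200, max_depth = NULL,
                           learning_rate = 0.1) {
  family <- match.arg(family)
  if (penalty < 0) stop("penalty must be >= 0")
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must be in [0, 1]")
  if (n_estimators < 1) stop("n_estimators must be >= 1")
  structure(list(family = family, penalty = penalty, l1_ratio = l1_ratio,
                 n_estimators = as.integer(n_estimators),
                 max_depth = max_depth, learning_rate = learning_rate),
            class = "regressor_spec")
}

glmnet_alpha <- function(spec) {
  switch(spec$family, ridge = 0, lasso = 1, elastic_net = spec$l1_ratio)
}

#' Fit a regressor on reduced-space scores
#'
#' @param spec a [regressor_spec()].
#' @param scores samples x components matrix from the feature reducer.
#' @param y numeric target (craving rating, or the 0/1 cue code).
#' @param seed RNG seed for the stochastic tree families.
#' @return Object of class `crave_regressor` carrying, for linear
#'   families, the coefficient vector `B` and intercept `b0`.
#' @export
fit_regressor <- function(spec, scores, y, seed = 1L) {
  stopifnot(inherits(spec, "regressor_spec"))
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y)) stop("rows(scores) must equal length(y)")
  out <- list(spec = spec)
  if (stats::var(y) == 0) {
    # constant target: every family degenerates to the constant predictor
    out$B <- rep(0, ncol(scores))
    out$b0 <- y[1L]
    out$constant <- TRUE
    return(structure(out, class = "crave_regressor"))
  }
  if (spec$family == "ols") {
    qr_x <- qr(cbind(1, scores))
    if (qr_x$rank < ncol(scores) + 1L)
      stop("singular design in exact least squares; reduce components")
    cf <- qr.coef(qr_x, y)
    out$b0 <- cf[1L]
    out$B <- cf[-1L]
  } else if (spec$family %in% c("ridge", "lasso", "elastic_net")) {
    fit <- glmnet::glmnet(scores, y, alpha = glmnet_alpha(spec),
                          lambda = spec$penalty, standardize = FALSE,
                          thresh = 1e-10)
    cf <- as.vector(stats::coef(fit, s = spec$penalty))
    out$b0 <- cf[1L]
    out$B <- cf[-1L]
  } else if (spec$family == "random_forest") {
    # rating targets have <= 4 unique values by design; regression on an
    # ordinal target is intended, so muffle randomForest's advisory
    out$fit <- with_seed(seed, withCallingHandlers(
      randomForest::randomForest(
        x = scores, y = y, ntree = spec$n_estimators,
        maxnodes = if (!is.null(spec$max_depth)) 2L^spec$max_depth else NULL),
      warning = function(w) {
        if (grepl("five or fewer unique values", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }))
  } else {  # gradient_boosting
    out$fit <- xgboost::xgboost(
      scores, y, nrounds = spec$n_estimators,
      max_depth = spec$max_depth, learning_rate = spec$learning_rate,
      nthreads = 1L, seed = seed %% .Machine$integer.max, verbosity = 0L)
  }
  structure(out, class = "crave_regressor")
}

#' @export
predict.crave_regressor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$B)) {
    drop(newdata %*% object$B + object$b0)
  } else {
    as.numeric(stats::predict(object$fit, newdata))
  }
}

#' Fit the full reduction + regression pipeline
#'
#' Convenience wrapper: fits the feature reducer on the training matrix,
#' projects it, and fits the regressor on the scores. The returned
#' object carries everything needed to predict new raw beta maps and,
#' for PCA + linear fits, to back-project the model into voxel space
#' (see [back_project()]).
#'
#' @param X training samples x voxels matrix (full voxel count).
#' @param y numeric target aligned with the rows of `X`.
#' @param spec a [regressor_spec()].
#' @param method,n_components,k_best,variance_threshold passed to
#'   [fit_reducer()].
#' @param train_subjects optional identifiers of the training subjects,
#'   recorded for leakage audits.
#' @param seed seed for stochastic regressors.
#' @return Object of class `crave_pipeline`.
#' @export
fit_pipeline <- function(X, y, spec = regressor_spec("ols"),
                         method = "pca", n_components = 100, k_best = 100,
                         variance_threshold = 0.001,
                         train_subjects = NULL, seed = 1L) {
  reducer <- fit_reducer(X, y = y, method = method,
                         n_components = n_components, k_best = k_best,
                         variance_threshold = variance_threshold)
  scores <- predict(reducer, X)
  model <- fit_regressor(spec, scores, y, seed = seed)
  structure(list(reducer = reducer, model = model, spec = spec,
                 train_subjects = train_subjects),
            class = "crave_pipeline")
}

#' Predict raw beta maps with a fitted pipeline
#'
#' @param object a `crave_pipeline`.
#' @param newdata samples x voxels matrix (full voxel count), or a
#'   `crave_cohort` whose `X` is used.
#' @param ... unused.
#' @return Numeric predictions, one per sample. The raw regression
#'   output is returned unclipped: threshold mapping for the binary
#'   tasks happens downstream.
#' @export
predict.crave_pipeline <- function(object, newdata, ...) {
  if (inherits(newdata, "crave_cohort")) newdata <- newdata$X
  predict(object$model, predict(object$reducer, newdata))
}

candidate_label <- function(cand) {
  sz <- if (identical(cand$features$method, "anova"))
    cand$features$k_best else cand$features$n_components
  sprintf("%s%d+%s", cand$features$method, as.integer(sz),
          cand$spec$family)
}

#' Default feature-selection x regressor candidate grid
#'
#' Builds the cross-product of feature-selection configurations and
#' regressor specifications evaluated during model selection: PCA and
#' ANOVA reductions at the given sizes, crossed with the full estimator
#' menu at the default hyperparameter grids (penalties 0.01/0.1/1/10,
#' elastic-net mixing 0.25/0.5/0.75, 200-tree ensembles at depth 3 and
#' unlimited).
#'
#' @param methods feature-selection methods to include.
#' @param sizes component counts (PCA) / kept-column counts (ANOVA).
#' @param families regressor families to include.
#' @param penalties,l1_ratios,max_depths hyperparameter grids.
#' @return List of candidates, each `list(features = ..., spec = ...)`.
#' @export
default_candidates <- function(methods = c("pca", "anova"),
                               sizes = c(50, 100),
                               families = REGRESSOR_FAMILIES,
                               penalties = c(0.01, 0.1, 1, 10),
                               l1_ratios = c(0.25, 0.5, 0.75),
                               max_depths = list(3L, NULL)) {
  out <- list()
  for (m in methods) for (sz in sizes) {
    feat <- if (m == "pca") list(method = "pca", n_components = sz)
            else list(method = "anova", k_best = sz)
    for (fam in families) {
      specs <- switch(fam,
        ols = list(regressor_spec("ols")),
        ridge = lapply(penalties, function(p) regressor_spec("ridge", penalty = p)),
        lasso = lapply(penalties, function(p) regressor_spec("lasso", penalty = p)),
        elastic_net = {
          grid <- expand.grid(p = penalties, a = l1_ratios)
          lapply(seq_len(nrow(grid)), function(i)
            regressor_spec("elastic_net", penalty = grid$p[i],
                           l1_ratio = grid$a[i]))
        },
        random_forest = lapply(max_depths, function(d)
          regressor_spec("random_forest", max_depth = d)),
        gradient_boosting = lapply(max_depths[!vapply(max_depths, is.null,
                                                      logical(1))],
                                   function(d)
          regressor_spec("gradient_boosting", max_depth = d)))
      out <- c(out, lapply(specs, function(s) list(features = feat, spec = s)))
    }
  }
  out
}

#' Select the best pipeline configuration by cross-validated RMSE
#'
#' Scores every candidate (feature-selection configuration x regressor
#' specification) by subject-level k-fold cross-validation on the
#' fitting cohort, using the stratified RMSE as the selection metric,
#' and returns the candidate with the lowest mean CV RMSE. Ties are
#' broken deterministically: fewer components first, then the simpler
#' family in menu order. Candidates that are invalid for the data size
#' (e.g., more components than training samples) are marked failed with
#' the reason, never silently dropped.
#'
#' @param candidates list of `list(features = ..., spec = ...)`
#'   candidates, e.g., from [default_candidates()].
#' @param cohort fitting `crave_cohort` (hold-out already removed).
#' @param target `"rating"` or `"cue"`.
#' @param k folds.
#' @param seed seed controlling the CV split and stochastic fits.
#' @return Object of class `grid_result`: `table` (one row per
#'   candidate: label, mean CV RMSE, status), `winner` (index),
#'   `candidates`.
#' @export
grid_search <- function(candidates, cohort, target = c("rating", "cue"),
                        k = 5, seed = 1L) {
  target <- match.arg(target)
  stopifnot(length(candidates) >= 1)
  plan <- make_split(cohort_subjects(cohort), holdout_fraction = 0,
                     k = k, seed = seed)
  res <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    cv <- tryCatch(
      run_cv(cohort, plan, target = target, spec = cand$spec,
             features = cand$features, seed = seed),
      error = function(e) e)
    if (inherits(cv, "error")) {
      list(rmse = NA_real_, status = paste("failed:",
                                           conditionMessage(cv)))
    } else {
      list(rmse = mean(cv$fold_metrics$rmse), status = "ok")
    }
  })
  rmse <- vapply(res, `[[`, numeric(1), "rmse")
  size <- vapply(candidates, function(cand)
    as.numeric(if (identical(cand$features$method, "anova"))
      cand$features$k_best else cand$features$n_components), numeric(1))
  fam_rank <- vapply(candidates, function(cand)
    match(cand$spec$family, REGRESSOR_FAMILIES), numeric(1))
  ok <- which(!is.na(rmse))
  if (length(ok) == 0L) stop("every candidate failed")
  winner <- ok[order(rmse[ok], size[ok], fam_rank[ok])][1L]
  structure(list(
    table = data.frame(
      candidate = vapply(candidates, candidate_label, character(1)),
      cv_rmse = rmse,
      status = vapply(res, `[[`, character(1), "status"),
      stringsAsFactors = FALSE),
    winner = winner,
    candidates = candidates,
    seed = seed
  ), class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("grid_search over", nrow(x$table), "candidates; winner:",
      x$table$candidate[x$winner],
      sprintf("(CV RMSE %.4f)\n", x$table$cv_rmse[x$winner]))
  invisible(x)
}
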