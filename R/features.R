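#' Variance filter over voxel columns
#'
#' Identifies the feature columns whose unbiased sample variance meets
#' the threshold. With sparse beta maps this removes, at minimum, every
#' out-of-mask (all-zero) voxel and any constant column.
#'
#' @param X samples x voxels matrix (>= 2 rows).
#' @param threshold minimum retained variance (default 0.001).
#' @return Integer vector of kept column indices (ascending).
#' @export
fit_variance_filter <- function(X, threshold = 0.001) {
  if (nrow(X) < 2L) stop("variance requires at least 2 samples")
  n <- nrow(X)
  cm <- colMeans(X)
  v <- (colSums(X^2) - n * cm^2) / (n - 1)
  which(v >= threshold)
}

# Economy PCA of a (pre-scaled) matrix: when n < p the eigendecomposition
# of the n x n Gram matrix is used instead of a direct SVD of the n x p
# matrix; the two are algebraically identical.
pca_components <- function(Xs, n_components) {
  n <- nrow(Xs); p <- ncol(Xs)
  if (n <= p) {
    e <- eigen(tcrossprod(Xs), symmetric = TRUE)
    pos <- e$values > max(e$values, 0) * 1e-12
    d <- sqrt(pmax(e$values, 0))
    k <- min(n_components, sum(pos))
    V <- crossprod(Xs, e$vectors[, seq_len(k), drop = FALSE]) /
      rep(d[seq_len(k)], each = p)
  } else {
    s <- svd(Xs, nu = 0, nv = n_components)
    d <- s$d
    k <- min(n_components, sum(d > max(d, 0) * 1e-12))
    V <- s$v[, seq_len(k), drop = FALSE]
  }
  # fix the sign of each component: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  list(V = V, sdev = d[seq_len(ncol(V))] / sqrt(n - 1))
}

# Vectorized one-way ANOVA F statistic per column, grouping rows by g.
anova_f_stats <- function(X, g) {
  g <- as.factor(g)
  counts <- table(g)
  if (any(counts < 2L))
    stop("every grouping level needs >= 2 samples for ANOVA selection")
  n <- nrow(X); k <- nlevels(g)
  grand <- colMeans(X)
  G <- rowsum(X, g)                      # level sums, k x p
  means <- G / as.vector(counts)
  ss_between <- colSums(as.vector(counts) * (t(t(means) - grand))^2)
  ss_total <- colSums(X^2) - n * grand^2
  ss_within <- pmax(ss_total - ss_between, 0)
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Fit the feature-reduction stage on training data
#'
#' The reduction is a fixed sequence fit on training samples only:
#' (1) drop columns with sample variance below `variance_threshold`;
#' (2) standardize each kept column to zero mean and unit SD;
#' (3) either project onto the leading principal components of the
#' standardized training matrix (`method = "pca"`, eigenvector matrix
#' `V` with orthonormal columns sorted by descending explained
#' variance), or keep the `k_best` columns with the largest one-way
#' ANOVA F statistic of the betas grouped by craving-rating level
#' (`method = "anova"`).
#'
#' Component signs are fixed by forcing the largest-magnitude loading of
#' each component to be positive, so repeated fits on identical data
#' produce bit-identical projections (and hence reproducible signature
#' maps).
#'
#' @param X training samples x voxels matrix (full voxel count).
#' @param y ratings (or other grouping labels); required for
#'   `method = "anova"`, ignored for PCA.
#' @param method `"pca"` or `"anova"`.
#' @param n_components number of principal components (PCA); capped at
#'   `min(n_train - 1, n_kept)`.
#' @param k_best number of columns kept by ANOVA selection.
#' @param variance_threshold variance-filter cutoff.
#' @return An object of class `feature_reducer`.
#' @export
fit_reducer <- function(X, y = NULL, method = c("pca", "anova"),
                        n_components = 100, k_best = 100,
                        variance_threshold = 0.001) {
  method <- match.arg(method)
  kept <- fit_variance_filter(X, variance_threshold)
  if (length(kept) == 0L) stop("variance filter removed every column")
  Xk <- X[, kept, drop = FALSE]
  n <- nrow(Xk)
  mu <- colMeans(Xk)
  sigma <- sqrt((colSums(Xk^2) - n * mu^2) / (n - 1))
  stopifnot(all(sigma > 0))  # guaranteed by the filter threshold > 0
  Xs <- t((t(Xk) - mu) / sigma)
  out <- list(variance_threshold = variance_threshold, kept = kept,
              mu = mu, sigma = sigma, method = method, n_train = n,
              n_voxels = ncol(X))
  if (method == "pca") {
    max_k <- min(n - 1L, length(kept))
    if (n_components > max_k)
      stop(sprintf("n_components (%d) exceeds min(n-1, p) = %d",
                   as.integer(n_components), max_k))
    pc <- pca_components(Xs, n_components)
    out$n_components <- ncol(pc$V)
    out$V <- pc$V
    out$sdev <- pc$sdev
  } else {
    if (is.null(y)) stop("ANOVA selection needs grouping labels y")
    if (k_best > length(kept))
      stop(sprintf("k_best (%d) exceeds the %d columns kept by the filter",
                   as.integer(k_best), length(kept)))
    f <- anova_f_stats(Xs, y)
    out$selected <- sort(order(f, decreasing = TRUE)[seq_len(k_best)])
    out$f_stats <- f
    out$n_components <- as.integer(k_best)
  }
  structure(out, class = "feature_reducer")
}

#' Project samples through a fitted reducer
#'
#' Applies, in order, the training-time column selection, the
#' standardization `(x - mu) / sigma`, and the projection (`V` for PCA,
#' column subset for ANOVA). Never re-fits: transforming held-out data
#' leaves the reducer untouched.
#'
#' @param object a `feature_reducer`.
#' @param newdata samples x voxels matrix with the original full voxel
#'   count.
#' @param ... unused.
#' @return samples x components score matrix.
#' @export
predict.feature_reducer <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  Xs <- t((t(newdata[, object$kept, drop = FALSE]) - object$mu) /
            object$sigma)
  if (object$method == "pca") {
    Xs %*% object$V
  } else {
    Xs[, object$selected, drop = FALSE]
  }
}

#' @export
print.feature_reducer <- function(x, ...) {
  cat(sprintf(
    "feature_reducer: %s, %d columns kept (var >= %g), %d components\n",
    x$method, length(x$kept), x$variance_threshold, x$n_components))
  invisible(x)
}
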