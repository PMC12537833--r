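#' Back-project a fitted PCA + linear pipeline into voxel space
#'
#' Collapses the fitted reduced-space model into a single per-voxel
#' weight vector: the product of the PCA eigenvector matrix `V` and the
#' regression coefficient vector `B`. Two variants are kept:
#'
#' * `vb` — the literal product `V B`, living in the standardized
#'   (z-scored) voxel space; this is the per-voxel contribution vector
#'   used for display and regional summaries.
#' * `vb_raw` — `vb / sigma` (folding in the scaler), valid for dot
#'   products with raw beta maps: together with the adjusted intercept
#'   `b0_adj = b0 - sum(mu * vb / sigma)`, it reproduces the pipeline's
#'   predictions exactly: `yhat = <x_raw, vb_raw> + b0_adj`.
#'
#' Both are returned zero-filled to the full voxel grid (filtered-out
#' and off-mask voxels are exactly zero).
#'
#' @param pipeline a `crave_pipeline` with a PCA reducer and a linear
#'   regressor family.
#' @return Object of class `signature_map`: `vb`, `vb_raw` (full-length
#'   voxel vectors), `b0_adj`, `kept` (column indices carrying weight),
#'   `norm_factor` (1 until [normalize_for_display()] is applied),
#'   `regional_means` (`NULL` until [summarize_by_atlas()]).
#' @export
back_project <- function(pipeline) {
  stopifnot(inherits(pipeline, "crave_pipeline"))
  red <- pipeline$reducer
  if (red$method != "pca")
    stop("back-projection requires a PCA reducer (no V under ANOVA selection)")
  if (is.null(pipeline$model$B))
    stop("back-projection requires a linear regressor family")
  vb_kept <- drop(red$V %*% pipeline$model$B)
  structure(list(
    vb = scatter_to_full(vb_kept, red$kept, red$n_voxels),
    vb_raw = scatter_to_full(vb_kept / red$sigma, red$kept, red$n_voxels),
    b0_adj = pipeline$model$b0 - sum(red$mu * vb_kept / red$sigma),
    kept = red$kept,
    norm_factor = 1,
    regional_means = NULL
  ), class = "signature_map")
}

# Zero-filled full-length vector with values at the kept columns. The
# full length is the largest kept index unless a longer grid is implied
# by the caller; cohorts always index up to their final column because
# callers pass matrices with the full voxel count.
scatter_to_full <- function(values, kept, n = NULL) {
  if (is.null(n)) n <- max(kept)
  out <- numeric(n)
  out[kept] <- values
  out
}

#' Predict raw samples from a signature map (algebraic identity)
#'
#' @param map a `signature_map`.
#' @param X samples x voxels matrix (full voxel count).
#' @return `X vb_raw + b0_adj`; equal to the originating pipeline's
#'   predictions up to float round-off.
#' @export
signature_predict <- function(map, X) {
  v <- map$vb_raw
  if (ncol(X) < length(v)) stop("X has fewer columns than the map")
  drop(X[, seq_along(v), drop = FALSE] %*% v) + map$b0_adj
}

#' Rescale a signature map for visualization
#'
#' Scales the map so that the L2 norm of `vb_raw` equals the norm of a
#' reference map (conventionally the across-sample mean beta map), so
#' that signature values are displayable on the same color scale as the
#' data. Sign pattern and ranking are unchanged; the scale factor is
#' recorded.
#'
#' @param map a `signature_map`.
#' @param reference numeric voxel vector with nonzero norm.
#' @return The rescaled `signature_map` with `norm_factor` set.
#' @export
normalize_for_display <- function(map, reference) {
  ref_norm <- sqrt(sum(reference^2))
  if (ref_norm == 0) stop("reference map has zero norm")
  own <- sqrt(sum(map$vb_raw^2))
  if (own == 0) stop("cannot normalize an all-zero signature")
  f <- ref_norm / own
  map$vb <- map$vb * f
  map$vb_raw <- map$vb_raw * f
  map$norm_factor <- f
  map
}

#' Regional summary of a signature map over a parcellation
#'
#' Assigns each in-mask voxel to its atlas region and averages the
#' per-voxel `vb` contribution within each region, ranked descending
#' for bar-plot display. Regions with no in-mask voxels are reported
#' as missing (`NA` mean), never as zero.
#'
#' @param map a `signature_map`.
#' @param parcellation a `parcellation` (see
#'   [synthetic_parcellation()] / [read_parcellation()]).
#' @param mask logical voxel vector restricting the summary (e.g., the
#'   cohort's brain mask); defaults to all voxels.
#' @return Data frame with `region_id`, `region_name`, `mean_vb`,
#'   `n_voxels`, `rank` (descending by mean, `NA` for empty regions),
#'   sorted by rank.
#' @export
summarize_by_atlas <- function(map, parcellation, mask = NULL) {
  stopifnot(inherits(parcellation, "parcellation"))
  labels <- parcellation$labels
  vb <- map$vb
  if (length(vb) < length(labels))
    vb <- c(vb, numeric(length(labels) - length(vb)))
  if (length(vb) != length(labels))
    stop("map and parcellation grids do not match")
  use <- labels != 0L
  if (!is.null(mask)) use <- use & mask
  if (!any(use)) stop("no overlap between the parcellation and the mask")
  sums <- tapply(vb[use], labels[use], mean)
  ids <- parcellation$region_ids
  means <- unname(sums[as.character(ids)])
  nvox <- unname(tapply(rep(1L, sum(use)), labels[use], sum)[
    as.character(ids)])
  nvox[is.na(nvox)] <- 0L
  out <- data.frame(region_id = ids,
                    region_name = parcellation$region_names,
                    mean_vb = means,
                    n_voxels = as.integer(nvox),
                    stringsAsFactors = FALSE)
  out$rank <- NA_integer_
  present <- !is.na(out$mean_vb)
  out$rank[present] <- rank(-out$mean_vb[present], ties.method = "first")
  out[order(out$rank, na.last = TRUE), , drop = FALSE]
}
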