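#' @importFrom RNifti readNifti writeNifti asNifti
NULL

# Attach an affine as the sform/qform of an RNifti image.
set_affine <- function(img, affine) {
  if (!is.null(affine)) {
    RNifti::`sform<-`(img, structure(affine, code = 2L))
  } else img
}

#' Write a cohort to disk as NIfTI + TSV
#'
#' Serializes a cohort as one 4D NIfTI of beta maps (samples along the
#' 4th axis, voxels in column-major x-fastest order), a 3D brain-mask
#' NIfTI, and a UTF-8 tab-separated metadata table with columns
#' `subject_id`, `block_index`, `cue_type` (0 neutral / 1 drug) and
#' `rating`. Beta volumes are stored at full double precision so a write
#' followed by [read_dataset()] reproduces the cohort bit-exactly.
#'
#' @param cohort a `crave_cohort`.
#' @param dir output directory, created if missing.
#' @return Invisibly, the paths written (`volume`, `metadata`, `mask`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "crave_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(volume = file.path(dir, "betas.nii.gz"),
                metadata = file.path(dir, "metadata.tsv"),
                mask = file.path(dir, "mask.nii.gz"))
  vol <- array(t(cohort$X), dim = c(cohort$dim, nrow(cohort$X)))
  writeNifti(set_affine(asNifti(vol, datatype = "double"), cohort$affine),
             paths$volume)
  writeNifti(set_affine(asNifti(array(as.integer(cohort$mask),
                                      dim = cohort$dim),
                                datatype = "uint8"), cohort$affine),
             paths$mask)
  utils::write.table(cohort$meta, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Read a beta-map dataset from NIfTI + TSV
#'
#' Loads a 4D beta-coefficient volume and its per-sample metadata into a
#' `crave_cohort`. Each 3D volume along the 4th axis is flattened into
#' one row of the feature matrix in column-major (x-fastest) voxel
#' order; this ordering is fixed so signature maps are comparable across
#' runs. If no mask is supplied, the mask is taken as the voxels that
#' are nonzero in at least one sample.
#'
#' @param volume_path 4D NIfTI of beta maps.
#' @param metadata_path TSV with header `subject_id`, `block_index`,
#'   `cue_type`, `rating`; one row per 4th-axis sample, in order.
#' @param mask_path optional 3D NIfTI mask (nonzero = in brain).
#' @return A `crave_cohort`. Out-of-mask voxels are zeroed in `X`.
#' @export
read_dataset <- function(volume_path, metadata_path, mask_path = NULL) {
  vol <- readNifti(volume_path)
  affine <- structure(RNifti::xform(vol), class = NULL)
  vol <- as.array(vol)
  if (length(dim(vol)) == 3L) dim(vol) <- c(dim(vol), 1L)
  if (length(dim(vol)) != 4L)
    stop("expected a 3D or 4D beta volume")
  d3 <- dim(vol)[1:3]
  n_samples <- dim(vol)[4L]
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            stringsAsFactors = FALSE)
  required <- c("subject_id", "block_index", "cue_type", "rating")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(meta) != n_samples)
    stop(sprintf("metadata has %d rows but volume has %d samples",
                 nrow(meta), n_samples))
  if (!all(meta$rating %in% 1:4))
    stop("ratings must lie on the 1-4 craving scale")
  if (!all(meta$cue_type %in% c(0L, 1L)))
    stop("cue_type codes must be 0 (neutral) or 1 (drug)")
  meta$subject_id <- as.character(meta$subject_id)
  meta$block_index <- as.integer(meta$block_index)
  meta$cue_type <- as.integer(meta$cue_type)
  meta$rating <- as.integer(meta$rating)

  X <- t(matrix(vol, nrow = prod(d3), ncol = n_samples))
  if (!is.null(mask_path)) {
    mask <- as.vector(as.array(readNifti(mask_path))) != 0
    if (length(mask) != prod(d3))
      stop("mask grid does not match the beta volume grid")
    X[, !mask] <- 0
  } else {
    mask <- colSums(X != 0) > 0
  }
  structure(list(X = X, meta = meta, dim = d3, mask = mask,
                 affine = affine),
            class = "crave_cohort")
}

#' Map between in-mask 3D coordinates and flat feature columns
#'
#' @param mask logical voxel vector (flat, column-major).
#' @param grid_dim length-3 grid dimensions.
#' @return Data frame with `x`, `y`, `z` (1-based voxel coordinates) and
#'   `column` (flat index into the feature matrix), one row per in-mask
#'   voxel in ascending column order.
#' @export
voxel_index_map <- function(mask, grid_dim) {
  idx <- which(mask)
  coords <- arrayInd(idx, grid_dim)
  data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
             column = idx)
}

#' Write a voxel map (e.g., a VB signature) as a 3D NIfTI
#'
#' Scatters a weight vector back onto the voxel grid and writes it as a
#' float32 volume. `weights` may be full-length (one value per grid
#' voxel) or in-mask-length (one value per masked voxel, in ascending
#' flat-index order); out-of-mask voxels are written as 0.
#'
#' @param weights numeric vector of per-voxel weights.
#' @param ref a `crave_cohort` (or any list with `dim`, `mask`,
#'   `affine`) defining the grid.
#' @param path output NIfTI path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(weights, ref, path) {
  n_vox <- prod(ref$dim)
  full <- numeric(n_vox)
  if (length(weights) == n_vox) {
    full <- as.numeric(weights)
    full[!ref$mask] <- 0
  } else if (length(weights) == sum(ref$mask)) {
    full[ref$mask] <- weights
  } else {
    stop(sprintf(
      "weights length %d matches neither the grid (%d) nor the mask (%d)",
      length(weights), n_vox, sum(ref$mask)))
  }
  writeNifti(set_affine(asNifti(array(full, dim = ref$dim),
                                datatype = "float"), ref$affine),
             path)
  invisible(path)
}

#' Read a voxel map written by [write_map()]
#'
#' @param path NIfTI path.
#' @return Numeric vector of length `prod(dim)` in column-major order.
#' @export
read_map <- function(path) {
  as.vector(as.array(readNifti(path)))
}

#' Read a parcellation volume
#'
#' @param path 3D integer-labeled NIfTI; 0 is background.
#' @param region_names optional character vector or two-column data frame
#'   (id, name) naming the regions.
#' @return A `parcellation` object.
#' @export
read_parcellation <- function(path, region_names = NULL) {
  vol <- as.array(readNifti(path))
  labels <- as.integer(round(as.vector(vol)))
  ids <- sort(unique(labels[labels != 0L]))
  nm <- sprintf("region_%03d", ids)
  if (!is.null(region_names)) {
    if (is.data.frame(region_names)) {
      nm <- region_names[[2]][match(ids, region_names[[1]])]
    } else nm <- region_names[ids]
  }
  structure(list(labels = labels, region_ids = ids, region_names = nm,
                 dim = dim(vol)), class = "parcellation")
}
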