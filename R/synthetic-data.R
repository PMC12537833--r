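#' Configuration of the synthetic cue-reactivity cohort generator
#'
#' Parameters controlling the simulated cohort: its size, the voxel grid,
#' the planted multivariate signature linking brain activity to craving,
#' and the noise structure. Defaults emulate the characteristics of a
#' residential methamphetamine-use-disorder cue-reactivity study at desk
#' scale: 69 recruited subjects of whom 18 are flagged for exclusion
#' (51 analyzed), 8 blocks per subject (4 drug / 4 neutral, alternating
#' from neutral), sparse high-dimensional beta vectors with a large
#' proportion of exact zeros (out-of-mask voxels), and systematically
#' higher craving ratings after drug blocks than after neutral blocks.
#'
#' The voxel grid defaults to 16 x 16 x 16 (4096 voxels, ~60% in-mask),
#' a deliberate scale-down of the million-voxel maps of a real study so
#' that full pipelines run in seconds; all dimensions are configurable
#' upward.
#'
#' @param n_subjects recruited subjects.
#' @param n_excluded subjects flagged as having missing/incomplete data;
#'   removed by [apply_exclusions()] before any model fitting.
#' @param grid_dim length-3 integer voxel grid dimensions.
#' @param mask_fraction fraction of grid voxels inside the brain mask.
#' @param signature_support number of truly predictive voxels.
#' @param signature_amplitude_drug,signature_amplitude_neutral mean scale
#'   of the planted signature during drug and neutral blocks; drug must
#'   exceed neutral, which drives the drug > neutral rating gap.
#' @param subject_sd SD of the per-subject random offset (shared between
#'   the beta maps and the latent craving score).
#' @param noise_sd SD of the voxelwise beta noise and of the latent rating
#'   noise.
#' @param rating_thresholds three strictly increasing cut-points mapping
#'   the latent craving score to the ordinal 1--4 rating scale.
#' @param seed master RNG seed; every random draw descends from it through
#'   per-subject child seeds, so any subject subset is reproducible.
#' @return A list of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_subjects = 69,
                             n_excluded = 18,
                             grid_dim = c(16L, 16L, 16L),
                             mask_fraction = 0.6,
                             signature_support = 150,
                             signature_amplitude_drug = 2.2,
                             signature_amplitude_neutral = 1.0,
                             subject_sd = 0.35,
                             noise_sd = 0.35,
                             rating_thresholds = c(0.9, 1.6, 2.3),
                             seed = 1L) {
  stopifnot(length(grid_dim) == 3, all(grid_dim >= 2))
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (n_excluded < 0 || n_excluded >= n_subjects)
    stop("n_excluded must be in [0, n_subjects)")
  if (mask_fraction <= 0 || mask_fraction > 1)
    stop("mask_fraction must be in (0, 1]")
  if (signature_amplitude_neutral < 0 ||
      signature_amplitude_drug <= signature_amplitude_neutral)
    stop("amplitudes must satisfy drug > neutral >= 0")
  if (subject_sd < 0 || noise_sd < 0) stop("SDs must be >= 0")
  if (length(rating_thresholds) != 3 || any(diff(rating_thresholds) <= 0))
    stop("rating_thresholds must be 3 strictly increasing cut-points")
  n_voxels <- prod(grid_dim)
  if (signature_support < 1 ||
      signature_support > floor(mask_fraction * n_voxels))
    stop("signature_support must fit inside the mask")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_excluded = as.integer(n_excluded),
    grid_dim = as.integer(grid_dim),
    n_voxels = as.integer(n_voxels),
    mask_fraction = mask_fraction,
    signature_support = as.integer(signature_support),
    signature_amplitude_drug = signature_amplitude_drug,
    signature_amplitude_neutral = signature_amplitude_neutral,
    subject_sd = subject_sd,
    noise_sd = noise_sd,
    rating_thresholds = rating_thresholds,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Spawn n child seeds from a master seed (all < 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Centered quasi-spherical brain mask covering a fixed voxel count:
# the floor(fraction * n) voxels nearest the grid center (ties by index).
make_brain_mask <- function(grid_dim, mask_fraction) {
  n <- prod(grid_dim)
  ctr <- (grid_dim + 1) / 2
  coords <- arrayInd(seq_len(n), grid_dim)
  d2 <- colSums((t(coords) - ctr)^2)
  keep <- order(d2, seq_len(n))[seq_len(floor(mask_fraction * n))]
  mask <- logical(n)
  mask[keep] <- TRUE
  mask
}

#' Generate a synthetic cue-reactivity cohort with a planted signature
#'
#' Simulates block-level beta maps and craving ratings with the causal
#' structure the downstream pipeline assumes. Each block `b` of subject
#' `i` receives a scalar signal intensity
#' `a_ib = amplitude(cue_ib) * u_ib` with `u_ib ~ U(0.25, 1.75)`; the
#' beta vector is `mask * (a_ib * w + o_i * f + eps)` where `w` is the
#' unit-norm planted signature, `f` a fixed unit-norm subject-offset
#' field, `o_i ~ N(0, subject_sd)` and `eps ~ N(0, noise_sd)` voxelwise.
#' The latent craving score of the same block is `a_ib + o_i + eta_ib`
#' with `eta ~ N(0, noise_sd)`, discretized into ratings 1--4 by the
#' configured thresholds. Because the rating derives from the same latent
#' term that scales `w`, the signature is recoverable by the pipeline,
#' and in the noiseless limit the rating is a deterministic function of
#' the projection of the betas onto `w`.
#'
#' @param cfg a [synthetic_config()].
#' @param design a [build_task_design()]; supplies the number of blocks
#'   and the alternating cue sequence.
#' @return A list with elements `cohort` (class `crave_cohort`: beta
#'   matrix `X` of samples x voxels with off-mask columns exactly zero,
#'   `meta` data frame with `subject_id`, `block_index` (0-based),
#'   `cue_type` (0 neutral / 1 drug) and `rating`, plus `dim`, `mask`,
#'   `affine`) and `truth` (class `crave_truth`: full-length `w_true`,
#'   per-subject offsets, `excluded_ids`).
#' @examples
#' sim <- generate_cohort(synthetic_config(n_subjects = 6, n_excluded = 1,
#'                                         seed = 7))
#' dim(sim$cohort$X)
#' table(sim$cohort$meta$cue_type, sim$cohort$meta$rating)
#' @export
generate_cohort <- function(cfg = synthetic_config(),
                            design = build_task_design()) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(design, "task_design"))
  n_vox <- cfg$n_voxels
  mask <- make_brain_mask(cfg$grid_dim, cfg$mask_fraction)
  in_mask <- which(mask)
  n_mask <- length(in_mask)
  n_blocks <- design$n_blocks
  cue <- design$block_types
  amp <- ifelse(cue == 1L, cfg$signature_amplitude_drug,
                cfg$signature_amplitude_neutral)

  seeds <- child_seeds(cfg$seed, cfg$n_subjects + 1L)
  # Cohort-level structure from the first child seed.
  global <- with_seed(seeds[1L], {
    support <- sort(sample(in_mask, cfg$signature_support))
    w <- numeric(n_vox)
    # constant-magnitude sign pattern: per-voxel standardization in the
    # pipeline equalizes signal scales, so a +/- pattern is what a
    # standardized linear read-out can recover up to a global scale
    w[support] <- sample(c(-1, 1), cfg$signature_support, replace = TRUE)
    w <- w / sqrt(sum(w^2))
    f <- numeric(n_vox)
    f[in_mask] <- rnorm(n_mask)
    f <- f / sqrt(sum(f^2))
    offsets <- rnorm(cfg$n_subjects, sd = cfg$subject_sd)
    excluded <- sample(cfg$n_subjects, cfg$n_excluded)
    list(w = w, f = f, offsets = offsets, excluded = excluded)
  })

  ids <- sprintf("S%03d", seq_len(cfg$n_subjects))
  names(global$offsets) <- ids
  X <- matrix(0, nrow = cfg$n_subjects * n_blocks, ncol = n_vox)
  rating <- integer(nrow(X))
  w_mask <- global$w[in_mask]
  f_mask <- global$f[in_mask]
  for (i in seq_len(cfg$n_subjects)) {
    rows <- (i - 1L) * n_blocks + seq_len(n_blocks)
    o_i <- global$offsets[i]
    blocks <- with_seed(seeds[i + 1L], {
      u <- runif(n_blocks, 0.25, 1.75)
      eta <- rnorm(n_blocks, sd = cfg$noise_sd)
      eps <- matrix(rnorm(n_blocks * n_mask, sd = cfg$noise_sd),
                    nrow = n_blocks)
      list(u = u, eta = eta, eps = eps)
    })
    a <- amp * blocks$u
    X[rows, in_mask] <- a %o% w_mask + o_i * rep(1, n_blocks) %o% f_mask +
      blocks$eps
    latent <- a + o_i + blocks$eta
    rating[rows] <- 1L + findInterval(latent, cfg$rating_thresholds)
  }
  if (length(unique(rating)) == 1L)
    warning("rating thresholds do not cover the latent range: ",
            "all ratings collapsed to level ", rating[1L])

  meta <- data.frame(
    subject_id = rep(ids, each = n_blocks),
    block_index = rep(seq_len(n_blocks) - 1L, cfg$n_subjects),
    cue_type = rep(cue, cfg$n_subjects),
    rating = rating,
    stringsAsFactors = FALSE
  )
  cohort <- structure(list(
    X = X, meta = meta, dim = cfg$grid_dim, mask = mask,
    affine = diag(4)
  ), class = "crave_cohort")
  truth <- structure(list(
    w_true = global$w,
    subject_offsets = global$offsets,
    excluded_ids = ids[sort(global$excluded)]
  ), class = "crave_truth")
  list(cohort = cohort, truth = truth)
}

#' Remove subjects flagged as excluded
#'
#' Filters out every sample of the excluded subjects (e.g., those with
#' missing or incomplete data) before any splitting or model fitting.
#'
#' @param cohort a `crave_cohort`.
#' @param excluded_ids character vector of subject IDs to drop, or a
#'   `crave_truth` whose `excluded_ids` are used.
#' @return The filtered `crave_cohort`.
#' @examples
#' sim <- generate_cohort(synthetic_config(n_subjects = 5, n_excluded = 2,
#'                                         seed = 3))
#' nlevels(factor(apply_exclusions(sim$cohort, sim$truth)$meta$subject_id))
#' @export
apply_exclusions <- function(cohort, excluded_ids) {
  stopifnot(inherits(cohort, "crave_cohort"))
  if (inherits(excluded_ids, "crave_truth"))
    excluded_ids <- excluded_ids$excluded_ids
  keep <- !(cohort$meta$subject_id %in% excluded_ids)
  cohort$X <- cohort$X[keep, , drop = FALSE]
  cohort$meta <- cohort$meta[keep, , drop = FALSE]
  rownames(cohort$meta) <- NULL
  cohort
}

#' Subjects present in a cohort
#'
#' @param cohort a `crave_cohort`.
#' @return Character vector of unique subject IDs, in first-appearance
#'   order.
#' @export
cohort_subjects <- function(cohort) {
  unique(cohort$meta$subject_id)
}

#' Synthetic brain parcellation over a mask
#'
#' Partitions the in-mask voxels into a given number of contiguous
#' (index-ordered) regions of near-equal size, emulating an anatomical
#' atlas such as a 246-region whole-brain parcellation for tests and
#' examples. Background (out-of-mask) voxels carry label 0.
#'
#' @param mask logical voxel vector (flat, column-major).
#' @param grid_dim length-3 grid dimensions.
#' @param n_regions number of regions.
#' @return An object of class `parcellation`: integer `labels` vector
#'   (length `prod(grid_dim)`), `region_ids`, `region_names`, `dim`.
#' @export
synthetic_parcellation <- function(mask, grid_dim, n_regions = 246) {
  in_mask <- which(mask)
  if (n_regions < 1 || n_regions > length(in_mask))
    stop("n_regions must be in [1, number of in-mask voxels]")
  labels <- integer(length(mask))
  # deal voxels into regions in index order, sizes differing by <= 1
  reg <- rep(seq_len(n_regions),
             times = diff(floor(seq(0, length(in_mask),
                                    length.out = n_regions + 1))))
  labels[in_mask] <- reg
  structure(list(
    labels = labels,
    region_ids = seq_len(n_regions),
    region_names = sprintf("region_%03d", seq_len(n_regions)),
    dim = as.integer(grid_dim)
  ), class = "parcellation")
}
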