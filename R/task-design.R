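#' Block design of the drug cue reactivity task
#'
#' Describes the timing and ordering of the cue-reactivity run: alternating
#' blocks of neutral and drug images, starting with a neutral block, each
#' block a fixed number of images separated by short blanks, with a craving
#' self-report (1--4) collected after every block.
#'
#' Defaults reproduce the standard design: 6 images of 5 s separated by
#' 0.2 s gaps (31 s per block), 8 blocks (4 neutral, 4 drug) alternating
#' from neutral, a jittered 8--12 s inter-block fixation, TR 2 s and 196
#' volumes.
#'
#' @param images_per_block number of images shown per block.
#' @param image_duration duration of each image, seconds.
#' @param inter_image_gap blank between consecutive images, seconds.
#' @param n_blocks total number of blocks; must be even so cue types balance.
#' @param inter_block_interval length-2 range of the inter-block fixation,
#'   seconds.
#' @param tr repetition time of the EPI sequence, seconds.
#' @param n_repetitions number of acquired volumes.
#' @return An object of class `task_design` with the fields above plus
#'   `block_types` (integer vector, 0 = neutral, 1 = drug, alternating and
#'   starting with neutral) and `block_duration` (seconds).
#' @examples
#' d <- build_task_design()
#' d$block_duration  # 31
#' table(d$block_types)
#' @export
build_task_design <- function(images_per_block = 6,
                              image_duration = 5,
                              inter_image_gap = 0.2,
                              n_blocks = 8,
                              inter_block_interval = c(8, 12),
                              tr = 2,
                              n_repetitions = 196) {
  if (images_per_block < 1 || n_blocks < 1 || n_repetitions < 1)
    stop("counts must be positive")
  if (image_duration <= 0 || inter_image_gap < 0 || tr <= 0)
    stop("durations must be positive (gaps may be zero)")
  if (n_blocks %% 2 != 0)
    stop("n_blocks must be even so drug and neutral blocks balance")
  if (length(inter_block_interval) != 2 || diff(inter_block_interval) < 0)
    stop("inter_block_interval must be an increasing length-2 range")
  block_types <- rep_len(c(0L, 1L), n_blocks)  # alternating, neutral first
  structure(list(
    images_per_block = as.integer(images_per_block),
    image_duration = image_duration,
    inter_image_gap = inter_image_gap,
    n_blocks = as.integer(n_blocks),
    block_types = block_types,
    inter_block_interval = inter_block_interval,
    tr = tr,
    n_repetitions = as.integer(n_repetitions),
    block_duration = images_per_block * image_duration +
      (images_per_block - 1) * inter_image_gap
  ), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "Cue-reactivity block design: %d blocks (%d drug / %d neutral, neutral first)\n",
    x$n_blocks, sum(x$block_types == 1L), sum(x$block_types == 0L)))
  cat(sprintf("  %d images x %g s + %g s gaps -> %g s per block\n",
              x$images_per_block, x$image_duration, x$inter_image_gap,
              x$block_duration))
  cat(sprintf("  inter-block fixation %g-%g s, TR %g s, %d volumes\n",
              x$inter_block_interval[1], x$inter_block_interval[2],
              x$tr, x$n_repetitions))
  invisible(x)
}
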