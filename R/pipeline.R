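#' Default pipeline configuration
#'
#' @param task `"regress"`, `"classify_craving"` or `"classify_cue"`.
#' @return Nested list understood by [run_pipeline()]; any subset can
#'   be overridden via a YAML file or an overrides list. Sections:
#'   `synthetic` ([synthetic_config()] arguments, or `NULL` when
#'   `paths` point at real data), `paths` (volume / metadata / mask
#'   NIfTI+TSV inputs), `features` (method and size; component counts
#'   default per task to 100 / 50 / 100), `models` (regressor family
#'   and hyperparameters; `grid: true` enables candidate selection),
#'   `evaluation` (k, holdout_fraction, repetitions), `inference`
#'   (n_perm, n_boot, alpha), `atlas` (n_regions of the synthetic
#'   parcellation, or a NIfTI path).
#' @export
default_config <- function(task = "regress") {
  list(
    task = task,
    synthetic = list(),
    paths = NULL,
    features = list(method = "pca"),
    models = list(family = "ols", grid = FALSE),
    evaluation = list(k = 5, holdout_fraction = 0.2, repetitions = 50),
    inference = list(n_perm = 200, n_boot = 1000, alpha = 0.05),
    atlas = list(n_regions = 246)
  )
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    else base[[nm]] <- overrides[[nm]]
  }
  base
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  merge_config(default_config(config$task %||% "regress"), config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Run the full analysis pipeline end to end
#'
#' Executes: simulate (or load) -> exclusions -> subject-level
#' hold-out + CV split -> optional grid search -> repeated CV ->
#' hold-out evaluation -> permutation inference -> statistical report
#' -> (regression task) VB signature back-projection, display
#' normalization and atlas summary. All artifacts are written as
#' plain-text TSV / NIfTI into `out_dir`, stamped with the config hash
#' and seed; identical config + seed reproduce byte-identical tables.
#'
#' @param config `NULL` (defaults), a nested list, or a YAML path; see
#'   [default_config()].
#' @param out_dir output directory.
#' @param seed master seed for every stage.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `plan`, `observed`, `null`, `report`, `holdout`, and for the
#'   regression task `signature` and `regions`).
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("crave_run_"),
                         seed = 1L) {
  cfg <- read_config(config)
  task <- match.arg(cfg$task, TASKS)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_lines <- c(sprintf("config_hash: %s", cfg_hash),
                 sprintf("seed: %d", as.integer(seed)),
                 sprintf("task: %s", task))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  t0 <- proc.time()[3]
  stage <- function(nm) say("[%7.1fs] stage: %s", proc.time()[3] - t0, nm)
  on_fail <- function(nm, e)
    stop(sprintf("pipeline stage '%s' failed: %s", nm,
                 conditionMessage(e)), call. = FALSE)

  stage("data")
  data <- tryCatch({
    if (!is.null(cfg$paths)) {
      cohort <- read_dataset(cfg$paths$volume, cfg$paths$metadata,
                             cfg$paths$mask)
      list(cohort = cohort, truth = NULL)
    } else {
      sim_args <- merge_config(cfg$synthetic %||% list(),
                               list(seed = as.integer(seed)))
      sim <- generate_cohort(do.call(synthetic_config, sim_args))
      sim$cohort <- apply_exclusions(sim$cohort, sim$truth)
      sim
    }
  }, error = function(e) on_fail("data", e))
  cohort <- data$cohort
  say("samples: %d, subjects: %d, voxels: %d (in-mask %d)",
      nrow(cohort$X), length(cohort_subjects(cohort)), ncol(cohort$X),
      sum(cohort$mask))
  say("cohort_hash: %s", cohort_hash(cohort))

  stage("split")
  plan <- make_split(cohort_subjects(cohort),
                     holdout_fraction = cfg$evaluation$holdout_fraction,
                     k = cfg$evaluation$k, seed = seed)
  say("holdout subjects: %d, fitting subjects: %d in %d folds",
      length(plan$holdout_subjects), length(plan$folds), plan$k)

  feat <- task_features(task, cfg$features)
  spec <- do.call(regressor_spec, cfg$models[
    setdiff(names(cfg$models), c("grid", "candidates"))])
  if (isTRUE(cfg$models$grid)) {
    stage("grid_search")
    fitting <- subset_cohort(cohort,
                             cohort$meta$subject_id %in% names(plan$folds))
    gr <- tryCatch(
      grid_search(cfg$models$candidates %||% default_candidates(),
                  fitting, target = if (task == "classify_cue") "cue"
                                    else "rating",
                  k = cfg$evaluation$k, seed = seed),
      error = function(e) on_fail("grid_search", e))
    write_tsv(gr$table, file.path(out_dir, "grid.tsv"))
    win <- gr$candidates[[gr$winner]]
    spec <- win$spec
    feat <- task_features(task, win$features)
    say("grid winner: %s", gr$table$candidate[gr$winner])
  }
  say("regressor: %s; features: %s with %d components; threshold: %s",
      spec$family, feat$method,
      if (feat$method == "pca") feat$n_components else feat$k_best,
      if (task == "classify_cue") "0.5"
      else if (task == "classify_craving") "F1-optimized per iteration"
      else "none")

  stage("repeated_cv")
  observed <- tryCatch(
    repeated_task(cohort, fitting_subjects = names(plan$folds),
                  task = task, n_reps = cfg$evaluation$repetitions,
                  k = cfg$evaluation$k, spec = spec, features = feat,
                  seed = seed),
    error = function(e) on_fail("repeated_cv", e))
  write_tsv(observed, file.path(out_dir, "metrics_cv.tsv"))

  stage("holdout")
  holdout <- tryCatch(
    evaluate_holdout_task(cohort, plan, task = task, spec = spec,
                          features = feat, seed = seed),
    error = function(e) on_fail("holdout", e))
  write_tsv(holdout$predictions,
            file.path(out_dir, "holdout_predictions.tsv"))
  if (!is.null(holdout$roc))
    write_tsv(holdout$roc, file.path(out_dir, "roc_holdout.tsv"))

  stage("permutation")
  null <- tryCatch(
    permutation_null(cohort, fitting_subjects = names(plan$folds),
                     task = task, n_perm = cfg$inference$n_perm,
                     k = cfg$evaluation$k, spec = spec, features = feat,
                     seed = seed),
    error = function(e) on_fail("permutation", e))
  write_tsv(null, file.path(out_dir, "metrics_null.tsv"))

  stage("report")
  report <- report_table(observed, null,
                         out_of_sample = holdout$metrics,
                         alpha = cfg$inference$alpha,
                         n_boot = cfg$inference$n_boot, seed = seed)
  write_tsv(report, file.path(out_dir, "report.tsv"))

  result <- list(cohort = cohort, truth = data$truth, plan = plan,
                 spec = spec, features = feat, observed = observed,
                 null = null, holdout = holdout, report = report,
                 out_dir = out_dir)

  if (task == "regress" && feat$method == "pca" &&
      !is.null(holdout$pipeline$model$B)) {
    stage("signature")
    map <- back_project(holdout$pipeline)
    fitting_rows <- cohort$meta$subject_id %in% names(plan$folds)
    mean_beta <- colMeans(cohort$X[fitting_rows, , drop = FALSE])
    map <- normalize_for_display(map, mean_beta)
    write_map(map$vb, cohort, file.path(out_dir, "signature_vb.nii.gz"))
    write_map(map$vb_raw, cohort,
              file.path(out_dir, "signature_vb_raw.nii.gz"))
    parc <- if (!is.null(cfg$atlas$path))
      read_parcellation(cfg$atlas$path)
    else synthetic_parcellation(cohort$mask, cohort$dim,
                                n_regions = cfg$atlas$n_regions)
    regions <- summarize_by_atlas(map, parc, mask = cohort$mask)
    write_tsv(regions, file.path(out_dir, "signature_regions.tsv"))
    result$signature <- map
    result$regions <- regions
  }

  stage("done")
  writeLines(log_lines, log_path)
  invisible(result)
}

# Stable content hash of a cohort (shared-upstream audit across tasks).
cohort_hash <- function(cohort) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(X = round(cohort$X, 12), meta = cohort$meta,
               mask = cohort$mask, dim = cohort$dim), f)
  unname(tools::md5sum(f))
}
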