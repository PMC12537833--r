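test_that("hold-out arithmetic reproduces the 51 -> 11 + 40 split", {
  subjects <- sprintf("S%03d", 1:51)
  plan <- make_split(subjects, holdout_fraction = 0.2, k = 5, seed = 1)
  expect_equal(length(plan$holdout_subjects), 11L)
  expect_equal(length(plan$folds), 40L)
  expect_equal(as.vector(table(plan$folds)), rep(8L, 5))
  expect_length(intersect(plan$holdout_subjects, names(plan$folds)), 0)
})

test_that("a zero hold-out fraction folds every subject", {
  plan <- make_split(letters[1:10], holdout_fraction = 0, k = 5, seed = 2)
  expect_length(plan$holdout_subjects, 0)
  expect_setequal(names(plan$folds), letters[1:10])
})

test_that("splits are deterministic per seed and vary across seeds", {
  subjects <- sprintf("S%02d", 1:30)
  p1 <- make_split(subjects, seed = 3)
  p2 <- make_split(subjects, seed = 3)
  p3 <- make_split(subjects, seed = 4)
  expect_identical(p1$holdout_subjects, p2$holdout_subjects)
  expect_identical(p1$folds, p2$folds)
  expect_false(identical(p1$holdout_subjects, p3$holdout_subjects))
})

test_that("too many folds for the fitting subjects is an error", {
  expect_error(make_split(letters[1:6], holdout_fraction = 0.5, k = 5),
               "exceeds")
})

test_that("stratified errors equal the hand-computed and brute-force values", {
  # level 1: errors (0, 1) -> rmse sqrt(1/2); level 2: 0 -> mean 0.35355
  expect_equal(stratified_metric(c(1, 1, 2, 2), c(1, 2, 2, 2), "rmse"),
               sqrt(0.5) / 2, tolerance = 1e-12)
  expect_equal(stratified_metric(c(1, 2, 3), c(1, 2, 3), "rmse"), 0)
  # single-stratum collapse equals the plain metric
  set.seed(5)
  yhat <- rnorm(10, 2)
  expect_equal(stratified_metric(rep(2, 10), yhat, "rmse"),
               sqrt(mean((2 - yhat)^2)), tolerance = 1e-12)
  # brute-force oracle on random inputs
  for (s in 1:5) {
    set.seed(s)
    y <- sample(1:4, 40, replace = TRUE)
    yh <- rnorm(40, y)
    expect_equal(stratified_metric(y, yh, "rmse"),
                 oracle_stratified(y, yh, "rmse"), tolerance = 1e-12)
    expect_equal(stratified_metric(y, yh, "mae"),
                 oracle_stratified(y, yh, "mae"), tolerance = 1e-12)
  }
  expect_error(stratified_metric(numeric(0), numeric(0)), "non-empty")
})

test_that("pooled Pearson correlation matches hand computations", {
  y <- c(1, 2, 3, 4)
  expect_equal(pearson_metric(y, y), 1)
  expect_equal(pearson_metric(y, -y), -1)
  expect_equal(pearson_metric(y, c(2, 1, 4, 3)), 0.6, tolerance = 1e-12)
  expect_error(pearson_metric(y, rep(1, 4)), "constant")
})

test_that("AUC-ROC equals pair counting, handles separation and ties", {
  expect_equal(classification_metrics(c(0, 0, 1, 1),
                                      c(0.1, 0.4, 0.35, 0.8))$auc_roc,
               0.75)
  expect_equal(classification_metrics(c(0, 0, 1, 1),
                                      c(1, 2, 3, 4))$auc_roc, 1)
  expect_equal(classification_metrics(c(0, 1, 0, 1),
                                      rep(0.3, 4))$auc_roc, 0.5)
  for (s in 1:5) {
    set.seed(s)
    lab <- rbinom(30, 1, 0.4)
    sc <- rnorm(30) + lab
    sc[1:5] <- round(sc[1:5])  # force some ties
    expect_equal(classification_metrics(lab, sc)$auc_roc,
                 oracle_auc(lab, sc), tolerance = 1e-12)
  }
  # single-class AUC reported as NA, not an error
  expect_true(is.na(classification_metrics(c(1, 1), c(0.2, 0.4))$auc_roc))
})

test_that("AUC-ROC/PR agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  lab <- rbinom(50, 1, 0.5)
  sc <- rnorm(50) + 0.8 * lab
  ours <- classification_metrics(lab, sc)$auc_roc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("accuracy and precision respect the >= threshold convention", {
  m <- classification_metrics(c(0, 1), c(0.5, 0.5), threshold = 0.5)
  expect_equal(m$accuracy, 0.5)  # both predicted positive
  m2 <- classification_metrics(c(0, 0, 1, 1), c(0.1, 0.6, 0.7, 0.2))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$precision, 0.5)
})

test_that("ROC points form a monotone staircase from (0,0) to (1,1)", {
  set.seed(10)
  lab <- rbinom(40, 1, 0.5)
  sc <- rnorm(40) + lab
  rc <- roc_points(lab, sc)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("extreme extraction takes first occurrences in block order", {
  ex <- extract_extremes(c(2, 1, 3, 1, 4, 4), 0:5)
  expect_equal(ex$min_at, 2L)   # block 1 (rating 1)
  expect_equal(ex$max_at, 5L)   # block 4 (rating 4)
  expect_false(ex$degenerate)

  ex2 <- extract_extremes(c(2, 2, 2))
  expect_equal(ex2$min_at, 1L)
  expect_equal(ex2$max_at, 1L)
  expect_true(ex2$degenerate)

  ex3 <- extract_extremes(3)
  expect_equal(ex3$min_at, ex3$max_at)
  expect_true(ex3$degenerate)

  # order by block index even if rows arrive shuffled
  ex4 <- extract_extremes(c(4, 1, 4), c(2, 1, 0))
  expect_equal(ex4$max_at, 3L)  # block 0 comes first
})

test_that("cross-validation never mixes a subject across train and test", {
  sc <- small_cohort(seed = 11)
  plan <- make_split(cohort_subjects(sc$cohort), 0.2, k = 3, seed = 11)
  cv <- run_cv(sc$cohort, plan, "rating",
               features = list(n_components = 10), seed = 11)
  oof <- cv$predictions
  expect_length(intersect(oof$subject_id, plan$holdout_subjects), 0)
  # a planted duplicate subject ID spanning folds trips the assertion
  dup_subjects <- c(cohort_subjects(sc$cohort),
                    cohort_subjects(sc$cohort)[1])
  bad_plan <- make_split(dup_subjects, 0, k = 3, seed = 1)
  expect_error(run_cv(sc$cohort, bad_plan, "rating",
                      features = list(n_components = 10), seed = 1),
               "leakage")
})

test_that("a noiseless cohort is predicted to the quantization floor", {
  sim <- generate_cohort(synthetic_config(noise_sd = 0, subject_sd = 0,
                                          seed = 12))
  coh <- apply_exclusions(sim$cohort, sim$truth)
  plan <- make_split(cohort_subjects(coh), 0.2, 5, seed = 12)
  cv <- run_cv(coh, plan, "rating", seed = 12)
  # ratings are a deterministic staircase of the latent score; a linear
  # read-out recovers everything but the quantization gap
  expect_lt(cv$pooled$rmse, 0.4)
  expect_gt(cv$pooled$pearson, 0.9)
})

test_that("permuted labels drive the pooled correlation to chance", {
  sim <- default_sim()
  coh <- sim$cohort
  coh$meta$rating <- with_seed_for_test(13, sample(coh$meta$rating))
  plan <- make_split(cohort_subjects(coh), 0.2, 5, seed = 13)
  cv <- run_cv(coh, plan, "rating", seed = 13)
  expect_lt(abs(cv$pooled$pearson), 0.2)
})
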