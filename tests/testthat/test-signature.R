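test_that("back-projection reproduces pipeline predictions for every linear family", {
  sc <- small_cohort(seed = 1)
  y <- as.numeric(sc$cohort$meta$rating)
  X_new <- generate_cohort(small_cfg(seed = 99))$cohort$X
  for (fam in c("ols", "ridge", "lasso", "elastic_net")) {
    pipe <- fit_pipeline(sc$cohort$X, y,
                         regressor_spec(fam, penalty = 0.1),
                         n_components = 15)
    map <- back_project(pipe)
    expect_lt(max(abs(predict(pipe, X_new) -
                        signature_predict(map, X_new))), 1e-8)
    # zero weight off the kept columns
    expect_true(all(map$vb[-map$kept] == 0))
    expect_true(all(map$vb_raw[!sc$cohort$mask] == 0))
  }
})

test_that("back-projection identity holds across component counts and seeds", {
  for (s in 4:6) {
    sc <- small_cohort(seed = s)
    y <- as.numeric(sc$cohort$meta$rating)
    for (nc in c(1, 5, 40)) {
      pipe <- fit_pipeline(sc$cohort$X, y, regressor_spec("ols"),
                           n_components = nc)
      map <- back_project(pipe)
      expect_lt(max(abs(predict(pipe, sc$cohort$X) -
                          signature_predict(map, sc$cohort$X))), 1e-8)
    }
  }
})

test_that("degenerate back-projections behave algebraically", {
  sc <- small_cohort(seed = 2)
  y <- as.numeric(sc$cohort$meta$rating)
  # B = 0 (constant target) -> zero map
  pipe0 <- fit_pipeline(sc$cohort$X, rep(2, length(y)),
                        regressor_spec("ridge", penalty = 1),
                        n_components = 10)
  map0 <- back_project(pipe0)
  expect_true(all(map0$vb == 0))
  expect_equal(map0$b0_adj, 2)
  # single component with B = 1: vb equals the first eigenvector
  pipe1 <- fit_pipeline(sc$cohort$X, y, regressor_spec("ols"),
                        n_components = 1)
  map1 <- back_project(pipe1)
  expect_equal(map1$vb[pipe1$reducer$kept],
               drop(pipe1$reducer$V) * pipe1$model$B,
               tolerance = 1e-12)
})

test_that("back-projection refuses non-linear or ANOVA fits", {
  sc <- small_cohort(seed = 3)
  y <- as.numeric(sc$cohort$meta$rating)
  rf <- fit_pipeline(sc$cohort$X, y,
                     regressor_spec("random_forest", n_estimators = 20),
                     n_components = 10)
  expect_error(back_project(rf), "linear")
  an <- fit_pipeline(sc$cohort$X, y, regressor_spec("ols"),
                     method = "anova", k_best = 10)
  expect_error(back_project(an), "PCA")
})

test_that("display normalization matches the reference norm exactly", {
  sc <- small_cohort(seed = 7)
  y <- as.numeric(sc$cohort$meta$rating)
  pipe <- fit_pipeline(sc$cohort$X, y, regressor_spec("ols"),
                       n_components = 10)
  map <- back_project(pipe)
  # reference = the map itself -> factor 1
  self <- normalize_for_display(map, map$vb_raw)
  expect_equal(self$norm_factor, 1, tolerance = 1e-12)
  # seeded reference: norms equal to 1e-10; doubling reference doubles norm
  ref <- colMeans(sc$cohort$X)
  n1 <- normalize_for_display(map, ref)
  expect_equal(sqrt(sum(n1$vb_raw^2)), sqrt(sum(ref^2)),
               tolerance = 1e-10)
  n2 <- normalize_for_display(map, 2 * ref)
  expect_equal(sqrt(sum(n2$vb_raw^2)), 2 * sqrt(sum(ref^2)),
               tolerance = 1e-10)
  # sign pattern unchanged
  expect_identical(sign(n1$vb), sign(map$vb))
  expect_error(normalize_for_display(map, numeric(length(map$vb))),
               "zero norm")
})

test_that("atlas summaries equal hand and loop oracles", {
  # two regions with voxel values {1,3} and {2} -> means {2, 2}
  labels <- integer(8)
  labels[c(1, 2)] <- 1L
  labels[3] <- 2L
  parc <- structure(list(labels = labels, region_ids = 1:2,
                         region_names = c("a", "b"), dim = c(2L, 2L, 2L)),
                    class = "parcellation")
  map <- list(vb = c(1, 3, 2, rep(0, 5)))
  class(map) <- "signature_map"
  tab <- summarize_by_atlas(map, parc)
  expect_equal(sort(tab$mean_vb), c(2, 2))

  # uniform map: every region mean equals the constant
  sc <- small_cohort(seed = 8)
  parc2 <- synthetic_parcellation(sc$cohort$mask, sc$cohort$dim, 12)
  mapu <- structure(list(vb = rep(4.2, prod(sc$cohort$dim))),
                    class = "signature_map")
  tabu <- summarize_by_atlas(mapu, parc2, mask = sc$cohort$mask)
  expect_true(all(abs(tabu$mean_vb - 4.2) < 1e-12))

  # random map vs per-region loop oracle
  set.seed(9)
  vb <- rnorm(prod(sc$cohort$dim)) * sc$cohort$mask
  mapr <- structure(list(vb = vb), class = "signature_map")
  tabr <- summarize_by_atlas(mapr, parc2, mask = sc$cohort$mask)
  oracle <- oracle_atlas_means(vb, parc2$labels, sc$cohort$mask,
                               parc2$region_ids)
  expect_equal(tabr$mean_vb[order(tabr$region_id)], oracle,
               tolerance = 1e-12)
  # ranking is descending in the mean
  expect_true(all(diff(tabr$mean_vb[order(tabr$rank)]) <= 0))
})

test_that("a 246-region parcellation yields 246 regional values", {
  sim <- default_sim()
  parc <- synthetic_parcellation(sim$cohort$mask, sim$cohort$dim, 246)
  vb <- as.numeric(sim$cohort$mask)
  map <- structure(list(vb = vb), class = "signature_map")
  tab <- summarize_by_atlas(map, parc, mask = sim$cohort$mask)
  expect_equal(nrow(tab), 246L)
  expect_true(all(!is.na(tab$mean_vb)))
})

test_that("empty regions are reported missing, not zero", {
  sc <- small_cohort(seed = 10)
  parc <- synthetic_parcellation(sc$cohort$mask, sc$cohort$dim, 5)
  parc$region_ids <- c(parc$region_ids, 99L)
  parc$region_names <- c(parc$region_names, "empty")
  map <- structure(list(vb = rnorm(prod(sc$cohort$dim))),
                   class = "signature_map")
  tab <- summarize_by_atlas(map, parc, mask = sc$cohort$mask)
  expect_true(is.na(tab$mean_vb[tab$region_id == 99L]))
  expect_equal(tab$n_voxels[tab$region_id == 99L], 0L)
  expect_error(summarize_by_atlas(map, parc,
                                  mask = rep(FALSE, prod(sc$cohort$dim))),
               "no overlap")
})

test_that("two fits on identical data produce bit-identical maps", {
  sc <- small_cohort(seed = 11)
  y <- as.numeric(sc$cohort$meta$rating)
  m1 <- back_project(fit_pipeline(sc$cohort$X, y, regressor_spec("ols"),
                                  n_components = 12))
  m2 <- back_project(fit_pipeline(sc$cohort$X, y, regressor_spec("ols"),
                                  n_components = 12))
  expect_identical(m1$vb, m2$vb)
  expect_identical(m1$vb_raw, m2$vb_raw)
  expect_identical(m1$b0_adj, m2$b0_adj)
})
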