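# Small seeded cohorts shared across test files. Generation is cheap but
# not free, so the common ones are built once per test run.

small_cfg <- function(seed = 1L, ...) {
  synthetic_config(n_subjects = 12, n_excluded = 2,
                   grid_dim = c(8L, 8L, 8L), signature_support = 40,
                   seed = seed, ...)
}

small_cohort <- function(seed = 1L, ...) {
  sim <- generate_cohort(small_cfg(seed = seed, ...))
  list(cohort = apply_exclusions(sim$cohort, sim$truth),
       truth = sim$truth)
}

# default-scale cohort used by several suites (51 analyzed subjects)
.fixture_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    sim <- generate_cohort(synthetic_config(seed = 20260920))
    sim$cohort <- apply_exclusions(sim$cohort, sim$truth)
    .fixture_cache$sim <- sim
  }
  .fixture_cache$sim
}

with_seed_for_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# seeded dense matrix for feature/model unit tests
toy_matrix <- function(n = 20, p = 10, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(n * p), nrow = n)
}
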