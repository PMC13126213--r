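test_that("manifests reproduce the factorial design counts exactly", {
  d1 <- experiment_design("study1", collections = sprintf("c%02d", 1:21),
                          prevalence_grid = c(0.005, 0.01, 0.05, 0.10),
                          algorithms = as.list(sprintf("alg%02d", 1:10)),
                          n_replications = 1000)
  m1 <- enumerate_runs(d1)
  expect_equal(attr(m1, "n_artificial_collections"), 21 * 4 * 1000)
  expect_equal(nrow(m1), 21 * 4 * 1000 * 10)

  d2 <- experiment_design("study2", collections = sprintf("c%d", 1:9),
                          prevalence_grid = c(0.01, 0.025, 0.05),
                          n_rel_grid = c(20, 40), training_grid = c(1, 2, 5),
                          n_replications = 1000)
  m2 <- enumerate_runs(d2)
  expect_equal(attr(m2, "n_artificial_collections"), 9 * 3 * 2 * 1000)
  expect_equal(nrow(m2), 9 * 3 * 2 * 1000 * 3)

  # degenerate grid: one level per factor -> a single run
  d0 <- experiment_design("study1", "c1", 0.05, algorithms = list("lr+tfidf"),
                          n_replications = 1)
  expect_equal(nrow(enumerate_runs(d0)), 1L)
})

test_that("per-run seeds are deterministic and shared across algorithms", {
  d <- experiment_design("study1", c("a", "b"), c(0.02, 0.05),
                         algorithms = list("lr+tfidf", "nb+tfidf"),
                         n_replications = 3, master_seed = 9)
  m <- enumerate_runs(d)
  expect_identical(m, enumerate_runs(d))
  # the artificial collection seed does not depend on the algorithm
  seeds <- tapply(m$collection_seed,
                  paste(m$collection, m$prevalence, m$replication),
                  function(s) length(unique(s)))
  expect_true(all(seeds == 1))
  # but run seeds differ between algorithms
  expect_gt(length(unique(m$run_seed)), length(unique(m$collection_seed)))
})

test_that("execution is thinned per cell, deterministic, and conserves rows", {
  suite <- generate_suite(2, corpus_spec(n_total = 400, prevalence = 0.1,
                                         vocab_size = 150, doc_length_mean = 15),
                          seed = 3)
  d <- experiment_design("study2", suite, prevalence_grid = c(0.05, 0.1),
                         n_rel_grid = 10, training_grid = 1,
                         n_replications = 10, master_seed = 4)
  m <- enumerate_runs(d)
  res <- execute(m, suite, scale_factor = 0.2, retrain_interval = 20)
  expect_length(attr(res, "failures"), 0L)
  # 2 reps of 10 kept, every cell present
  expect_equal(sort(unique(res$replication)), c(1, 2))
  expect_equal(nrow(unique(res[, c("collection", "prevalence")])), 4L)
  # one row per executed run and metric
  n_runs <- nrow(unique(res[, c("collection", "prevalence", "replication")]))
  expect_equal(nrow(res), n_runs * 4L)
  expect_identical(res, execute(m, suite, scale_factor = 0.2, retrain_interval = 20))
})

test_that("failed runs are recorded without aborting the execution", {
  suite <- generate_suite(1, corpus_spec(n_total = 300, prevalence = 0.05,
                                         vocab_size = 150, doc_length_mean = 15),
                          seed = 8)
  d <- experiment_design("study2", suite, prevalence_grid = c(0.05, 0.001),
                         n_rel_grid = 10, training_grid = 1,
                         n_replications = 1, master_seed = 5)
  m <- enumerate_runs(d)
  # prevalence 0.1% needs 9,990 irrelevant records; that cell must fail
  res <- execute(m, suite, retrain_interval = 20)
  expect_equal(length(attr(res, "failures")), 1L)
  expect_match(attr(res, "failures"), "irrelevant")
  expect_equal(unique(res$prevalence), 0.05)
})

test_that("performance summaries match hand-computed quantiles", {
  s <- summarize_performance(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q25, 25.75)
  expect_equal(s$q90, 90.1)
  expect_equal(s$n_runs, 100L)

  const <- summarize_performance(rep(7, 12))
  expect_equal(const$sd, 0)
  expect_equal(const$q75 - const$q25, 0)

  set.seed(13)
  for (i in 1:10) {
    v <- stats::runif(sample(5:40, 1))
    s <- summarize_performance(v)
    expect_equal(s$q90, oracle_quantile(v, 0.9))
    expect_equal(s$median, oracle_quantile(v, 0.5))
    expect_true(s$q25 <= s$median && s$median <= s$q75 && s$q75 <= s$q90)
  }
  expect_error(summarize_performance(numeric(0)), "no values")
})

test_that("designs round-trip through YAML configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("study_id: study2",
               "collections: [c1, c2, c3]",
               "prevalence_grid: [0.01, 0.025, 0.05]",
               "n_rel_grid: [20, 40]",
               "training_grid: [1, 2, 5]",
               "n_replications: 50",
               "master_seed: 11"), path)
  d <- design_from_yaml(path)
  expect_s3_class(d, "experiment_design")
  expect_equal(attr(enumerate_runs(d), "n_artificial_collections"), 3 * 3 * 2 * 50)
})
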