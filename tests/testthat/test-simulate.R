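sim_fixture <- function(n = 120, prev = 0.1, seed = 31) {
  x <- generate_corpus(corpus_spec(n_total = n, prevalence = prev, vocab_size = 150,
                                   doc_length_mean = 20, signal_strength = 0.9,
                                   noise_rate = 0, seed = seed))
  parts <- sample_training_set(x, training_spec(1, 1, FALSE, seed = seed + 1))
  list(x = x, parts = parts)
}

test_that("traces are a permutation of the screening set", {
  fx <- sim_fixture()
  tr <- run_simulation(fx$parts$screening, fx$parts$training,
                       al_config("lr", "tfidf", retrain_interval = 10, seed = 7))
  expect_equal(nrow(tr$ordered), n_records(fx$x))
  expect_setequal(tr$ordered$record_id, fx$x$record_id)
  expect_equal(tr$ordered$position, seq_len(n_records(fx$x)))
  expect_true(tr$includes_training_in_positions)
  expect_identical(tr$ordered$record_id[1:2], fx$parts$training$record_id)
})

test_that("the model is refit once per retrain interval", {
  fx <- sim_fixture(n = 105)
  n_cand <- 105 - 2  # training occupies two in-collection positions
  for (k in c(1, 10, 50)) {
    tr <- run_simulation(fx$parts$screening, fx$parts$training,
                         al_config("lr", "tfidf", retrain_interval = k, seed = 7))
    expect_equal(tr$n_model_fits, ceiling(n_cand / k))
  }
})

test_that("retrain interval changes order at most, never membership", {
  fx <- sim_fixture(n = 80)
  t1 <- run_simulation(fx$parts$screening, fx$parts$training,
                       al_config("lr", "tfidf", retrain_interval = 1, seed = 7))
  t10 <- run_simulation(fx$parts$screening, fx$parts$training,
                        al_config("lr", "tfidf", retrain_interval = 10, seed = 7))
  expect_setequal(t1$ordered$record_id, t10$ordered$record_id)
})

test_that("simulation is deterministic given the config seed", {
  fx <- sim_fixture(n = 60)
  cfg <- al_config("lr", "tfidf", retrain_interval = 5, seed = 11)
  t1 <- run_simulation(fx$parts$screening, fx$parts$training, cfg)
  t2 <- run_simulation(fx$parts$screening, fx$parts$training, cfg)
  expect_identical(t1$ordered, t2$ordered)
})

test_that("disjoint training sets stay outside the trace", {
  x <- generate_corpus(corpus_spec(n_total = 150, prevalence = 0.1, vocab_size = 150,
                                   doc_length_mean = 20, seed = 5))
  screen <- sample_fixed_relevant(x, 5, 0.05, seed = 6)
  parts <- sample_training_set(x, training_spec(2, 5, TRUE, seed = 7),
                               screening = screen)
  tr <- run_simulation(parts$screening, parts$training,
                       al_config("lr", "tfidf", retrain_interval = 10, seed = 8))
  expect_false(tr$includes_training_in_positions)
  expect_equal(nrow(tr$ordered), n_records(screen))
  expect_false(any(parts$training$record_id %in% tr$ordered$record_id))
})

test_that("single-class training sets are rejected before any iteration", {
  fx <- sim_fixture(n = 40)
  bad <- fx$parts$training[fx$parts$training$label == "relevant", , drop = FALSE]
  expect_error(run_simulation(fx$parts$screening, bad,
                              al_config("lr", "tfidf", seed = 1)),
               "relevant and one irrelevant")
})

test_that("the perfect-ranking stub reveals all relevant records first", {
  fx <- sim_fixture(n = 100, prev = 0.2)
  cfg <- al_config("oracle", "tfidf", retrain_interval = 10, seed = 3)
  tr <- run_simulation(fx$parts$screening, fx$parts$training, cfg)
  lab <- tr$ordered$label
  R <- sum(lab == "relevant")
  # training head is 1 relevant + 1 irrelevant; all candidate relevants
  # surface immediately after it
  expect_true(all(lab[3:(R + 1)] == "relevant"))
  expect_true(all(lab[(R + 2):length(lab)] == "irrelevant"))
})

test_that("random-order screening is seeded and uniform in expectation", {
  x <- generate_corpus(corpus_spec(n_total = 200, prevalence = 0.15, vocab_size = 120,
                                   doc_length_mean = 10, seed = 17))
  expect_identical(run_random_order(x, 5)$ordered, run_random_order(x, 5)$ordered)
  differs <- vapply(1:10, function(i) {
    !identical(run_random_order(x, i)$ordered$record_id,
               run_random_order(x, i + 100)$ordered$record_id)
  }, logical(1))
  expect_true(all(differs))
  # mean sensitivity at half depth equals the screened fraction (hypergeometric)
  half <- n_records(x) %/% 2
  sens <- vapply(1:200, function(i) {
    sensitivity(confusion_at(run_random_order(x, i), half))
  }, numeric(1))
  expect_gt(mean(sens), 0.45)
  expect_lt(mean(sens), 0.55)
})

test_that("sensitivity is nondecreasing along any trace", {
  fx <- sim_fixture(n = 80)
  tr <- run_simulation(fx$parts$screening, fx$parts$training,
                       al_config("lr", "tfidf", retrain_interval = 10, seed = 2))
  sens <- vapply(seq_len(nrow(tr$ordered)), function(d)
    sensitivity(confusion_at(tr, d)), numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("trace serialisation writes positions, labels and cumulative hits", {
  tr <- trace_from_pattern("RIIRI")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  df <- utils::read.csv(path)
  expect_equal(df$cumulative_tp, c(1, 1, 1, 2, 2))
  expect_equal(df$position, 1:5)
})
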