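test_that("TF-IDF matches the documented smoothed formula", {
  # three docs; token "shared" in all, "rare" in one
  x <- collection(title = c("shared alpha", "shared beta", "shared rare"),
                  abstract = c("", "", ""), label = c(1, 0, 0))
  suppressWarnings(f <- extract_features(x, "tfidf"))
  m <- as.matrix(f$matrix)
  N <- 3
  idf_shared <- log((1 + N) / (1 + 3)) + 1       # floor value: exactly 1
  idf_rare <- log((1 + N) / (1 + 1)) + 1
  expect_equal(idf_shared, 1)
  # row 3 before normalisation: shared -> 1 * 1, rare -> 1 * idf_rare
  raw <- c(shared = idf_shared, rare = idf_rare)
  expected <- raw / sqrt(sum(raw^2))
  expect_equal(m[3, "shared"], unname(expected["shared"]))
  expect_equal(m[3, "rare"], unname(expected["rare"]))
  # rows are unit length
  expect_equal(unname(rowSums(m^2)), rep(1, 3))
})

test_that("documents with disjoint token sets are orthogonal", {
  x <- collection(title = c("apple banana", "carrot daikon"),
                  abstract = c("", ""), label = c(1, 0))
  f <- extract_features(x, "tfidf")
  m <- as.matrix(f$matrix)
  expect_equal(sum(m[1, ] * m[2, ]), 0)
  expect_true(f$nonnegative)
})

test_that("empty-text records yield zero rows with a warning", {
  x <- collection(title = c("words here", "..."), abstract = c("more", "..."),
                  label = c(1, 0))
  expect_warning(f <- extract_features(x, "tfidf"), "no tokens")
  expect_equal(sum(as.matrix(f$matrix)[2, ]), 0)
})

test_that("the hashed stub is a deterministic signed embedding", {
  x <- tiny_collection()
  f1 <- extract_features(x, "hashed_stub")
  f2 <- extract_features(x, "hashed_stub")
  expect_identical(f1, f2)
  expect_false(f1$nonnegative)
  expect_equal(nrow(f1$matrix), n_records(x))
  expect_error(extract_features(x, "sbert"), "register_extractor")
})

test_that("naive Bayes is flagged incompatible with signed extractors", {
  x <- tiny_collection()
  tfidf <- extract_features(x, "tfidf")
  stub <- extract_features(x, "hashed_stub")
  expect_true(check_compatibility("nb", tfidf))
  expect_false(check_compatibility("nb", stub))
  for (cls in c("lr", "svm", "rf", "nn2layer")) {
    expect_true(check_compatibility(cls, stub))
  }
  expect_error(al_config("nb", "sbert"), "nonnegative")
  expect_error(fit_model(stub, data.frame(record_id = c("a", "b"),
                                          label = c("relevant", "irrelevant")),
                         "nb"), "negative")
})

test_that("dynamic resampling upweights the relevant class to the target share", {
  labeled <- data.frame(record_id = sprintf("r%02d", 1:11),
                        label = c("relevant", rep("irrelevant", 10)))
  out <- balance_training(labeled, "dynamic_resampling", seed = 3)
  expect_equal(nrow(out), 11L)
  expect_gte(sum(out$label == "relevant"), 5L)
  expect_true(all(out$record_id[out$label == "relevant"] == "r01"))

  balanced <- data.frame(record_id = sprintf("r%02d", 1:10),
                         label = rep(c("relevant", "irrelevant"), each = 5))
  expect_identical(balance_training(balanced, "dynamic_resampling", seed = 1),
                   balanced)
  expect_identical(balance_training(labeled, "none"), labeled)
  expect_error(balance_training(labeled[labeled$label == "irrelevant", ],
                                "dynamic_resampling"), "relevant")
})

test_that("every classifier fits, scores finitely, and is seed-deterministic", {
  x <- generate_corpus(corpus_spec(n_total = 60, prevalence = 0.2, vocab_size = 120,
                                   doc_length_mean = 20, signal_strength = 0.9,
                                   noise_rate = 0, seed = 8))
  f <- extract_features(x, "tfidf")
  train <- data.frame(record_id = x$record_id[1:20], label = x$label[1:20])
  expect_gte(sum(train$label == "relevant"), 2)  # fixture provides both classes
  cand <- x$record_id[21:60]
  for (cls in c("lr", "nb", "svm", "rf", "nn2layer")) {
    m1 <- fit_model(f, train, cls, seed = 5)
    m2 <- fit_model(f, train, cls, seed = 5)
    s1 <- score_records(m1, f, cand)
    s2 <- score_records(m2, f, cand)
    expect_true(all(is.finite(s1)), info = cls)
    expect_identical(s1, s2, info = cls)
    if (cls %in% c("lr", "nb", "rf", "nn2layer")) {
      expect_true(all(s1 >= 0 & s1 <= 1), info = cls)
    }
    expect_setequal(rank_candidates(m1, f, cand), cand)
  }
})

test_that("logistic regression separates a separable toy problem", {
  # two clusters of disjoint vocabulary
  x <- collection(
    title = c(sprintf("pos%d signal marker", 1:5), sprintf("neg%d noise filler", 1:5)),
    abstract = rep("", 10),
    label = rep(c(1, 0), each = 5))
  f <- extract_features(x, "tfidf")
  train <- data.frame(record_id = x$record_id, label = x$label)
  m <- fit_model(f, train, "lr", seed = 1)
  s <- score_records(m, f, x$record_id)
  expect_gt(min(s[x$label == "relevant"]), max(s[x$label == "irrelevant"]))
})

test_that("nn2layer handles tiny training sets via clamped hidden widths", {
  x <- tiny_collection()
  f <- extract_features(x, "tfidf")
  train <- data.frame(record_id = c("a", "b", "c", "d"),
                      label = c("relevant", "irrelevant", "relevant", "irrelevant"))
  m <- fit_model(f, train, "nn2layer", seed = 2, params = list(epochs = 50))
  expect_s3_class(m, "relevance_model")
  expect_true(all(is.finite(score_records(m, f, x$record_id))))
})

test_that("ranking sorts by score with a stable original-order tie-break", {
  # docs c, d, e share identical text, so their scores tie exactly and the
  # original candidate order must be preserved among them
  x <- collection(record_id = letters[1:6],
                  title = c("signal marker", "noise filler", rep("common words", 3),
                            "signal marker extra"),
                  abstract = rep("", 6),
                  label = c(1, 0, 0, 0, 0, 1))
  f <- extract_features(x, "tfidf")
  train <- data.frame(record_id = c("a", "b"), label = c("relevant", "irrelevant"))
  m <- fit_model(f, train, "lr", seed = 1)
  r <- rank_candidates(m, f, c("c", "d", "e", "f"))
  expect_identical(r[which(r %in% c("c", "d", "e"))], c("c", "d", "e"))
  expect_identical(r[1], "f")  # shares the relevant vocabulary
  expect_identical(rank_candidates(m, f, "c"), "c")
  expect_error(rank_candidates(m, f, character(0)), "no candidates")
})
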