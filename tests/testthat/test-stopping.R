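test_that("the consecutive-irrelevant rule stops at the end of the first run", {
  tr <- screening_trace(c("relevant", rep("irrelevant", 50), rep("relevant", 3)))
  expect_equal(stop_data_driven(tr, 50), 51L)
  expect_true(is.na(stop_data_driven(screening_trace(rep("relevant", 5)), 2)))
  tr2 <- trace_from_pattern("RRIRI")
  expect_equal(stop_data_driven(tr2, 1), 3L)  # first irrelevant label
  # fractional cutoffs convert to ceil(fraction * N)
  tr3 <- screening_trace(c(rep("irrelevant", 30), rep("relevant", 2)))
  expect_equal(stop_data_driven(tr3, 0.25), 8L)  # ceil(0.25 * 32) = 8
})

test_that("the time-based rule stops at the ceiling of the fraction", {
  mk <- function(n) random_label_trace(n, 2, seed = n)
  expect_equal(stop_time_based(mk(1000), 0.10), 100L)
  expect_equal(stop_time_based(mk(1800), 0.35), 630L)
  expect_equal(stop_time_based(mk(7), 1), 7L)
  expect_equal(stop_time_based(mk(33), 0.1), 4L)  # ceil(3.3)
})

test_that("the key-study rule waits for the last key record", {
  tr <- random_label_trace(40, 10, seed = 4)
  ids <- tr$ordered$record_id
  expect_equal(stop_key_study(tr, ids[c(3, 17)]), 17L)
  expect_equal(stop_key_study(tr, ids[1]), 1L)
  keys <- ids[c(5, 11, 2, 31, 19, 40, 8)]
  expect_equal(stop_key_study(tr, keys), oracle_key_study(ids, keys))
  expect_error(stop_key_study(tr, "nonexistent"), "absent")
})

test_that("combined all-met stopping is the max of member first-met positions", {
  # a 50-run ending inside the first 10%: the time-based member binds
  lab <- c(rep("relevant", 3), rep("irrelevant", 50), rep("relevant", 20),
           rep("irrelevant", 600))
  tr <- screening_trace(lab)  # N = 673
  out <- stop_combined(tr, list(rule_time_based(0.10), rule_data_driven(50)))
  expect_equal(out$stop_position, max(53L, ceiling(0.10 * 673)))
  expect_equal(out$sensitivity_at_stop,
               sensitivity(confusion_at(tr, out$stop_position)))

  # a key study at the final position forces screening to exhaustion
  keys <- tr$ordered$record_id[nrow(tr$ordered)]
  out2 <- stop_combined(tr, list(rule_time_based(0.10), rule_key_study(keys)))
  expect_equal(out2$stop_position, nrow(tr$ordered))

  # unsatisfiable member: outcome is none, with a diagnostic
  allrel <- screening_trace(rep("relevant", 30))
  out3 <- stop_combined(allrel, list(rule_time_based(0.5), rule_data_driven(5)))
  expect_true(is.na(out3$stop_position))
  expect_match(out3$diagnostics, "data_driven")
})

test_that("the breakout run pre-empts the fallback only when it ends earlier", {
  # all relevant found by 10%; a 15% irrelevant run then ends well before the
  # 40% time-based fallback
  N <- 1000
  lab <- rep("irrelevant", N)
  lab[1:100] <- "relevant"
  tr <- screening_trace(lab)
  out <- stop_breakout(tr, 0.15, rule_time_based(0.40))
  expect_equal(out$stop_position, 100L + 150L)  # run of ceil(0.15*1000) after last find
  expect_equal(out$triggered_by, "breakout")
  expect_equal(out$sensitivity_at_stop, 1)

  # no qualifying run: the fallback position is used
  lab2 <- rep(c("relevant", rep("irrelevant", 9)), 100)
  tr2 <- screening_trace(lab2)
  out2 <- stop_breakout(tr2, 0.15, rule_time_based(0.40))
  expect_equal(out2$stop_position, 400L)

  # run completing after the fallback: min wins
  lab3 <- c(rep(c("relevant", "irrelevant"), 450), rep("irrelevant", 100))
  tr3 <- screening_trace(lab3)
  out3 <- stop_breakout(tr3, 0.10, rule_time_based(0.40))
  expect_equal(out3$stop_position, 400L)
})

test_that("the random-phase completion check enforces the 1% and 100 floors", {
  expect_true(safe_phase1_check(2000, 200, 6))
  expect_false(safe_phase1_check(2000, 19, 3))
  expect_false(safe_phase1_check(2000, 200, 0))
  # 1% of 50,000 = 500 > 100
  expect_false(safe_phase1_check(50000, 400, 2))
  expect_true(safe_phase1_check(50000, 500, 1))
  # when 1% < 100 the floor of 100 applies
  expect_false(safe_phase1_check(2000, 99, 5))
  expect_true(safe_phase1_check(2000, 100, 5))
})

test_that("all stopping rules agree with brute-force scans on random traces", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(10:120, 1)
    tr <- random_label_trace(n, sample.int(max(1, n %/% 3), 1), seed = 7000 + i)
    lab <- tr$ordered$label
    ids <- tr$ordered$record_id

    cutoff <- sample(1:15, 1)
    expect_identical(stop_data_driven(tr, cutoff), oracle_data_driven(lab, cutoff))

    f <- stats::runif(1, 0.05, 1)
    expect_equal(stop_time_based(tr, f), oracle_time_based(n, f))

    keys <- sample(ids, sample.int(min(5, n), 1))
    expect_equal(stop_key_study(tr, keys), oracle_key_study(ids, keys))

    members <- list(rule_time_based(stats::runif(1, 0.05, 0.8)),
                    rule_data_driven(sample(1:8, 1)),
                    rule_min_relevant(sample(1:3, 1)))
    got <- stop_combined(tr, members)
    want <- oracle_combined(lab, ids, members)
    expect_identical(got$stop_position, want)
  }
})

test_that("cost at stop grows and sensitivity never falls as cutoffs rise", {
  tr <- random_label_trace(300, 25, seed = 55)
  fracs <- c(0.1, 0.2, 0.4, 0.7, 1)
  pos <- vapply(fracs, function(f) stop_time_based(tr, f), integer(1))
  sens <- vapply(pos, function(p) sensitivity(confusion_at(tr, p)), numeric(1))
  expect_true(all(diff(pos) > 0))
  expect_true(all(diff(sens) >= 0))
})

test_that("rule sets round-trip through YAML configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rules:",
               "  - rule: time_based",
               "    fraction: 0.10",
               "  - rule: data_driven",
               "    cutoff: 50",
               "  - rule: min_relevant",
               "    count: 2"), path)
  rules <- rules_from_yaml(path)
  expect_length(rules, 3L)
  lab <- c(rep("relevant", 3), rep("irrelevant", 60), rep("relevant", 40),
           rep("irrelevant", 200))
  tr <- screening_trace(lab)
  out <- stop_combined(tr, rules)
  expect_equal(out$stop_position,
               oracle_combined(lab, tr$ordered$record_id, rules))
  writeLines(c("rules:", "  - rule: mystery"), path)
  expect_error(rules_from_yaml(path), "unknown rule")
})
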