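# Shared fixtures and independent oracles used across test files.

# A tiny hand-built collection with known counts.
tiny_collection <- function() {
  collection(
    record_id = c("a", "b", "c", "d", "e", "f"),
    title = c("mindfulness therapy trial", "galaxy cluster survey",
              "mindfulness stress reduction", "protein folding dynamics",
              "soil microbiome diversity", "mindfulness anxiety outcomes"),
    abstract = c("randomized mindfulness intervention outcomes",
                 "dark matter lensing maps",
                 "mindfulness based stress program adults",
                 "molecular simulation energy landscape",
                 "bacterial community sequencing fields",
                 "clinical trial mindfulness anxiety adults"),
    label = c(1, 0, 1, 0, 0, 1),
    key_study = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

# Build a screening trace directly from a relevant/irrelevant pattern string,
# e.g. "RIIRI".
trace_from_pattern <- function(pattern) {
  lab <- strsplit(pattern, "")[[1]]
  screening_trace(ifelse(lab == "R", "relevant", "irrelevant"))
}

random_label_trace <- function(n, n_rel, seed) {
  set.seed(seed)
  lab <- rep("irrelevant", n)
  lab[sample.int(n, n_rel)] <- "relevant"
  screening_trace(lab)
}

# --- Independent brute-force oracles -------------------------------------

# Consecutive-irrelevant rule: scan every position, count the run ending
# there. O(N^2) on purpose: independent of the rle-based implementation.
oracle_data_driven <- function(labels, cutoff) {
  for (i in seq_along(labels)) {
    if (i < cutoff) next
    window <- labels[(i - cutoff + 1):i]
    if (all(window == "irrelevant")) return(i)
  }
  NA_integer_
}

oracle_time_based <- function(n, fraction) {
  for (i in seq_len(n)) if (i / n >= fraction - 1e-12) return(i)
  n
}

oracle_key_study <- function(ids, key_ids) {
  last <- 0L
  for (i in seq_along(ids)) if (ids[i] %in% key_ids) last <- i
  last
}

oracle_min_relevant <- function(labels, count) {
  found <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == "relevant") found <- found + 1L
    if (found >= count) return(i)
  }
  NA_integer_
}

# All-met combination: walk forward, checking each member's "met" state at
# every position. Run lengths are tracked with a streak counter and a
# running maximum, independent of the rle-based implementation.
oracle_combined <- function(labels, ids, members) {
  n <- length(labels)
  streak <- integer(n)
  s <- 0L
  for (i in seq_len(n)) {
    s <- if (labels[i] == "irrelevant") s + 1L else 0L
    streak[i] <- s
  }
  longest_run_so_far <- cummax(streak)
  rel_so_far <- cumsum(labels == "relevant")
  key_seen_at <- function(keys) {
    pos <- 0L
    for (i in seq_len(n)) if (ids[i] %in% keys) pos <- i
    pos
  }
  for (pos in seq_len(n)) {
    all_met <- TRUE
    for (m in members) {
      met <- switch(m$rule_id,
        data_driven = {
          cutoff <- if (m$cutoff < 1) max(1, ceiling(m$cutoff * n - 1e-9)) else m$cutoff
          longest_run_so_far[pos] >= cutoff
        },
        time_based = pos / n >= m$fraction - 1e-12,
        key_study = pos >= key_seen_at(m$key_ids),
        min_relevant = rel_so_far[pos] >= m$count)
      if (!met) { all_met <- FALSE; break }
    }
    if (all_met) return(pos)
  }
  NA_integer_
}

# Linear-interpolation quantile, computed from the textbook definition.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Trapezoidal AUC of scores against binary labels (1 = positive).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
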