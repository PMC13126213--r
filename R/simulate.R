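#' Active-learning configuration
#'
#' Bundles the choices that define one screening algorithm: the classifier,
#' the feature extractor, the certainty-based query strategy, the balancing
#' strategy, and the retraining interval `k` (the ranking is refreshed after
#' every k-th revealed label; between refits the simulator walks down the
#' current ranking). The special classifier id `"oracle"` is a
#' perfect-ranking stub that scores candidates by their true labels; it
#' exists for analytic checks, not as a screening algorithm.
#'
#' @param classifier_id `"lr"`, `"nb"`, `"svm"`, `"rf"`, `"nn2layer"`, or
#'   `"oracle"`.
#' @param extractor_id `"tfidf"`, `"hashed_stub"`, or a registered plug-in.
#' @param query_strategy only `"certainty"` is implemented.
#' @param balance_strategy `"dynamic_resampling"` or `"none"`.
#' @param retrain_interval refit period k (>= 1).
#' @param seed integer seed governing every random choice in the run.
#' @param extractor_params,classifier_params parameter lists passed through.
#' @return An object of class `al_config`.
#' @export
al_config <- function(classifier_id = "lr", extractor_id = "tfidf",
                      query_strategy = "certainty",
                      balance_strategy = c("dynamic_resampling", "none"),
                      retrain_interval = 1, seed = 1,
                      extractor_params = list(), classifier_params = list()) {
  balance_strategy <- match.arg(balance_strategy)
  stopifnot(query_strategy == "certainty", retrain_interval >= 1)
  if (classifier_id == "nb" && extractor_id %in% c("doc2vec", "sbert", "hashed_stub")) {
    stop("naive Bayes requires a nonnegative feature extractor; '",
         extractor_id, "' produces signed values")
  }
  structure(list(classifier_id = classifier_id, extractor_id = extractor_id,
                 query_strategy = query_strategy, balance_strategy = balance_strategy,
                 retrain_interval = as.integer(retrain_interval),
                 seed = as.integer(seed),
                 extractor_params = extractor_params,
                 classifier_params = classifier_params),
            class = "al_config")
}

new_trace <- function(ordered, training_ids, config, seed,
                      includes_training, n_model_fits = NA_integer_) {
  stopifnot(is.data.frame(ordered))
  ordered$position <- seq_len(nrow(ordered))
  structure(list(ordered = ordered[, c("position", "record_id", "label")],
                 training_ids = training_ids, config = config, seed = seed,
                 includes_training_in_positions = includes_training,
                 n_model_fits = n_model_fits),
            class = "screening_trace")
}

#' Construct a screening trace from an ordered label sequence
#'
#' Low-level constructor used when the screening order is already known
#' (e.g. assembling traces for stopping-rule analysis). Most users obtain
#' traces from [run_simulation()] or [run_random_order()].
#'
#' @param labels ordered relevance labels; anything accepted by
#'   [coerce_labels()].
#' @param record_id optional ids (generated if `NULL`).
#' @return A `screening_trace`.
#' @export
screening_trace <- function(labels, record_id = NULL) {
  lab <- coerce_labels(labels)
  if (anyNA(lab)) stop("unparseable label(s) in trace")
  if (is.null(record_id)) record_id <- sprintf("trc%05d", seq_along(lab))
  new_trace(data.frame(record_id = as.character(record_id), label = lab,
                       stringsAsFactors = FALSE),
            training_ids = character(), config = NULL, seed = NA_integer_,
            includes_training = FALSE)
}

trace_length <- function(trace) nrow(trace$ordered)
trace_labels <- function(trace) trace$ordered$label
trace_n_relevant <- function(trace) sum(trace$ordered$label == "relevant")

#' Simulate active-learning screening to exhaustion
#'
#' Runs the full human-in-the-loop screening loop against oracle labels:
#' fit the classifier on the training set plus all labels revealed so far
#' (rebalanced per the config), rank the unlabeled records by predicted
#' relevance, reveal the stored label of the top-ranked record, and repeat
#' until the screening set is exhausted. The model is refit only after every
#' `retrain_interval`-th revealed label; within a batch the simulator
#' reveals records in the current rank order without re-ranking. The trace
#' always runs to exhaustion so that stopping rules can be evaluated post
#' hoc on identical orderings.
#'
#' When the training records are members of the screening collection
#' (non-disjoint designs) they occupy positions 1..t of the trace and count
#' as screened; with a disjoint training set the trace covers the screening
#' set only.
#'
#' @param screening an `abstract_collection` to screen.
#' @param training an `abstract_collection` (or data frame with `record_id`,
#'   `title`, `abstract`, `label`) holding the initial training records;
#'   must contain both classes.
#' @param config an [al_config()].
#' @param features optional precomputed `feature_matrix` covering training
#'   and screening records; when `NULL` the extractor is fitted once on the
#'   union of training and screening records.
#' @return A `screening_trace`.
#' @export
run_simulation <- function(screening, training, config, features = NULL) {
  validate_collection(screening)
  stopifnot(inherits(config, "al_config"))
  if (sum(training$label == "relevant") < 1 || sum(training$label == "irrelevant") < 1) {
    stop("training set must contain at least one relevant and one irrelevant record")
  }
  non_disjoint <- all(training$record_id %in% screening$record_id)
  if (is.null(features) && config$classifier_id != "oracle") {
    union_col <- if (non_disjoint) screening else {
      validate_collection(new_collection(as.data.frame(training)))
      new_collection(rbind(as.data.frame(training), as.data.frame(screening)))
    }
    features <- extract_features(union_col, config$extractor_id, config$extractor_params)
    if (!check_compatibility(config$classifier_id, features)) {
      stop("classifier '", config$classifier_id,
           "' is incompatible with extractor '", config$extractor_id, "'")
    }
  }
  candidates <- setdiff(screening$record_id, training$record_id)
  if (!length(candidates)) stop("screening set contains no unlabeled records")
  cand_label <- screening$label[match(candidates, screening$record_id)]
  names(cand_label) <- candidates
  labeled <- data.frame(record_id = training$record_id,
                        label = training$label, stringsAsFactors = FALSE)
  k <- config$retrain_interval
  revealed_ids <- character(0)
  n_fits <- 0L
  remaining <- candidates
  while (length(remaining)) {
    n_fits <- n_fits + 1L
    fit_seed <- derive_seed(config$seed, "fit", n_fits)
    if (config$classifier_id == "oracle") {
      scores <- as.numeric(cand_label[remaining] == "relevant")
      ranked <- remaining[order(-scores, method = "radix")]
    } else {
      train_multiset <- balance_training(labeled, config$balance_strategy,
                                         seed = derive_seed(fit_seed, "balance"))
      model <- fit_model(features, train_multiset, config$classifier_id,
                         seed = fit_seed, params = config$classifier_params)
      ranked <- rank_candidates(model, features, remaining)
    }
    batch <- ranked[seq_len(min(k, length(ranked)))]
    revealed_ids <- c(revealed_ids, batch)
    labeled <- rbind(labeled, data.frame(record_id = batch,
                                         label = unname(cand_label[batch]),
                                         stringsAsFactors = FALSE))
    remaining <- remaining[!remaining %in% batch]
  }
  ordered_ids <- if (non_disjoint) c(training$record_id, revealed_ids) else revealed_ids
  ordered_lab <- if (non_disjoint) {
    screening$label[match(ordered_ids, screening$record_id)]
  } else {
    unname(cand_label[ordered_ids])
  }
  new_trace(data.frame(record_id = ordered_ids, label = ordered_lab,
                       stringsAsFactors = FALSE),
            training_ids = training$record_id, config = config,
            seed = config$seed, includes_training = non_disjoint,
            n_model_fits = n_fits)
}

#' Screen in uniformly random order
#'
#' The random-screening baseline (and the prescreening phase of phased
#' protocols): a seeded uniform permutation of the screening set.
#'
#' @param screening an `abstract_collection` (nonempty).
#' @param seed integer seed.
#' @return A `screening_trace`.
#' @export
run_random_order <- function(screening, seed) {
  validate_collection(screening)
  if (!n_records(screening)) stop("screening set is empty")
  perm <- with_seed(seed, sample.int(n_records(screening)))
  new_trace(data.frame(record_id = screening$record_id[perm],
                       label = screening$label[perm], stringsAsFactors = FALSE),
            training_ids = character(), config = NULL, seed = seed,
            includes_training = FALSE)
}

#' @export
print.screening_trace <- function(x, ...) {
  cat(sprintf("<screening_trace> N_s = %d, R = %d%s%s\n",
              trace_length(x), trace_n_relevant(x),
              if (length(x$training_ids))
                sprintf(", training records = %d (%s trace positions)",
                        length(x$training_ids),
                        if (x$includes_training_in_positions) "inside" else "outside")
              else "",
              if (!is.na(x$n_model_fits)) sprintf(", model fits = %d", x$n_model_fits) else ""))
  invisible(x)
}

#' @export
summary.screening_trace <- function(object, s = 0.95, p = 0.10, ...) {
  out <- list(
    n_screen = trace_length(object),
    n_relevant = trace_n_relevant(object),
    sc = screening_cost_at_sensitivity(object, s)$value,
    fpr = fpr_at_sensitivity(object, s)$value,
    wss = wss_at_sensitivity(object, s)$value,
    rrf = rrf_at(object, p)$value,
    s = s, p = p)
  class(out) <- "summary.screening_trace"
  out
}

#' @export
print.summary.screening_trace <- function(x, ...) {
  cat(sprintf("Screening trace over %d records (%d relevant)\n", x$n_screen, x$n_relevant))
  cat(sprintf("  SC@%.0f%%  = %6.2f%%   (screened fraction to reach %.0f%% sensitivity)\n",
              100 * x$s, 100 * x$sc, 100 * x$s))
  cat(sprintf("  WSS@%.0f%% = %6.2f%%   (workload saved at that sensitivity)\n",
              100 * x$s, 100 * x$wss))
  cat(sprintf("  FPR@%.0f%% = %6.2f%%   (irrelevant records screened at that depth)\n",
              100 * x$s, 100 * x$fpr))
  cat(sprintf("  RRF@%.0f%% = %6.2f%%   (sensitivity after screening %.0f%%)\n",
              100 * x$p, 100 * x$rrf, 100 * x$p))
  invisible(x)
}

#' Plot the recall curve of a screening trace
#'
#' Sensitivity (fraction of relevant records found) against the fraction of
#' records screened, with the diagonal random-screening expectation for
#' reference.
#'
#' @param x a `screening_trace`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.screening_trace <- function(x, ...) {
  R <- trace_n_relevant(x)
  if (R == 0) stop("trace contains no relevant records")
  frac <- seq_len(trace_length(x)) / trace_length(x)
  sens <- cumsum(trace_labels(x) == "relevant") / R
  graphics::plot(frac, sens, type = "s", xlab = "fraction screened",
                 ylab = "sensitivity", ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Serialise a screening trace to CSV
#'
#' One row per screened record: position, record id, label, cumulative
#' relevant count.
#'
#' @param trace a `screening_trace`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- trace$ordered
  df$cumulative_tp <- cumsum(df$label == "relevant")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
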