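#' Heuristic stopping rules for screening traces
#'
#' Rule constructors for use with [stop_combined()] and [stop_breakout()].
#' `rule_data_driven(cutoff)` is satisfied once a run of `cutoff`
#' consecutive irrelevant labels has occurred (a fractional cutoff is
#' converted to `ceiling(cutoff * N_s)` records); `rule_time_based(fraction)`
#' once `ceiling(fraction * N_s)` records have been screened;
#' `rule_key_study(key_ids)` once every key record has surfaced;
#' `rule_min_relevant(count)` once at least `count` relevant records have
#' been found (e.g. twice the number found during a random prescreening
#' phase).
#'
#' @param cutoff consecutive-irrelevant threshold: a count (>= 1) or, if
#'   below 1, a fraction of the trace length.
#' @param fraction fraction of the trace length in (0, 1].
#' @param key_ids nonempty character vector of record ids.
#' @param count minimum number of relevant records (>= 1).
#' @return A `stopping_rule` object.
#' @name stopping_rules
NULL

new_rule <- function(rule_id, ...) {
  structure(list(rule_id = rule_id, ...), class = "stopping_rule")
}

#' @rdname stopping_rules
#' @export
rule_data_driven <- function(cutoff) {
  stopifnot(cutoff > 0)
  new_rule("data_driven", cutoff = cutoff)
}

#' @rdname stopping_rules
#' @export
rule_time_based <- function(fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  new_rule("time_based", fraction = fraction)
}

#' @rdname stopping_rules
#' @export
rule_key_study <- function(key_ids) {
  stopifnot(length(key_ids) >= 1)
  new_rule("key_study", key_ids = as.character(key_ids))
}

#' @rdname stopping_rules
#' @export
rule_min_relevant <- function(count) {
  stopifnot(count >= 1)
  new_rule("min_relevant", count = as.integer(count))
}

resolve_cutoff <- function(cutoff, N) {
  if (cutoff < 1) max(1L, ceil_frac(cutoff * N)) else as.integer(cutoff)
}

#' Stop after a run of consecutive irrelevant labels
#'
#' The data-driven heuristic: screening stops at the first position that
#' completes a run of `cutoff` consecutive irrelevant labels (commonly 50 in
#' a row).
#'
#' @param trace a `screening_trace`.
#' @param cutoff run length; a count, or a fraction of the trace length if
#'   below 1.
#' @return The stop position, or `NA` if no qualifying run occurs.
#' @export
stop_data_driven <- function(trace, cutoff) {
  stopifnot(inherits(trace, "screening_trace"), cutoff > 0)
  N <- trace_length(trace)
  cutoff <- resolve_cutoff(cutoff, N)
  irr <- trace_labels(trace) == "irrelevant"
  r <- rle(irr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= cutoff)
  if (!length(hit)) return(NA_integer_)
  as.integer(starts[hit[1]] + cutoff - 1L)
}

#' Stop after a fixed fraction of the collection has been screened
#'
#' The time-based heuristic: the stop position is
#' `ceiling(fraction * N_s)`.
#'
#' @param trace a `screening_trace`.
#' @param fraction fraction in (0, 1].
#' @return The stop position (always defined).
#' @export
stop_time_based <- function(trace, fraction) {
  stopifnot(inherits(trace, "screening_trace"), fraction > 0, fraction <= 1)
  max(1L, ceil_frac(fraction * trace_length(trace)))
}

#' Stop once all key studies have surfaced
#'
#' Key studies are records known to be relevant beforehand, hidden among the
#' unscreened records; screening may not stop until the ranking has
#' presented all of them.
#'
#' @param trace a `screening_trace`.
#' @param key_ids record ids of the key studies (must all occur in the
#'   trace).
#' @return The position at which the last key study is revealed.
#' @export
stop_key_study <- function(trace, key_ids) {
  stopifnot(inherits(trace, "screening_trace"), length(key_ids) >= 1)
  pos <- match(as.character(key_ids), trace$ordered$record_id)
  if (anyNA(pos)) {
    stop("key id(s) absent from trace: ",
         paste(utils::head(key_ids[is.na(pos)], 5), collapse = ", "))
  }
  as.integer(max(pos))
}

# first position at which a single rule is (permanently) satisfied
rule_first_met <- function(rule, trace) {
  switch(rule$rule_id,
    data_driven = stop_data_driven(trace, rule$cutoff),
    time_based = stop_time_based(trace, rule$fraction),
    key_study = stop_key_study(trace, rule$key_ids),
    min_relevant = {
      pos <- which(cumsum(trace_labels(trace) == "relevant") >= rule$count)
      if (length(pos)) pos[1] else NA_integer_
    },
    stop("unknown rule '", rule$rule_id, "'"))
}

stop_outcome <- function(trace, position, triggered_by, diagnostics = NULL) {
  out <- list(stop_position = position, triggered_by = triggered_by,
              diagnostics = diagnostics)
  if (!is.na(position)) {
    cm <- confusion_at(trace, position)
    out$sensitivity_at_stop <- sensitivity(cm)
    out$sc_at_stop <- position / trace_length(trace)
  } else {
    out$sensitivity_at_stop <- NA_real_
    out$sc_at_stop <- NA_real_
  }
  structure(out, class = "stop_outcome")
}

#' @export
print.stop_outcome <- function(x, ...) {
  if (is.na(x$stop_position)) {
    cat("<stop_outcome> never triggered:", paste(x$diagnostics, collapse = "; "), "\n")
  } else {
    cat(sprintf("<stop_outcome> stop at position %d (%.1f%% screened), sensitivity %.1f%% [%s]\n",
                x$stop_position, 100 * x$sc_at_stop, 100 * x$sensitivity_at_stop,
                paste(x$triggered_by, collapse = " + ")))
  }
  invisible(x)
}

#' Stop when every member criterion has been met
#'
#' Checklist semantics as in phased screening protocols: each member rule is
#' considered met from the first position at which its condition has been
#' satisfied, permanently thereafter; screening stops at the smallest
#' position at which all members are met (the maximum of the members' first
#' -met positions). If any member can never be satisfied on the trace the
#' outcome carries `NA` with diagnostics.
#'
#' @param trace a `screening_trace`.
#' @param members list of at least two `stopping_rule` objects.
#' @param mode only `"all_met"` is implemented.
#' @return A `stop_outcome`.
#' @export
stop_combined <- function(trace, members, mode = "all_met") {
  stopifnot(inherits(trace, "screening_trace"), mode == "all_met",
            length(members) >= 2)
  pos <- vapply(members, rule_first_met, integer(1), trace = trace)
  ids <- vapply(members, `[[`, "", "rule_id")
  if (anyNA(pos)) {
    return(stop_outcome(trace, NA_integer_, character(),
                        diagnostics = sprintf("rule '%s' never satisfied on this trace",
                                              ids[is.na(pos)])))
  }
  stop_outcome(trace, max(pos), triggered_by = ids)
}

#' Breakout stopping: a high-cutoff run can pre-empt the fallback rule
#'
#' When the ranking performs well, all relevant records surface early and a
#' long run of consecutive irrelevant labels follows; the breakout rule ends
#' screening at the first run of `ceiling(breakout_fraction * N_s)`
#' consecutive irrelevant labels, if that happens before the fallback rule
#' would stop. The stop position is the minimum of the breakout-run position
#' and the fallback position.
#'
#' @param trace a `screening_trace`.
#' @param breakout_fraction consecutive-irrelevant run length as a fraction
#'   of the trace in (0, 1).
#' @param fallback a `stopping_rule` or list of rules (treated as an
#'   all-met combination).
#' @return A `stop_outcome`.
#' @export
stop_breakout <- function(trace, breakout_fraction, fallback) {
  stopifnot(inherits(trace, "screening_trace"),
            breakout_fraction > 0, breakout_fraction < 1)
  run_pos <- stop_data_driven(trace, breakout_fraction)
  fb <- if (inherits(fallback, "stopping_rule")) {
    stop_outcome(trace, rule_first_met(fallback, trace), fallback$rule_id)
  } else {
    stop_combined(trace, fallback)
  }
  if (is.na(fb$stop_position) && is.na(run_pos)) {
    return(stop_outcome(trace, NA_integer_, character(),
                        diagnostics = "neither breakout run nor fallback triggered"))
  }
  cand <- c(breakout = run_pos, fallback = fb$stop_position)
  cand <- cand[!is.na(cand)]
  winner <- names(cand)[which.min(cand)]
  trig <- if (winner == "breakout") "breakout" else fb$triggered_by
  stop_outcome(trace, unname(min(cand)), triggered_by = trig)
}

#' Check the random-prescreening phase completion criterion
#'
#' The random prescreening phase may end once at least 1% of all records
#' (but no fewer than `minimum`, default 100) have been screened and at
#' least one relevant record has been found.
#'
#' @param n_total total number of records retrieved.
#' @param n_random_screened records screened at random so far.
#' @param n_relevant_found relevant records found among them.
#' @param minimum floor on the number of random screens (default 100).
#' @return `TRUE` or `FALSE`.
#' @export
safe_phase1_check <- function(n_total, n_random_screened, n_relevant_found,
                              minimum = 100) {
  stopifnot(n_random_screened <= n_total)
  threshold <- max(ceil_frac(0.01 * n_total), minimum)
  n_random_screened >= threshold && n_relevant_found >= 1
}

#' Read a stopping-rule set from a YAML file
#'
#' Expects a top-level `rules:` sequence; each entry names a `rule` and its
#' parameter (`cutoff` for data_driven, `fraction` for time_based,
#' `key_ids` for key_study, `count` for min_relevant).
#'
#' @param path YAML file path.
#' @return A list of `stopping_rule` objects, usable with [stop_combined()].
#' @export
rules_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- cfg$rules %||% cfg
  lapply(rules, function(r) {
    switch(r$rule,
      data_driven = rule_data_driven(r$cutoff),
      time_based = rule_time_based(r$fraction),
      key_study = rule_key_study(r$key_ids),
      min_relevant = rule_min_relevant(r$count),
      stop("unknown rule '", r$rule, "' in ", path))
  })
}
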