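#' Confusion counts at a screening depth
#'
#' Treating the first `n_screened` trace positions as screened: TP is the
#' number of relevant records screened, FP the irrelevant records screened,
#' FN the relevant records not (yet) screened and TN the irrelevant records
#' not screened. At every depth TP + FP = n_screened and the four counts sum
#' to the trace length.
#'
#' @param trace a `screening_trace`.
#' @param n_screened depth in `[0, N_s]`.
#' @return A list with elements `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_at <- function(trace, n_screened) {
  stopifnot(inherits(trace, "screening_trace"))
  N <- trace_length(trace)
  if (n_screened < 0 || n_screened > N) {
    stop("n_screened must be between 0 and ", N)
  }
  lab <- trace_labels(trace)
  R <- sum(lab == "relevant")
  TP <- if (n_screened == 0) 0L else sum(lab[seq_len(n_screened)] == "relevant")
  list(TP = as.integer(TP), FP = as.integer(n_screened - TP),
       FN = as.integer(R - TP), TN = as.integer(N - R - (n_screened - TP)))
}

#' Sensitivity (recall) from confusion counts
#'
#' The fraction of truly relevant records identified: `TP / (TP + FN)`.
#'
#' @param counts a list with `TP` and `FN` (e.g. from [confusion_at()]).
#' @return A fraction in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  if (counts$TP + counts$FN < 1) stop("sensitivity undefined: no relevant records (R = 0)")
  counts$TP / (counts$TP + counts$FN)
}

metric_result <- function(metric_id, level, value) {
  structure(list(metric_id = metric_id, level = level, value = value),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s@%s = %.2f%%\n", toupper(x$metric_id),
              if (is.null(x$level)) "" else sprintf("%.0f%%", 100 * x$level),
              100 * x$value))
  invisible(x)
}

# first depth at which TP reaches ceiling(s * R); the ceiling rule makes
# 19/20 and 38/40 meet s = 0.95 exactly
depth_at_sensitivity <- function(trace, s) {
  R <- trace_n_relevant(trace)
  if (R < 1) stop("trace contains no relevant records")
  stopifnot(s > 0, s <= 1)
  needed <- max(1L, ceil_frac(s * R))
  rel_pos <- which(trace_labels(trace) == "relevant")
  rel_pos[needed]
}

#' Screening cost at a sensitivity level
#'
#' SC@s is the fraction of the collection that must be screened, in trace
#' order, before sensitivity `s` is reached: `n* / N_s`, where `n*` is the
#' smallest depth with `TP >= ceiling(s * R)`. An SC@95% of 40% means 95% of
#' the relevant records were identified after screening 40% of the records.
#'
#' @param trace a `screening_trace` with at least one relevant record.
#' @param s sensitivity level in (0, 1], default 0.95.
#' @return A `metric_result` with the SC value as a fraction.
#' @export
screening_cost_at_sensitivity <- function(trace, s = 0.95) {
  n_star <- depth_at_sensitivity(trace, s)
  metric_result("sc", s, n_star / trace_length(trace))
}

#' False-positive rate at a sensitivity level
#'
#' The fraction of irrelevant records screened, out of all irrelevant
#' records, at the depth where sensitivity `s` is first reached:
#' `FP / (FP + TN)` at `n*`. Unlike SC it is unaffected by the number of
#' relevant records, so it compares conditions with different prevalence on
#' an equal footing.
#'
#' @inheritParams screening_cost_at_sensitivity
#' @return A `metric_result` with the FPR value as a fraction.
#' @export
fpr_at_sensitivity <- function(trace, s = 0.95) {
  N <- trace_length(trace); R <- trace_n_relevant(trace)
  if (N - R < 1) stop("FPR undefined: trace contains no irrelevant records")
  n_star <- depth_at_sensitivity(trace, s)
  cm <- confusion_at(trace, n_star)
  metric_result("fpr", s, cm$FP / (cm$FP + cm$TN))
}

#' Relevant records found after screening a fraction of the collection
#'
#' RRF@p is the sensitivity at depth `floor(p * N_s)`: the share of relevant
#' records identified after screening a fraction `p` of all records.
#'
#' @param trace a `screening_trace` with at least one relevant record.
#' @param p screened fraction in (0, 1], default 0.10.
#' @return A `metric_result` with the RRF value as a fraction.
#' @export
rrf_at <- function(trace, p = 0.10) {
  stopifnot(p > 0, p <= 1)
  depth <- floor_frac(p * trace_length(trace))
  metric_result("rrf", p, sensitivity(confusion_at(trace, depth)))
}

#' Work saved over sampling at a sensitivity level
#'
#' The fraction of records that do not require screening at sensitivity
#' `s`; the complement of the screening cost, `WSS@s = 1 - SC@s`.
#'
#' @inheritParams screening_cost_at_sensitivity
#' @return A `metric_result` with the WSS value as a fraction.
#' @export
wss_at_sensitivity <- function(trace, s = 0.95) {
  metric_result("wss", s, 1 - screening_cost_at_sensitivity(trace, s)$value)
}

#' Tidy metric table for a screening trace
#'
#' Convenience wrapper evaluating SC, FPR, WSS at `s` and RRF at `p`.
#'
#' @param trace a `screening_trace`.
#' @param s sensitivity level(s).
#' @param p screened fraction(s).
#' @return A data frame with columns `metric_id`, `level`, `value`.
#' @export
trace_metrics <- function(trace, s = 0.95, p = 0.10) {
  rows <- list()
  for (si in s) {
    rows[[length(rows) + 1L]] <- data.frame(metric_id = "sc", level = si,
      value = screening_cost_at_sensitivity(trace, si)$value)
    rows[[length(rows) + 1L]] <- data.frame(metric_id = "fpr", level = si,
      value = fpr_at_sensitivity(trace, si)$value)
    rows[[length(rows) + 1L]] <- data.frame(metric_id = "wss", level = si,
      value = wss_at_sensitivity(trace, si)$value)
  }
  for (pi in p) {
    rows[[length(rows) + 1L]] <- data.frame(metric_id = "rrf", level = pi,
      value = rrf_at(trace, pi)$value)
  }
  do.call(rbind, rows)
}
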