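#' Prevalence-band recommendation table for stopping-rule cutoffs
#'
#' Maps estimated-prevalence bands to recommended stopping-rule cutoffs for
#' the combined (time-based + data-driven + key-study) stopping strategy and
#' the breakout rule. The default table ships only the entries with a
#' published anchor: for prevalence below 2.5%, a time-based cutoff of 40%
#' with a 15% breakout run; for prevalence between 2.5% and 7.5%, a
#' time-based cutoff of 35% with a 5% data-driven cutoff. Bands without
#' configured cutoffs (by default, above 7.5%) deliberately error on lookup
#' rather than guessing; supply a custom `bands` data frame to fill them.
#' Band boundaries are half-open `[low, high)`.
#'
#' @param bands optional data frame with columns `low`, `high`,
#'   `time_based`, `data_driven`, `breakout` (fractions; `NA` = not
#'   configured) partitioning (0, 1) without overlap.
#' @param random_phase_minimum floor on random-prescreen size (default 100).
#' @return An object of class `recommendation_table`.
#' @export
recommendation_table <- function(bands = NULL, random_phase_minimum = 100) {
  if (is.null(bands)) {
    bands <- data.frame(
      low = c(0, 0.025, 0.075),
      high = c(0.025, 0.075, 1),
      time_based = c(0.40, 0.35, NA),
      data_driven = c(NA, 0.05, NA),
      breakout = c(0.15, NA, NA))
  }
  stopifnot(all(c("low", "high", "time_based", "data_driven", "breakout") %in% names(bands)))
  o <- order(bands$low)
  bands <- bands[o, , drop = FALSE]
  if (any(bands$high <= bands$low)) stop("each band needs high > low")
  if (nrow(bands) > 1 && any(abs(bands$low[-1] - bands$high[-nrow(bands)]) > 1e-12)) {
    stop("bands must partition (0, 1) without gaps or overlap")
  }
  structure(list(bands = bands, random_phase_minimum = random_phase_minimum),
            class = "recommendation_table")
}

#' Estimate prevalence from a random screening phase
#'
#' The estimated prevalence is the number of relevant records found divided
#' by the number of randomly screened records. Multiplying the estimate by
#' the total number of retrieved records gives the expected number of
#' relevant records (see [expected_relevant()]), not a prevalence.
#'
#' @param n_relevant_found relevant records identified during random
#'   screening.
#' @param n_random_screened records screened at random (>= 1).
#' @return The estimated prevalence as a fraction; warns when no relevant
#'   record has been found (the random phase completion criterion is not
#'   satisfied).
#' @export
#' @examples
#' estimate_prevalence(6, 200)  # 0.03
estimate_prevalence <- function(n_relevant_found, n_random_screened) {
  if (n_random_screened < 1) stop("at least one record must have been screened")
  if (n_relevant_found == 0) {
    warning("no relevant record found yet; the random screening phase is not complete")
  }
  n_relevant_found / n_random_screened
}

#' Expected number of relevant records in the full collection
#'
#' @param prevalence estimated prevalence fraction.
#' @param n_total total number of retrieved records.
#' @return `prevalence * n_total`.
#' @export
expected_relevant <- function(prevalence, n_total) prevalence * n_total

#' Look up recommended stopping cutoffs for an estimated prevalence
#'
#' Finds the prevalence band containing `prevalence` and returns its
#' configured cutoffs. Bands with no configured cutoffs fail closed: the
#' lookup errors and asks for user-supplied values instead of guessing.
#'
#' @param prevalence estimated prevalence in (0, 1).
#' @param table a [recommendation_table()].
#' @return A list with `band` (`c(low, high)`) and the configured fractions
#'   among `time_based`, `data_driven`, `breakout` (unconfigured entries are
#'   `NA`).
#' @export
#' @examples
#' lookup_cutoffs(0.03)  # mid band: time-based 35%, data-driven 5%
lookup_cutoffs <- function(prevalence, table = recommendation_table()) {
  stopifnot(inherits(table, "recommendation_table"),
            prevalence > 0, prevalence < 1)
  b <- table$bands
  hit <- which(prevalence >= b$low & prevalence < b$high)
  if (!length(hit)) stop("prevalence ", prevalence, " falls outside all configured bands")
  row <- b[hit[1], ]
  if (is.na(row$time_based) && is.na(row$data_driven) && is.na(row$breakout)) {
    stop(sprintf(paste0("no cutoffs configured for the prevalence band [%g, %g); ",
                        "supply values via recommendation_table(bands = ...)"),
                 row$low, row$high))
  }
  list(band = c(low = row$low, high = row$high),
       time_based = row$time_based, data_driven = row$data_driven,
       breakout = row$breakout)
}

#' Project the workload saving of a stopping configuration
#'
#' The projected share of records never screened is
#' `1 - (random_fraction + time_based_cutoff + data_driven_cutoff)`: the
#' random prescreen, the time-based portion of AI-aided screening and the
#' additional consecutive-irrelevant run each consume their fraction of the
#' collection, and everything beyond them is saved. Absolute savings and
#' screening hours assume a fixed reading time per abstract.
#'
#' @param n_total total number of retrieved records.
#' @param random_fraction fraction screened at random (prescreen phase).
#' @param time_based_cutoff time-based heuristic cutoff fraction.
#' @param data_driven_cutoff data-driven heuristic cutoff fraction
#'   (default 0).
#' @param seconds_per_abstract screening time per abstract (default 30 s).
#' @return An object of class `recommendation` with fields
#'   `saving_fraction`, `abstracts_saved` (= `round(saving * n_total)`),
#'   `hours_saved` (exact) and `hours_saved_display` (rounded to the
#'   nearest hour).
#' @export
#' @examples
#' compute_workload_saving(2000, 0.01, 0.35, 0.05)  # 59% saved, 1180 abstracts
compute_workload_saving <- function(n_total, random_fraction, time_based_cutoff,
                                    data_driven_cutoff = 0,
                                    seconds_per_abstract = 30) {
  fractions <- c(random_fraction, time_based_cutoff, data_driven_cutoff)
  stopifnot(all(fractions >= 0), n_total >= 1)
  if (sum(fractions) > 1 + 1e-12) {
    stop("screened fractions sum to more than 100% of the collection")
  }
  saving <- 1 - sum(fractions)
  abstracts <- round(saving * n_total)
  hours <- abstracts * seconds_per_abstract / 3600
  structure(list(saving_fraction = saving, abstracts_saved = abstracts,
                 hours_saved = hours, hours_saved_display = round(hours),
                 n_total = n_total,
                 components = c(random = random_fraction,
                                time_based = time_based_cutoff,
                                data_driven = data_driven_cutoff),
                 seconds_per_abstract = seconds_per_abstract),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("Projected workload saving: %.0f%% of %d abstracts\n",
              100 * x$saving_fraction, x$n_total))
  cat(sprintf("  = %d abstracts never screened (~%d h at %g s/abstract)\n",
              x$abstracts_saved, x$hours_saved_display, x$seconds_per_abstract))
  cat(sprintf("  screened: %.0f%% random + %.0f%% time-based + %.0f%% data-driven\n",
              100 * x$components["random"], 100 * x$components["time_based"],
              100 * x$components["data_driven"]))
  invisible(x)
}

#' End-to-end screening recommendation from a random prescreen
#'
#' Convenience wrapper: estimates prevalence from the random screening
#' phase, looks up the band cutoffs, and projects the workload saving for
#' the whole collection. The random-phase fraction used in the projection
#' is `n_random_screened / n_total`.
#'
#' @param n_total total number of retrieved records.
#' @param n_random_screened records screened at random.
#' @param n_relevant_found relevant records found among them.
#' @param table a [recommendation_table()].
#' @param seconds_per_abstract screening time per abstract (default 30 s).
#' @return A `recommendation` with the estimated prevalence, expected
#'   relevant count and selected cutoffs attached.
#' @export
#' @examples
#' recommend_screening(2000, 200, 6)
recommend_screening <- function(n_total, n_random_screened, n_relevant_found,
                                table = recommendation_table(),
                                seconds_per_abstract = 30) {
  prev <- estimate_prevalence(n_relevant_found, n_random_screened)
  cuts <- lookup_cutoffs(prev, table)
  rec <- compute_workload_saving(
    n_total,
    random_fraction = n_random_screened / n_total,
    time_based_cutoff = cuts$time_based,
    data_driven_cutoff = if (is.na(cuts$data_driven)) 0 else cuts$data_driven,
    seconds_per_abstract = seconds_per_abstract)
  rec$estimated_prevalence <- prev
  rec$expected_relevant <- expected_relevant(prev, n_total)
  rec$cutoffs <- cuts
  rec
}
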