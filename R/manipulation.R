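#' Resample a collection to an exact target prevalence
#'
#' Reproduces the ratio-sampling manipulation used to build artificial
#' abstract collections: records are sampled without replacement from the
#' original collection until the target prevalence is met exactly. When the
#' original prevalence is below the target, irrelevant records are dropped;
#' when it is above, relevant records are dropped. Writing the target as a
#' reduced fraction a/b, the result keeps `k*a` relevant and `k*(b-a)`
#' irrelevant records with `k = min(floor(R/a), floor(I/(b-a)))` — the
#' largest subset with prevalence exactly a/b. Which records are kept is
#' uniform at random, seeded; the kept records preserve their original
#' relative order.
#'
#' @param x an `abstract_collection` with at least one record of each class.
#' @param p target prevalence in (0, 1).
#' @param seed integer seed.
#' @return An `abstract_collection` whose prevalence equals `p` exactly
#'   (as a rational number).
#' @export
#' @examples
#' src <- generate_corpus(corpus_spec(n_total = 1000, prevalence = 0.04, seed = 1))
#' out <- manipulate_prevalence_ratio(src, 0.05, seed = 2)
#' c(n_records(out), n_relevant(out))  # 800, 40
manipulate_prevalence_ratio <- function(x, p, seed) {
  validate_collection(x)
  R <- n_relevant(x); I <- n_records(x) - R
  if (R < 1 || I < 1) stop("collection needs at least one relevant and one irrelevant record")
  ab <- rational_approx(p)
  a <- ab[["num"]]; b <- ab[["den"]]
  k <- min(R %/% a, I %/% (b - a))
  if (k < 1) {
    stop(sprintf("no exact subset with prevalence %d/%d exists (R = %d, I = %d)",
                 a, b, R, I))
  }
  rel_ids <- x$record_id[x$label == "relevant"]
  irr_ids <- x$record_id[x$label == "irrelevant"]
  keep <- with_seed(seed, {
    c(sample(rel_ids, k * a), sample(irr_ids, k * (b - a)))
  })
  subset_collection(x, x$record_id[x$record_id %in% keep])
}

#' Sample a collection with a fixed number of relevant records
#'
#' Builds an artificial collection holding the number of relevant records
#' constant while prevalence is adjusted through the irrelevant count:
#' exactly `n_rel` relevant and `n_rel * (1 - p) / p` irrelevant records are
#' drawn uniformly without replacement, for a total of `n_rel / p`. With 20
#' relevant records this yields totals of 2,000 / 800 / 400 at prevalences
#' of 1% / 2.5% / 5%, and with 40 relevant records 4,000 / 1,600 / 800.
#'
#' @param x an `abstract_collection`.
#' @param n_rel number of relevant records to keep.
#' @param p target prevalence in (0, 1); `n_rel * (1 - p) / p` must round to
#'   an integer.
#' @param seed integer seed.
#' @return An `abstract_collection` of size `n_rel / p`.
#' @export
sample_fixed_relevant <- function(x, n_rel, p, seed) {
  validate_collection(x)
  stopifnot(n_rel >= 1, p > 0, p < 1)
  n_irr_exact <- n_rel * (1 - p) / p
  n_irr <- as.integer(round(n_irr_exact))
  if (abs(n_irr_exact - n_irr) > 1e-6) {
    stop(sprintf("n_rel = %d with prevalence %g implies a non-integer irrelevant count (%g)",
                 n_rel, p, n_irr_exact))
  }
  R <- n_relevant(x); I <- n_records(x) - R
  if (R < n_rel) stop(sprintf("collection has only %d relevant records, %d required", R, n_rel))
  if (I < n_irr) stop(sprintf("collection has only %d irrelevant records, %d required", I, n_irr))
  rel_ids <- x$record_id[x$label == "relevant"]
  irr_ids <- x$record_id[x$label == "irrelevant"]
  keep <- with_seed(seed, c(sample(rel_ids, n_rel), sample(irr_ids, n_irr)))
  subset_collection(x, x$record_id[x$record_id %in% keep])
}

#' Specification of an initial training set
#'
#' @param n_rel_train number of relevant training records (>= 1).
#' @param n_irrel_train number of irrelevant training records (>= 1).
#' @param disjoint_from_screening if `TRUE` the training set is drawn from a
#'   pool held out from the screening set, so screening-set counts are the
#'   same under every training condition; if `FALSE` the training records
#'   are members of the screening collection and count as pre-screened.
#' @param seed integer seed.
#' @return An object of class `training_spec`.
#' @export
training_spec <- function(n_rel_train = 1, n_irrel_train = 1,
                          disjoint_from_screening = TRUE, seed = 1) {
  stopifnot(n_rel_train >= 1, n_irrel_train >= 1)
  structure(list(n_rel_train = as.integer(n_rel_train),
                 n_irrel_train = as.integer(n_irrel_train),
                 disjoint_from_screening = isTRUE(disjoint_from_screening),
                 seed = as.integer(seed)),
            class = "training_spec")
}

#' Sample an initial training set (and the matching screening set)
#'
#' In disjoint mode the training records are drawn from `pool` excluding the
#' screening set: if `screening` is supplied the pool minus the screening
#' records is the reservoir and `screening` is returned unchanged; otherwise
#' the screening set is `pool` minus the sampled training records. In
#' non-disjoint mode the training records are members of `pool` itself and
#' the full pool is returned as the screening set (the simulator places the
#' training records at the head of the trace as pre-screened positions).
#'
#' @param pool an `abstract_collection` to draw from.
#' @param spec a [training_spec()].
#' @param screening optional `abstract_collection` already designated for
#'   screening (disjoint mode only).
#' @return A list with elements `training` and `screening`, both
#'   `abstract_collection` objects.
#' @export
sample_training_set <- function(pool, spec, screening = NULL) {
  validate_collection(pool)
  stopifnot(inherits(spec, "training_spec"))
  reservoir <- pool
  if (spec$disjoint_from_screening && !is.null(screening)) {
    reservoir <- new_collection(pool[!pool$record_id %in% screening$record_id, , drop = FALSE])
  }
  rel_ids <- reservoir$record_id[reservoir$label == "relevant"]
  irr_ids <- reservoir$record_id[reservoir$label == "irrelevant"]
  if (length(rel_ids) < spec$n_rel_train)
    stop(sprintf("pool has %d relevant records beyond the screening set, %d required",
                 length(rel_ids), spec$n_rel_train))
  if (length(irr_ids) < spec$n_irrel_train)
    stop(sprintf("pool has %d irrelevant records beyond the screening set, %d required",
                 length(irr_ids), spec$n_irrel_train))
  train_ids <- with_seed(spec$seed, {
    c(sample(rel_ids, spec$n_rel_train), sample(irr_ids, spec$n_irrel_train))
  })
  training <- subset_collection(pool, train_ids)
  screening_out <- if (!spec$disjoint_from_screening) {
    pool
  } else if (!is.null(screening)) {
    screening
  } else {
    new_collection(pool[!pool$record_id %in% train_ids, , drop = FALSE])
  }
  rownames(screening_out) <- NULL
  list(training = training, screening = screening_out)
}
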