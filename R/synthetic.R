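#' Specification of a synthetic labeled corpus
#'
#' The generator emulates the kind of two-class abstract collections used in
#' screening simulations: a shared background vocabulary plus a disjoint
#' block of signal tokens that only relevant records are drawn towards.
#' Documents are bags of tokens; lengths are Poisson around
#' `doc_length_mean`; relevant documents draw each token from the signal
#' vocabulary with probability `signal_strength` and from the background
#' otherwise, so `signal_strength = 0` makes the class-conditional
#' distributions identical (an unlearnable task) and `signal_strength = 1`
#' a near-separable one. A `noise_rate` fraction of relevant documents is
#' generated from the pure background distribution, emulating relevant
#' records that resemble nothing in the training set and therefore surface
#' late in a ranking.
#'
#' @param n_total total number of records N.
#' @param prevalence fraction of relevant records in (0, 1); the emitted
#'   collection has exactly `round(n_total * prevalence)` relevant records.
#' @param vocab_size number of distinct background tokens.
#' @param signal_strength number in `[0, 1]`; concentration of relevant-class
#'   tokens on the signal vocabulary.
#' @param doc_length_mean mean number of tokens per document.
#' @param noise_rate fraction in `[0, 1)` of relevant records generated from
#'   the background profile.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_total = 1000, prevalence = 0.05, vocab_size = 1000,
                        signal_strength = 0.7, doc_length_mean = 120,
                        noise_rate = 0.1, seed = 1) {
  spec <- list(n_total = as.integer(n_total), prevalence = prevalence,
               vocab_size = as.integer(vocab_size),
               signal_strength = signal_strength,
               doc_length_mean = doc_length_mean, noise_rate = noise_rate,
               seed = as.integer(seed))
  class(spec) <- "corpus_spec"
  validate_corpus_spec(spec)
}

validate_corpus_spec <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (spec$n_total < 2) stop("n_total must be at least 2")
  if (spec$prevalence <= 0 || spec$prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (round(spec$n_total * spec$prevalence) < 1)
    stop("round(n_total * prevalence) must be at least 1")
  if (spec$signal_strength < 0 || spec$signal_strength > 1)
    stop("signal_strength must be in [0, 1]")
  if (spec$noise_rate < 0 || spec$noise_rate >= 1)
    stop("noise_rate must be in [0, 1)")
  if (spec$vocab_size < 10) stop("vocab_size must be at least 10")
  if (spec$doc_length_mean < 3) stop("doc_length_mean must be at least 3")
  spec
}

# Zipf-like probabilities over k ranks: mass proportional to 1/rank.
zipf_probs <- function(k) {
  p <- 1 / seq_len(k)
  p / sum(p)
}

#' Generate a synthetic labeled abstract collection
#'
#' @param spec a [corpus_spec()].
#' @return An `abstract_collection` with `N = n_total` and
#'   `R = round(n_total * prevalence)` relevant records, byte-identical
#'   across calls with the same spec.
#' @export
#' @examples
#' x <- generate_corpus(corpus_spec(n_total = 200, prevalence = 0.05, seed = 7))
#' n_records(x); n_relevant(x)
generate_corpus <- function(spec) {
  validate_corpus_spec(spec)
  N <- spec$n_total
  R <- as.integer(round(N * spec$prevalence))
  n_sig <- max(10L, as.integer(round(0.05 * spec$vocab_size)))
  bg_vocab <- sprintf("w%05d", seq_len(spec$vocab_size))
  sig_vocab <- sprintf("s%04d", seq_len(n_sig))
  bg_p <- zipf_probs(spec$vocab_size)
  sig_p <- zipf_probs(n_sig)
  with_seed(spec$seed, {
    labels <- rep("irrelevant", N)
    labels[sample.int(N, R)] <- "relevant"
    n_noise <- as.integer(round(spec$noise_rate * R))
    noisy <- rep(FALSE, N)
    if (n_noise > 0) noisy[sample(which(labels == "relevant"), n_noise)] <- TRUE
    lens <- pmax(3L, stats::rpois(N, spec$doc_length_mean))
    texts <- character(N)
    for (i in seq_len(N)) {
      L <- lens[i]
      if (labels[i] == "relevant" && !noisy[i] && spec$signal_strength > 0) {
        n_s <- stats::rbinom(1L, L, spec$signal_strength)
        toks <- c(if (n_s > 0) sample(sig_vocab, n_s, replace = TRUE, prob = sig_p),
                  if (L - n_s > 0) sample(bg_vocab, L - n_s, replace = TRUE, prob = bg_p))
        toks <- sample(toks)
      } else {
        toks <- sample(bg_vocab, L, replace = TRUE, prob = bg_p)
      }
      texts[i] <- paste(toks, collapse = " ")
    }
  })
  n_title <- 8L
  split_at <- vapply(strsplit(texts, " ", fixed = TRUE), function(t) {
    sum(nchar(utils::head(t, n_title))) + min(length(t), n_title) - 1L
  }, integer(1))
  title <- substr(texts, 1L, split_at)
  abstract <- trimws(substr(texts, split_at + 1L, nchar(texts)))
  collection(record_id = sprintf("syn%06d", seq_len(N)), title = title,
             abstract = abstract, label = labels, key_study = FALSE)
}

#' Generate a suite of synthetic collections
#'
#' Emulates multi-collection simulation designs: `n_collections` corpora
#' sharing a base specification, with optional deterministic per-collection
#' jitter on `signal_strength` and `doc_length_mean` so collections differ
#' in task difficulty the way real abstract collections do. Sub-seeds are
#' derived from `seed` by a counter-based splitting scheme, so the suite is
#' reproducible regardless of generation order.
#'
#' @param n_collections number of collections (>= 1).
#' @param base_spec a [corpus_spec()] providing shared parameters.
#' @param heterogeneity nonnegative jitter half-width: `signal_strength` is
#'   perturbed by up to `+/- heterogeneity` (clamped to `[0, 1]`) and
#'   `doc_length_mean` by up to `+/- 100 * heterogeneity` percent.
#' @param seed integer master seed for the suite.
#' @return A named list of `abstract_collection` objects.
#' @export
generate_suite <- function(n_collections, base_spec, heterogeneity = 0, seed = 1) {
  stopifnot(n_collections >= 1, inherits(base_spec, "corpus_spec"), heterogeneity >= 0)
  out <- vector("list", n_collections)
  for (i in seq_len(n_collections)) {
    sub <- derive_seed(seed, "suite", i)
    spec_i <- base_spec
    if (heterogeneity > 0) {
      jit <- with_seed(derive_seed(sub, "jitter"),
                       stats::runif(2, -heterogeneity, heterogeneity))
      spec_i$signal_strength <- min(1, max(0, base_spec$signal_strength + jit[1]))
      spec_i$doc_length_mean <- max(3, base_spec$doc_length_mean * (1 + jit[2]))
    }
    spec_i$seed <- sub
    out[[i]] <- generate_corpus(validate_corpus_spec(spec_i))
  }
  names(out) <- sprintf("collection%02d", seq_len(n_collections))
  out
}
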