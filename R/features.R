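# Plug-in registry for embedding extractors (doc2vec, sbert). A plug-in is a
# function(collection, params) returning a numeric matrix with one row per
# record; the package never downloads model weights itself.
.extractor_registry <- new.env(parent = emptyenv())

#' Register an embedding extractor plug-in
#'
#' Extractors such as doc2vec or SBERT depend on pretrained models the
#' package does not ship. They can be plugged in as a function taking
#' `(collection, params)` and returning a numeric matrix with rows aligned
#' to the collection's records (row names are set to the record ids by the
#' caller). The deterministic `hashed_stub` extractor satisfies the same
#' contract, produces signed (possibly negative) pseudo-embeddings, and is
#' used to exercise the embedding code path in tests.
#'
#' @param id extractor name, e.g. `"sbert"`.
#' @param fun function `(collection, params)` returning a numeric matrix
#'   with `n_records(collection)` rows.
#' @return `id`, invisibly.
#' @export
register_extractor <- function(id, fun) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fun))
  assign(id, fun, envir = .extractor_registry)
  invisible(id)
}

tokenize <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Extract a feature matrix from a collection
#'
#' The built-in `tfidf` extractor lowercases and tokenises title plus
#' abstract, counts unigram term frequencies, applies the smoothed inverse
#' document frequency `log((1 + N) / (1 + df)) + 1`, and L2-normalises each
#' row; the vocabulary is fitted once on the full collection passed in
#' (training plus screening records). A token present in every document
#' therefore carries idf exactly 1. The `hashed_stub` extractor produces
#' deterministic signed pseudo-embeddings by hashing tokens into a fixed
#' number of dimensions; `doc2vec` and `sbert` must be supplied via
#' [register_extractor()].
#'
#' @param x an `abstract_collection` (nonempty).
#' @param extractor_id `"tfidf"`, `"hashed_stub"`, or a registered plug-in id.
#' @param params extractor parameters; `hashed_stub` honours `dim`
#'   (default 64).
#' @return An object of class `feature_matrix`: a list with `matrix` (rows
#'   named by record id), `extractor_id`, and `nonnegative`.
#' @export
extract_features <- function(x, extractor_id = "tfidf", params = list()) {
  validate_collection(x)
  if (n_records(x) == 0) stop("collection is empty")
  mat <- switch(extractor_id,
    tfidf = tfidf_matrix(x),
    hashed_stub = hashed_stub_matrix(x, dim = params$dim %||% 64L),
    {
      fun <- if (exists(extractor_id, envir = .extractor_registry))
        get(extractor_id, envir = .extractor_registry)
      else stop("unknown extractor '", extractor_id,
                "'; embedding extractors must be registered via register_extractor()")
      m <- fun(x, params)
      if (nrow(m) != n_records(x)) stop("plug-in extractor returned misaligned rows")
      m
    })
  rownames(mat) <- x$record_id
  structure(list(matrix = mat, extractor_id = extractor_id,
                 nonnegative = min_entry(mat) >= 0),
            class = "feature_matrix")
}

min_entry <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    if (length(m@x) == 0) 0 else min(0, min(m@x))
  } else min(m)
}

tfidf_matrix <- function(x) {
  texts <- paste(x$title, x$abstract)
  toks <- tokenize(texts)
  empty <- lengths(toks) == 0
  if (any(empty)) {
    warning(sum(empty), " record(s) have no tokens; their feature rows are zero")
  }
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  if (!length(vocab)) stop("collection contains no tokens at all")
  N <- length(toks)
  i <- rep.int(seq_len(N), lengths(toks))
  j <- match(unlist(toks, use.names = FALSE), vocab)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(N, length(vocab)),
                                 dimnames = list(NULL, vocab))
  df <- Matrix::colSums(counts > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  X <- counts %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(X^2))
  norms[norms == 0] <- 1
  X <- Matrix::Diagonal(x = 1 / norms) %*% X
  colnames(X) <- vocab
  methods::as(X, "CsparseMatrix")
}

# FNV-1a style string hash, exact in double arithmetic (mod 2^31 - 1).
hash_string <- function(s) {
  h <- 2166136261 %% 2147483647
  for (code in utf8ToInt(s)) h <- ((h * 16777) %% 2147483647 + code) %% 2147483647
  h
}

hashed_stub_matrix <- function(x, dim = 64L) {
  texts <- paste(x$title, x$abstract)
  toks <- tokenize(texts)
  vocab <- unique(unlist(toks, use.names = FALSE))
  h <- vapply(vocab, hash_string, numeric(1))
  slot <- (h %% dim) + 1
  sgn <- ifelse((h %/% dim) %% 2 == 0, 1, -1)
  m <- matrix(0, nrow = length(toks), ncol = dim)
  for (d in seq_along(toks)) {
    idx <- match(toks[[d]], vocab)
    m[d, ] <- unname(tapply(sgn[idx], slot[idx], sum)[as.character(seq_len(dim))])
  }
  m[is.na(m)] <- 0
  norms <- sqrt(rowSums(m^2)); norms[norms == 0] <- 1
  m / norms
}

#' Check classifier / feature-extractor compatibility
#'
#' Naive Bayes models token masses and cannot process negative feature
#' values, so it is incompatible with signed embedding extractors (doc2vec,
#' SBERT, hashed_stub); every other pairing is allowed.
#'
#' @param classifier_id one of `"lr"`, `"nb"`, `"svm"`, `"rf"`, `"nn2layer"`.
#' @param features a `feature_matrix`.
#' @return `TRUE` or `FALSE`.
#' @export
check_compatibility <- function(classifier_id, features) {
  stopifnot(inherits(features, "feature_matrix"))
  !(classifier_id == "nb" && !features$nonnegative)
}
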