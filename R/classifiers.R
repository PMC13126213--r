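#' Rebalance a labeled training set
#'
#' Screening data are heavily imbalanced: as labeling proceeds, irrelevant
#' records dominate the training set and risk swamping the relevant class.
#' The `dynamic_resampling` strategy counteracts this by undersampling the
#' irrelevant class and oversampling the relevant class while keeping the
#' training-set size constant: the relevant class is brought up to
#' `target_share` of the multiset (every relevant record retained, whole-set
#' replication plus a seeded remainder draw), and the irrelevant class is
#' subsampled without replacement to fill the rest. If the relevant share
#' already meets the target, the input is returned unchanged, as it is under
#' `strategy = "none"`.
#'
#' @param labeled data frame with columns `record_id` and `label`,
#'   containing at least one record of each class.
#' @param strategy `"dynamic_resampling"` or `"none"`.
#' @param seed integer seed.
#' @param target_share target share of the relevant class (default 0.5).
#' @return A data frame (`record_id`, `label`) of the same number of rows as
#'   `labeled`, possibly with repeated rows.
#' @export
balance_training <- function(labeled, strategy = c("dynamic_resampling", "none"),
                             seed = 1, target_share = 0.5) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(labeled), all(c("record_id", "label") %in% names(labeled)))
  n_rel <- sum(labeled$label == "relevant")
  n_irr <- sum(labeled$label == "irrelevant")
  if (n_rel < 1 || n_irr < 1) {
    stop("training set must contain at least one relevant and one irrelevant record")
  }
  if (strategy == "none") return(labeled)
  n <- nrow(labeled)
  n_rel_target <- max(1L, as.integer(round(target_share * n)))
  if (n_rel >= n_rel_target) return(labeled)
  n_irr_target <- n - n_rel_target
  rel <- labeled[labeled$label == "relevant", , drop = FALSE]
  irr <- labeled[labeled$label == "irrelevant", , drop = FALSE]
  with_seed(seed, {
    full_copies <- n_rel_target %/% n_rel
    remainder <- n_rel_target %% n_rel
    rel_rows <- c(rep(seq_len(n_rel), full_copies),
                  if (remainder > 0) sample.int(n_rel, remainder))
    irr_rows <- sample.int(n_irr, n_irr_target)
    out <- rbind(rel[rel_rows, , drop = FALSE], irr[irr_rows, , drop = FALSE])
  })
  rownames(out) <- NULL
  out
}

feature_rows <- function(features, ids) {
  idx <- match(ids, rownames(features$matrix))
  if (anyNA(idx)) stop("record id(s) absent from feature matrix: ",
                       paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  features$matrix[idx, , drop = FALSE]
}

#' Fit a relevance model on a labeled training multiset
#'
#' Fits one of the supported classifiers on the feature rows of the training
#' records and returns a model under a common score contract: higher score
#' means more likely relevant. Logistic regression is ridge-penalised
#' (`glmnet`, `lambda = 1/n`); naive Bayes is a multinomial model over
#' nonnegative feature mass with Laplace smoothing; the SVM (`e1071`,
#' linear kernel) scores by raw decision margin — ranking only, not a
#' probability; the random forest (`ranger`) scores by class-probability
#' votes; the two-hidden-layer network is a ReLU multilayer perceptron with
#' a sigmoid output, hidden widths clamped to the training-set size for tiny
#' samples. All fits are deterministic given `seed`.
#'
#' @param features a `feature_matrix` covering all training records.
#' @param training data frame (`record_id`, `label`) — typically the output
#'   of [balance_training()]; must contain both classes.
#' @param classifier_id `"lr"`, `"nb"`, `"svm"`, `"rf"` or `"nn2layer"`.
#' @param seed integer seed.
#' @param params optional classifier parameters (`rf`: `num_trees`,
#'   default 200; `nn2layer`: `hidden`, default 128, `epochs`, default 200).
#' @return An object of class `relevance_model`.
#' @export
fit_model <- function(features, training, classifier_id, seed = 1, params = list()) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!check_compatibility(classifier_id, features)) {
    stop("classifier '", classifier_id, "' cannot process negative feature values from '",
         features$extractor_id, "'")
  }
  n_rel <- sum(training$label == "relevant")
  n_irr <- sum(training$label == "irrelevant")
  if (n_rel < 1 || n_irr < 1) stop("training multiset must contain both classes")
  # collapse multiset repetitions into observation counts; classifiers that
  # accept weights train on the unique rows, the rest on expanded rows
  key <- paste(training$record_id, training$label)
  counts <- table(key)[unique(key)]
  first <- !duplicated(key)
  uid <- training$record_id[first]
  x <- feature_rows(features, uid)
  y <- factor(training$label[first], levels = c("irrelevant", "relevant"))
  w <- as.numeric(counts)
  for (cls in levels(y)) {
    rows <- x[y == cls, , drop = FALSE]
    if (all(Matrix::rowSums(abs(rows)) == 0)) {
      stop("degenerate features: every '", cls, "' training record has an all-zero row")
    }
  }
  expand <- function() rep(seq_along(w), w)
  fit <- switch(classifier_id,
    lr = fit_lr(x, y, w, seed),
    nb = fit_nb(x, y, w),
    svm = {
      i <- expand()
      fit_svm(x[i, , drop = FALSE], y[i], seed)
    },
    rf = {
      i <- expand()
      fit_rf(x[i, , drop = FALSE], y[i], seed, params)
    },
    nn2layer = {
      i <- expand()
      fit_nn2(x[i, , drop = FALSE], y[i], seed, params)
    },
    stop("unknown classifier '", classifier_id, "'"))
  structure(list(classifier_id = classifier_id, fit = fit, seed = seed),
            class = "relevance_model")
}

fit_lr <- function(x, y, w, seed) {
  # glmnet needs >= 2 rows per class; duplicating all rows (and halving the
  # weights) leaves the weighted penalised solution unchanged
  if (min(table(y)) < 2) {
    x <- rbind(x, x)
    y <- c(y, y)
    w <- c(w, w) / 2
  }
  n_eff <- sum(w)
  withCallingHandlers(
    with_seed(seed,
      glmnet::glmnet(x, y, family = "binomial", weights = w, alpha = 0,
                     lambda = 1 / n_eff, standardize = FALSE, thresh = 1e-4)),
    warning = function(wrn) {
      # tiny seeded training sets are the normal starting state here
      if (grepl("fewer than 8", conditionMessage(wrn)))
        invokeRestart("muffleWarning")
    })
}

fit_nb <- function(x, y, w, alpha = 1) {
  # multinomial naive Bayes over fractional token mass
  classes <- levels(y)
  V <- ncol(x)
  flp <- matrix(0, nrow = 2, ncol = V, dimnames = list(classes, NULL))
  prior <- numeric(2); names(prior) <- classes
  for (cls in classes) {
    mass <- as.numeric(Matrix::crossprod(x, w * (y == cls)))
    flp[cls, ] <- log(mass + alpha) - log(sum(mass) + alpha * V)
    prior[cls] <- log(sum(w[y == cls]) / sum(w))
  }
  list(feature_log_prob = flp, log_prior = prior)
}

fit_svm <- function(x, y, seed) {
  with_seed(seed,
    e1071::svm(x = as.matrix(x), y = y, kernel = "linear", scale = FALSE, cost = 1))
}

fit_rf <- function(x, y, seed, params) {
  xd <- as.matrix(x)
  colnames(xd) <- sprintf("f%05d", seq_len(ncol(xd)))
  ranger::ranger(x = xd, y = y, probability = TRUE,
                 num.trees = params$num_trees %||% 200L,
                 seed = seed, num.threads = 1L)
}

# Two-hidden-layer ReLU perceptron, full-batch Adam on the cross-entropy.
fit_nn2 <- function(x, y, seed, params) {
  xd <- as.matrix(x)
  n <- nrow(xd); p <- ncol(xd)
  h <- min(params$hidden %||% 128L, max(2L, n))
  epochs <- params$epochs %||% 200L
  target <- as.numeric(y == "relevant")
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(p * h, sd = sqrt(2 / p)), p, h); b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(h * h, sd = sqrt(2 / h)), h, h); b2 <- numeric(h)
    W3 <- matrix(stats::rnorm(h, sd = sqrt(2 / h)), h, 1);     b3 <- 0
  })
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
  mom <- lapply(pars, function(p) p * 0)
  vel <- lapply(pars, function(p) p * 0)
  lr <- 0.01; beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    a1 <- pmax(sweep(xd %*% pars$W1, 2, pars$b1, "+"), 0)
    a2 <- pmax(sweep(a1 %*% pars$W2, 2, pars$b2, "+"), 0)
    z3 <- drop(a2 %*% pars$W3) + pars$b3
    prob <- 1 / (1 + exp(-z3))
    d3 <- matrix((prob - target) / n, ncol = 1)
    g <- list(W3 = t(a2) %*% d3, b3 = sum(d3))
    d2 <- (d3 %*% t(pars$W3)) * (a2 > 0)
    g$W2 <- t(a1) %*% d2; g$b2 <- colSums(d2)
    d1 <- (d2 %*% t(pars$W2)) * (a1 > 0)
    g$W1 <- t(xd) %*% d1; g$b1 <- colSums(d1)
    for (nm in names(pars)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^t)
      vhat <- vel[[nm]] / (1 - beta2^t)
      pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  pars
}

#' Score records with a fitted relevance model
#'
#' @param model a `relevance_model`.
#' @param features a `feature_matrix` covering `ids`.
#' @param ids record ids to score.
#' @return A named numeric vector of finite relevance scores
#'   (higher = more likely relevant).
#' @export
score_records <- function(model, features, ids) {
  x <- feature_rows(features, ids)
  s <- switch(model$classifier_id,
    lr = as.numeric(stats::predict(model$fit, newx = x, type = "response")),
    nb = {
      jll <- as.matrix(x %*% t(model$fit$feature_log_prob))
      jll <- sweep(jll, 2, model$fit$log_prior, "+")
      # posterior probability of the relevant class
      1 / (1 + exp(jll[, "irrelevant"] - jll[, "relevant"]))
    },
    svm = {
      dv <- attr(stats::predict(model$fit, as.matrix(x), decision.values = TRUE),
                 "decision.values")
      pos_first <- startsWith(colnames(dv)[1], "relevant")
      if (pos_first) drop(dv) else -drop(dv)
    },
    rf = {
      xd <- as.matrix(x)
      colnames(xd) <- sprintf("f%05d", seq_len(ncol(xd)))
      stats::predict(model$fit, data = xd, num.threads = 1L)$predictions[, "relevant"]
    },
    nn2layer = {
      xd <- as.matrix(x)
      a1 <- pmax(sweep(xd %*% model$fit$W1, 2, model$fit$b1, "+"), 0)
      a2 <- pmax(sweep(a1 %*% model$fit$W2, 2, model$fit$b2, "+"), 0)
      1 / (1 + exp(-(drop(a2 %*% model$fit$W3) + model$fit$b3)))
    },
    stop("unknown classifier '", model$classifier_id, "'"))
  s <- as.numeric(s)
  if (any(!is.finite(s))) stop("non-finite relevance scores produced")
  names(s) <- ids
  s
}

#' Rank candidate records by predicted relevance
#'
#' Implements the certainty-based query strategy: candidates are ordered by
#' score descending; ties are broken by the original order of `ids`
#' (stable sort), so the ranking is a permutation of the input ids.
#'
#' @param model a `relevance_model`.
#' @param features a `feature_matrix` covering `ids`.
#' @param ids candidate record ids in original collection order.
#' @return `ids` reordered by decreasing relevance score.
#' @export
rank_candidates <- function(model, features, ids) {
  if (!length(ids)) stop("no candidates to rank")
  s <- score_records(model, features, ids)
  ids[order(-s, method = "radix")]
}
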