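#' Define a factorial screening-simulation design
#'
#' A design crosses abstract collections with manipulation conditions,
#' replications and algorithms. Study-1-style designs resample each source
#' collection to a grid of target prevalences (ratio sampling, training set
#' of one relevant plus one irrelevant record drawn from the collection
#' itself); Study-2-style designs hold the number of relevant records fixed
#' on a grid, adjust prevalence through the irrelevant count, and draw
#' disjoint training sets with a grid of relevant-record counts.
#'
#' @param study_id `"study1"` or `"study2"`.
#' @param collections character vector of collection ids (or a named list of
#'   `abstract_collection` objects, whose names are used).
#' @param prevalence_grid target prevalences.
#' @param n_rel_grid fixed relevant-record counts (study2 only).
#' @param training_grid list of [training_spec()]s, or for study2 a numeric
#'   vector of relevant-training counts (irrelevant count fixed at 10).
#' @param algorithms list of [al_config()]s or character algorithm labels.
#' @param n_replications replications per cell.
#' @param master_seed integer; all per-run seeds derive from it.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(study_id = c("study1", "study2"), collections,
                              prevalence_grid, n_rel_grid = NULL,
                              training_grid = NULL, algorithms = list("lr+tfidf"),
                              n_replications = 1000, master_seed = 1) {
  study_id <- match.arg(study_id)
  coll_ids <- if (is.list(collections)) names(collections) else as.character(collections)
  stopifnot(length(coll_ids) >= 1, length(prevalence_grid) >= 1, n_replications >= 1)
  if (study_id == "study2") {
    stopifnot(length(n_rel_grid) >= 1)
    if (is.null(training_grid)) training_grid <- c(1, 2, 5)
  } else {
    if (is.null(training_grid)) training_grid <- 1
  }
  structure(list(study_id = study_id, collection_ids = coll_ids,
                 collections = if (is.list(collections)) collections else NULL,
                 prevalence_grid = prevalence_grid, n_rel_grid = n_rel_grid,
                 training_grid = training_grid, algorithms = algorithms,
                 n_replications = as.integer(n_replications),
                 master_seed = as.integer(master_seed)),
            class = "experiment_design")
}

algorithm_labels <- function(design) {
  vapply(design$algorithms, function(a) {
    if (inherits(a, "al_config")) paste0(a$classifier_id, "+", a$extractor_id)
    else as.character(a)
  }, character(1))
}

#' Enumerate the run manifest of a design
#'
#' Expands the full cross-product of the design's factors into one row per
#' simulation run with deterministic per-run sub-seeds. The
#' artificial-collection seed is shared across algorithms (study 1) and
#' training conditions (study 2), so the same sampled records underlie every
#' algorithm/training comparison within a replication, as in the original
#' designs. The number of artificial collections (cells before crossing
#' with algorithms or training conditions) is attached as the attribute
#' `n_artificial_collections`.
#'
#' @param design an [experiment_design()].
#' @return A data frame manifest; rows are simulation runs.
#' @export
enumerate_runs <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  algs <- algorithm_labels(design)
  if (design$study_id == "study1") {
    cells <- expand.grid(collection = design$collection_ids,
                         prevalence = design$prevalence_grid,
                         replication = seq_len(design$n_replications),
                         algorithm = algs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n_art <- length(design$collection_ids) * length(design$prevalence_grid) *
      design$n_replications
    cells$collection_seed <- derive_seed_vec(design$master_seed, list(
      match(cells$collection, design$collection_ids),
      match(cells$prevalence, design$prevalence_grid),
      cells$replication))
    cells$run_seed <- derive_seed_vec(design$master_seed, list(
      cells$collection_seed, match(cells$algorithm, algs)))
  } else {
    cells <- expand.grid(collection = design$collection_ids,
                         prevalence = design$prevalence_grid,
                         n_rel = design$n_rel_grid,
                         replication = seq_len(design$n_replications),
                         n_rel_train = design$training_grid,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells$algorithm <- algs[1]
    n_art <- length(design$collection_ids) * length(design$prevalence_grid) *
      length(design$n_rel_grid) * design$n_replications
    cells$collection_seed <- derive_seed_vec(design$master_seed, list(
      match(cells$collection, design$collection_ids),
      match(cells$prevalence, design$prevalence_grid),
      match(cells$n_rel, design$n_rel_grid),
      cells$replication))
    cells$run_seed <- derive_seed_vec(design$master_seed, list(
      cells$collection_seed, match(cells$n_rel_train, design$training_grid)))
  }
  cells$run_id <- seq_len(nrow(cells))
  attr(cells, "n_artificial_collections") <- n_art
  attr(cells, "study_id") <- design$study_id
  cells
}

#' Execute (a thinned version of) a run manifest
#'
#' Runs manipulation, training-set selection, active-learning simulation and
#' metric computation for every manifest row with replication index at or
#' below `ceiling(scale_factor * max replication)` — every cell of the
#' design stays represented while the replication count is thinned for desk
#' -scale execution. TF-IDF features are extracted once per source
#' collection and reused across the runs drawn from it. Individual run
#' failures are recorded and do not abort the execution; re-execution with
#' the same manifest and collections reproduces the same table.
#'
#' @param manifest a manifest from [enumerate_runs()].
#' @param collections named list of source `abstract_collection` objects
#'   covering every manifest collection id.
#' @param scale_factor replication-thinning fraction in (0, 1].
#' @param algorithms named list mapping algorithm labels to [al_config()]s;
#'   labels of the form `"<classifier>+<extractor>"` are constructed
#'   automatically when absent.
#' @param retrain_interval refit period used for the simulations (defaults:
#'   10 for study1 manifests, 1 for study2).
#' @param s,p metric levels (sensitivity level and screened fraction).
#' @param n_irrel_train irrelevant training records per run (study2),
#'   default 10.
#' @return A long data frame: one row per run and metric, columns `run_id`,
#'   `collection`, condition columns, `metric_id`, `level`, `value`; failed
#'   runs are collected in the `failures` attribute.
#' @export
execute <- function(manifest, collections, scale_factor = 1, algorithms = NULL,
                    retrain_interval = NULL, s = 0.95, p = 0.10,
                    n_irrel_train = 10) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1,
            scale_factor > 0, scale_factor <= 1)
  study <- attr(manifest, "study_id") %||% "study1"
  if (is.null(retrain_interval)) retrain_interval <- if (study == "study1") 10L else 1L
  keep <- manifest$replication <= ceiling(scale_factor * max(manifest$replication))
  manifest <- manifest[keep, , drop = FALSE]
  feats <- lapply(collections, function(col) extract_features(col, "tfidf"))
  results <- vector("list", nrow(manifest))
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      src <- collections[[row$collection]]
      if (is.null(src)) stop("collection '", row$collection, "' not supplied")
      cfg <- resolve_algorithm(row$algorithm, algorithms, retrain_interval,
                               seed = row$run_seed)
      if (study == "study1") {
        art <- manipulate_prevalence_ratio(src, row$prevalence, seed = row$collection_seed)
        ts <- training_spec(1, 1, disjoint_from_screening = FALSE,
                            seed = derive_seed(row$run_seed, "train"))
        parts <- sample_training_set(art, ts)
      } else {
        screen <- sample_fixed_relevant(src, row$n_rel, row$prevalence,
                                        seed = row$collection_seed)
        ts <- training_spec(row$n_rel_train, n_irrel_train,
                            disjoint_from_screening = TRUE,
                            seed = derive_seed(row$run_seed, "train"))
        parts <- sample_training_set(src, ts, screening = screen)
      }
      trace <- run_simulation(parts$screening, parts$training, cfg,
                              features = if (cfg$extractor_id == "tfidf")
                                feats[[row$collection]] else NULL)
      m <- trace_metrics(trace, s = s, p = p)
      cond <- row[setdiff(names(row), c("collection_seed", "run_seed"))]
      cbind(cond[rep(1, nrow(m)), , drop = FALSE], m, row.names = NULL)
    }, error = function(e) {
      failures <<- c(failures, sprintf("run %d: %s", row$run_id, conditionMessage(e)))
      NULL
    })
    results[[i]] <- res
  }
  out <- do.call(rbind, results)
  attr(out, "failures") <- failures
  out
}

resolve_algorithm <- function(label, algorithms, retrain_interval, seed) {
  cfg <- if (!is.null(algorithms) && label %in% names(algorithms)) {
    algorithms[[label]]
  } else {
    parts <- strsplit(label, "+", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("cannot parse algorithm label '", label, "'")
    al_config(classifier_id = parts[1], extractor_id = parts[2])
  }
  cfg$retrain_interval <- as.integer(retrain_interval)
  cfg$seed <- as.integer(seed)
  cfg
}

#' Replication-level performance summary
#'
#' Mean, standard deviation, median, quartiles and the 90th percentile of a
#' set of metric values; quantiles use linear interpolation between order
#' statistics (the default convention of [stats::quantile()], type 7).
#'
#' @param values nonempty numeric vector.
#' @return An object of class `perf_summary`: a list with `mean`, `sd`,
#'   `median`, `q25`, `q75`, `q90`, `n_runs`.
#' @export
summarize_performance <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || all(is.na(values))) stop("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75, 0.9), type = 7, na.rm = TRUE)
  structure(list(mean = mean(values, na.rm = TRUE),
                 sd = stats::sd(values),
                 median = unname(q[2]), q25 = unname(q[1]),
                 q75 = unname(q[3]), q90 = unname(q[4]),
                 n_runs = sum(!is.na(values))),
            class = "perf_summary")
}

#' @export
print.perf_summary <- function(x, ...) {
  cat(sprintf("median %.4f [IQR %.4f, %.4f], q90 %.4f, mean %.4f (sd %.4f), n = %d\n",
              x$median, x$q25, x$q75, x$q90, x$mean, x$sd, x$n_runs))
  invisible(x)
}

#' Read an experiment design from a YAML file
#'
#' Expects top-level keys matching the arguments of [experiment_design()]
#' (`study_id`, `collections`, `prevalence_grid`, `n_rel_grid`,
#' `training_grid`, `algorithms`, `n_replications`, `master_seed`).
#'
#' @param path YAML file path.
#' @return An [experiment_design()].
#' @export
design_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  experiment_design(study_id = cfg$study_id,
                    collections = cfg$collections,
                    prevalence_grid = cfg$prevalence_grid,
                    n_rel_grid = cfg$n_rel_grid,
                    training_grid = cfg$training_grid,
                    algorithms = as.list(cfg$algorithms %||% list("lr+tfidf")),
                    n_replications = cfg$n_replications %||% 1000,
                    master_seed = cfg$master_seed %||% 1)
}
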