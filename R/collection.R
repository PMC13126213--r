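#' Labeled abstract collections
#'
#' An `abstract_collection` is the package's container for a set of labeled
#' abstracts: one row per record with a unique id, title, abstract, an oracle
#' relevance label (`"relevant"` or `"irrelevant"`) and a key-study flag.
#' Simulations require the oracle label on every record, mirroring the
#' simulation mode of screening tools in which stored inclusion decisions
#' stand in for a reviewer.
#'
#' @param record_id character vector of unique identifiers (generated if
#'   `NULL`).
#' @param title,abstract character vectors; either may be empty for a record
#'   but not both.
#' @param label relevance labels; anything accepted by [coerce_labels()].
#' @param key_study logical flag marking records known relevant beforehand.
#' @return An object of class `abstract_collection` (a data frame).
#' @export
#' @examples
#' collection(title = c("a b", "c d", "e f"),
#'            abstract = c("x", "y", "z"),
#'            label = c(1, 0, 0))
collection <- function(record_id = NULL, title = character(), abstract = character(),
                       label = character(), key_study = FALSE) {
  n <- max(length(title), length(abstract), length(label))
  if (is.null(record_id)) record_id <- sprintf("rec%05d", seq_len(n))
  df <- data.frame(
    record_id = as.character(record_id),
    title = rep_len(as.character(title), n),
    abstract = rep_len(as.character(abstract), n),
    label = coerce_labels(rep_len(label, n)),
    key_study = rep_len(as.logical(key_study), n),
    stringsAsFactors = FALSE
  )
  validate_collection(new_collection(df))
}

new_collection <- function(df) {
  class(df) <- c("abstract_collection", "data.frame")
  df
}

validate_collection <- function(x) {
  stopifnot(inherits(x, "abstract_collection"))
  needed <- c("record_id", "title", "abstract", "label", "key_study")
  missing <- setdiff(needed, names(x))
  if (length(missing)) stop("collection lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(x$record_id)) stop("record ids are not unique within the collection")
  if (any(is.na(x$label))) stop("every record must carry a relevance label")
  bad <- !x$label %in% c("relevant", "irrelevant")
  if (any(bad)) stop("invalid label value(s): ", paste(unique(x$label[bad]), collapse = ", "))
  empty <- !nzchar(trimws(x$title)) & !nzchar(trimws(x$abstract))
  if (any(empty)) stop("record(s) with both title and abstract empty: ",
                       paste(utils::head(x$record_id[empty], 5), collapse = ", "))
  x
}

#' Coerce heterogeneous label encodings to relevant/irrelevant
#'
#' Accepts 0/1, logical, yes/no, included/excluded and relevant/irrelevant
#' (case-insensitive).
#'
#' @param x vector of raw label values.
#' @return character vector with values `"relevant"` / `"irrelevant"`;
#'   unmappable values become `NA`.
#' @export
coerce_labels <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(v))
  out[v %in% c("1", "true", "yes", "included", "include", "relevant")] <- "relevant"
  out[v %in% c("0", "false", "no", "excluded", "exclude", "irrelevant")] <- "irrelevant"
  out
}

#' Collection counts
#'
#' `n_records()` is the total size N, `n_relevant()` the number of relevant
#' records R, and `prevalence()` the proportion R/N.
#'
#' @param x an `abstract_collection`.
#' @return An integer (or fraction for `prevalence()`).
#' @export
n_records <- function(x) nrow(x)

#' @rdname n_records
#' @export
n_relevant <- function(x) sum(x$label == "relevant")

#' @rdname n_records
#' @export
prevalence <- function(x) n_relevant(x) / n_records(x)

#' @export
print.abstract_collection <- function(x, ...) {
  cat(sprintf("<abstract_collection> N = %d, R = %d (prevalence %.2f%%), key studies = %d\n",
              n_records(x), n_relevant(x), 100 * prevalence(x), sum(x$key_study)))
  invisible(x)
}

subset_collection <- function(x, ids) {
  out <- x[match(ids, x$record_id), , drop = FALSE]
  rownames(out) <- NULL
  new_collection(out)
}

#' Default column / tag mapping for collection files
#'
#' CSV files use the columns `record_id`, `title`, `abstract`,
#' `label_included` (1/0) and `key_study` (1/0). RIS files carry text in the
#' standard TI/AB tags; since RIS has no relevance tag, the label and
#' key-study flag travel in configurable custom tags (defaults `C1`, `C2`).
#'
#' @return A named list of column names and RIS tags.
#' @export
default_mapping <- function() {
  list(id = "record_id", title = "title", abstract = "abstract",
       label = "label_included", key = "key_study",
       ris_label_tag = "C1", ris_key_tag = "C2")
}

#' Read a labeled abstract collection from CSV or RIS
#'
#' @param path file path.
#' @param format `"csv"` or `"ris"`.
#' @param mapping column/tag mapping, see [default_mapping()].
#' @return An `abstract_collection`.
#' @export
read_collection <- function(path, format = c("csv", "ris"), mapping = default_mapping()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "csv") read_collection_csv(path, mapping) else read_collection_ris(path, mapping)
}

read_collection_csv <- function(path, mapping) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        encoding = "UTF-8")
  if (nrow(df) == 0 && ncol(df) == 0) stop("empty file: ", path)
  if (!mapping$label %in% names(df)) {
    stop("missing label column '", mapping$label, "' in ", path)
  }
  for (col in c(mapping$title, mapping$abstract)) {
    if (!col %in% names(df)) stop("missing column '", col, "' in ", path)
  }
  labels <- coerce_labels(df[[mapping$label]])
  if (anyNA(labels)) {
    stop("unparseable label at row(s): ",
         paste(utils::head(which(is.na(labels)), 5), collapse = ", "))
  }
  ids <- if (mapping$id %in% names(df)) df[[mapping$id]] else sprintf("rec%05d", seq_len(nrow(df)))
  keys <- if (mapping$key %in% names(df)) {
    coerce_labels(df[[mapping$key]]) == "relevant"
  } else rep(FALSE, nrow(df))
  keys[is.na(keys)] <- FALSE
  col <- collection(record_id = ids, title = df[[mapping$title]],
                    abstract = df[[mapping$abstract]], label = labels, key_study = keys)
  empty_abs <- !nzchar(trimws(col$abstract))
  if (any(empty_abs)) {
    warning(sum(empty_abs), " record(s) have an empty abstract; kept with title-only text")
  }
  col
}

read_collection_ris <- function(path, mapping) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  recs <- list(); cur <- list(); i <- 0L
  flush_rec <- function(cur, i) {
    if (!length(cur)) return(NULL)
    lab <- cur[[mapping$ris_label_tag]]
    if (is.null(lab)) stop("missing label tag '", mapping$ris_label_tag,
                           "' in RIS record ", i)
    list(id = cur[["ID"]] %||% sprintf("rec%05d", i),
         title = cur[["TI"]] %||% "", abstract = cur[["AB"]] %||% "",
         label = lab, key = cur[[mapping$ris_key_tag]] %||% "0")
  }
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    tag <- sub("^([A-Z][A-Z0-9])  - .*$", "\\1", line)
    if (!grepl("^[A-Z][A-Z0-9]  - ", line)) next
    val <- sub("^[A-Z][A-Z0-9]  - ", "", line)
    if (tag == "ER") {
      i <- i + 1L
      recs[[i]] <- flush_rec(cur, i)
      cur <- list()
    } else cur[[tag]] <- val
  }
  if (!length(recs)) stop("no RIS records found in ", path)
  labels <- coerce_labels(vapply(recs, `[[`, "", "label"))
  if (anyNA(labels)) stop("unparseable label in RIS record(s): ",
                          paste(which(is.na(labels)), collapse = ", "))
  collection(record_id = vapply(recs, `[[`, "", "id"),
             title = vapply(recs, `[[`, "", "title"),
             abstract = vapply(recs, `[[`, "", "abstract"),
             label = labels,
             key_study = coerce_labels(vapply(recs, `[[`, "", "key")) == "relevant")
}

#' Write a labeled abstract collection to CSV or RIS
#'
#' The output is readable by [read_collection()] with the default mapping;
#' labels are encoded 1/0.
#'
#' @param x an `abstract_collection`.
#' @param path file path.
#' @param format `"csv"` or `"ris"`.
#' @param mapping column/tag mapping, see [default_mapping()].
#' @return `path`, invisibly.
#' @export
write_collection <- function(x, path, format = c("csv", "ris"), mapping = default_mapping()) {
  format <- match.arg(format)
  validate_collection(x)
  if (format == "csv") {
    df <- data.frame(x$record_id, x$title, x$abstract,
                     as.integer(x$label == "relevant"), as.integer(x$key_study))
    names(df) <- c(mapping$id, mapping$title, mapping$abstract, mapping$label, mapping$key)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(x))) {
      writeLines(c("TY  - JOUR",
                   paste0("ID  - ", x$record_id[i]),
                   paste0("TI  - ", x$title[i]),
                   paste0("AB  - ", x$abstract[i]),
                   paste0(mapping$ris_label_tag, "  - ", as.integer(x$label[i] == "relevant")),
                   paste0(mapping$ris_key_tag, "  - ", as.integer(x$key_study[i])),
                   "ER  - ", ""), con)
    }
  }
  invisible(path)
}

#' Check a collection against the simulation eligibility rules
#'
#' Study-1-style designs require collections with at least 1,000 abstracts of
#' which at least 50 are relevant. Study-2-style designs require at least
#' 4,000 irrelevant and at least 50 relevant abstracts (collections with
#' fewer than 4,000 irrelevant records are excluded). Boundaries are
#' inclusive.
#'
#' @param x an `abstract_collection`.
#' @param study `"study1"` or `"study2"`.
#' @return A list with `eligible` (logical) and `reasons` (character vector
#'   of failed clauses, empty when eligible).
#' @export
check_eligibility <- function(x, study = c("study1", "study2")) {
  study <- match.arg(study)
  validate_collection(x)
  N <- n_records(x); R <- n_relevant(x)
  reasons <- character()
  if (study == "study1") {
    if (N < 1000) reasons <- c(reasons, sprintf("N below 1000 (N = %d)", N))
    if (R < 50) reasons <- c(reasons, sprintf("fewer than 50 relevant records (R = %d)", R))
  } else {
    if (N - R < 4000) reasons <- c(reasons,
      sprintf("fewer than 4000 irrelevant records (N - R = %d)", N - R))
    if (R < 50) reasons <- c(reasons, sprintf("fewer than 50 relevant records (R = %d)", R))
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}
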