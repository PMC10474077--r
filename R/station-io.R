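#' Construct a station dataset
#'
#' A station dataset is a tibble of complete categorical records (one column
#' per schema variable, canonical column order) carrying its schema, a
#' station id and the number of records rejected at ingestion as
#' attributes. Records with values outside the schema, or with missing
#' values, never survive construction: the Bayesian-network math downstream
#' assumes complete data.
#'
#' @param records A data frame with one character column per schema
#'   variable.
#' @param schema A [tan_schema()].
#' @param station_id Label identifying the station.
#' @param n_rejected Count of records dropped at ingestion.
#' @return A `station_data` tibble.
#' @export
station_data <- function(records, schema, station_id, n_rejected = 0L) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(schema$variable, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  records <- records[, schema$variable]
  records[] <- lapply(records, as.character)
  for (v in schema$variable) {
    bad <- !(records[[v]] %in% schema_states(schema, v))
    if (any(bad)) {
      rlang::abort(paste0(
        "value(s) outside declared schema in column ", v, ": ",
        paste(unique(records[[v]][bad])[1:min(3, sum(bad))], collapse = ", ")
      ))
    }
  }
  tibble::new_tibble(
    records,
    schema = schema,
    station_id = station_id,
    n_rejected = as.integer(n_rejected),
    class = "station_data"
  )
}

#' @rdname station_data
#' @param x A `station_data` object.
#' @export
schema_of <- function(x) attr(x, "schema", exact = TRUE)

#' @rdname station_data
#' @export
station_id <- function(x) attr(x, "station_id", exact = TRUE)

#' @rdname station_data
#' @export
n_rejected <- function(x) attr(x, "n_rejected", exact = TRUE)

#' @export
print.station_data <- function(x, ...) {
  cat(
    "<station_data> ", station_id(x), ": ", nrow(x), " records (",
    n_rejected(x), " rejected at ingestion)\n",
    sep = ""
  )
  NextMethod()
}

# Recast records under a (typically harmonized) wider schema.
recast_station <- function(x, schema) {
  station_data(tibble::as_tibble(x), schema, station_id(x), n_rejected(x))
}

#' Read a station dataset from CSV
#'
#' Reads an RFC 4180 CSV (header row required, UTF-8) into a
#' [station_data()]. With an explicit schema, records containing a value
#' outside the declared states (or any missing value) are rejected with a
#' warning naming the offending rows; a missing required column is a hard
#' error. With `schema = NULL` the schema is inferred from the file
#' ([schema_infer()]) and rows with missing values are rejected.
#'
#' @param path CSV file path.
#' @param schema A [tan_schema()], or `NULL` to infer one from the file.
#' @param station_id Label for the station; defaults to the file stem.
#' @param class_var Class column name, used when inferring the schema.
#' @return A [station_data()]; `n_rejected()` reports dropped records.
#' @export
read_station_csv <- function(path, schema = NULL, station_id = NULL,
                             class_var = "Fraud type") {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (is.null(station_id)) {
    station_id <- tools::file_path_sans_ext(basename(path))
  }
  if (file.size(path) == 0) {
    if (is.null(schema)) {
      rlang::abort("cannot infer a schema from an empty file")
    }
    empty <- as.data.frame(
      stats::setNames(rep(list(character()), nrow(schema)), schema$variable)
    )
    return(station_data(empty, schema, station_id))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- trimws(names(raw))
  if (is.null(schema)) {
    keep <- stats::complete.cases(raw)
    if (any(!keep)) {
      rlang::warn(paste0(
        "rejected ", sum(!keep), " record(s) with missing values (rows ",
        paste(which(!keep), collapse = ", "), ")"
      ))
    }
    return(station_data(raw[keep, ], schema_infer(raw[keep, ], class_var),
      station_id,
      n_rejected = sum(!keep)
    ))
  }
  missing_cols <- setdiff(schema$variable, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  raw <- raw[, schema$variable]
  ok <- rep(TRUE, nrow(raw))
  for (v in schema$variable) {
    ok <- ok & raw[[v]] %in% schema_states(schema, v) # NA fails too
  }
  if (any(!ok)) {
    rlang::warn(paste0(
      "rejected ", sum(!ok), " record(s) outside the declared schema (rows ",
      paste(which(!ok), collapse = ", "), ")"
    ))
  }
  station_data(raw[ok, ], schema, station_id, n_rejected = sum(!ok))
}

#' Write a station dataset to CSV
#'
#' @param data A [station_data()] or plain data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Split a dataset into train and test partitions
#'
#' Seeded, reproducible 80/20-style split. With `stratify = TRUE` (the
#' default) each class contributes `round(fraction * n_class)` records to
#' the training set, subject to a deterministic global correction so the
#' total equals `round(fraction * n)`; a class with a single record always
#' goes to train (with a warning) so no class vanishes from training. With
#' `stratify = FALSE` a plain random split is drawn, matching a simple
#' "random 80/20 split" protocol.
#'
#' @param data A [station_data()].
#' @param fraction Train proportion in (0, 1); default 0.8.
#' @param seed Integer seed; the same seed always yields the same split.
#' @param stratify Stratify by class (default `TRUE`).
#' @return A list with class `split_result`: `train`, `test` (both
#'   [station_data()]), `seed`, `fraction`.
#' @export
split_train_test <- function(data, fraction = 0.8, seed, stratify = TRUE) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(data)
  if (n < 2) rlang::abort("need at least 2 records to split")
  schema <- schema_of(data)
  n_train <- round(fraction * n)
  labels <- data[[class_var(schema)]]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (!stratify) {
    train_idx <- sort(sample.int(n, n_train))
  } else {
    classes <- lex_sort(labels)
    n_c <- vapply(classes, function(c) sum(labels == c), 0L)
    target <- round(fraction * n_c)
    singles <- n_c == 1L
    if (any(singles)) {
      target[singles] <- 1L
      rlang::warn(paste0(
        "class(es) with a single record assigned to train: ",
        paste(classes[singles], collapse = ", ")
      ))
    }
    # deterministic correction so sum(target) == n_train: adjust classes in
    # order of the fractional remainder of fraction * n_class, ties by label
    resid <- fraction * n_c - floor(fraction * n_c)
    adjustable <- !singles
    while (sum(target) < n_train) {
      cand <- which(adjustable & target < n_c)
      if (length(cand) == 0) cand <- which(target < n_c)
      pick <- cand[order(-resid[cand], classes[cand], method = "radix")][1]
      target[pick] <- target[pick] + 1L
    }
    while (sum(target) > n_train) {
      cand <- which(adjustable & target > 0L)
      if (length(cand) == 0) break
      pick <- cand[order(resid[cand], classes[cand], method = "radix")][1]
      target[pick] <- target[pick] - 1L
    }
    train_idx <- sort(unlist(lapply(seq_along(classes), function(i) {
      rows <- which(labels == classes[i])
      rows[sample.int(length(rows), target[i])]
    })))
  }

  make <- function(rows) {
    station_data(data[rows, , drop = FALSE], schema, station_id(data))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(
    list(
      train = make(train_idx), test = make(test_idx),
      train_idx = train_idx, test_idx = test_idx,
      seed = seed, fraction = fraction
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(
    "<split_result> train ", nrow(x$train), " / test ", nrow(x$test),
    " (fraction ", x$fraction, ", seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
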