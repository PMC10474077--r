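#' Class-conditional sufficient statistics
#'
#' Dense contingency counts over the (harmonized) state space: the class
#' marginal, one (class x state) table per feature, and one
#' (class x state x state) tensor per unordered feature pair. These counts
#' are sufficient for both TAN structure learning (conditional mutual
#' information is a function of the pair tensors) and Dirichlet-smoothed
#' parameter estimation, and they are additive: summing the statistics of
#' disjoint record sets gives exactly the statistics of their union. That
#' additivity is what makes federated training exact — counts, not records
#' or fitted parameters, are the only thing a station needs to share.
#'
#' Tensors are zero-filled for states a station never observed, so
#' statistics from stations with heterogeneous local state spaces can be
#' pooled after [harmonize_schemas()].
#'
#' @param data A [station_data()] (or data frame conforming to `schema`).
#' @param schema A [tan_schema()]; defaults to the dataset's own schema.
#' @return A `tan_stats` object with fields `schema`, `n`, `class_counts`
#'   (named integer vector), `single_counts` (feature -> class x state
#'   matrix) and `pair_counts` (feature pair -> class x state x state
#'   array, keyed `"A || B"` with A before B in canonical order).
#' @export
count_statistics <- function(data, schema = schema_of(data)) {
  if (is.null(schema)) rlang::abort("no schema available for the data")
  data <- tibble::as_tibble(data)[, schema$variable]
  cls <- class_var(schema)
  fac <- lapply(schema$variable, function(v) {
    col <- data[[v]]
    f <- factor(col, levels = schema_states(schema, v))
    if (anyNA(f) || anyNA(col)) {
      rlang::abort(paste0(
        "record value outside the schema in column ", v,
        " (ingestion should have filtered it)"
      ))
    }
    f
  })
  names(fac) <- schema$variable
  feats <- feature_vars(schema)

  class_counts <- table(fac[[cls]])
  single <- lapply(feats, function(v) {
    unclass(table(fac[[cls]], fac[[v]]))
  })
  names(single) <- feats
  pairs <- list()
  if (length(feats) >= 2) {
    for (i in seq_len(length(feats) - 1)) {
      for (j in seq(i + 1, length(feats))) {
        key <- pair_key(feats[i], feats[j])
        pairs[[key]] <- unclass(table(fac[[cls]], fac[[feats[i]]],
          fac[[feats[j]]],
          dnn = NULL
        ))
      }
    }
  }
  structure(
    list(
      schema = schema, n = nrow(data),
      class_counts = stats::setNames(as.integer(class_counts),
        names(class_counts)),
      single_counts = single, pair_counts = pairs
    ),
    class = "tan_stats"
  )
}

pair_key <- function(a, b) paste(a, b, sep = " || ")

# pair tensor oriented as [class, xi, xj] whatever the stored key order
pair_tensor <- function(stats, xi, xj) {
  feats <- feature_vars(stats$schema)
  if (match(xi, feats) < match(xj, feats)) {
    stats$pair_counts[[pair_key(xi, xj)]]
  } else {
    aperm(stats$pair_counts[[pair_key(xj, xi)]], c(1, 3, 2))
  }
}

#' @export
print.tan_stats <- function(x, ...) {
  cat(
    "<tan_stats> n = ", x$n, ", ", length(x$class_counts), " classes, ",
    length(x$single_counts), " features\n",
    sep = ""
  )
  invisible(x)
}

#' All-zero statistics for a schema
#'
#' The identity element of statistics aggregation.
#'
#' @param schema A [tan_schema()].
#' @return A `tan_stats` with every count zero and `n = 0`.
#' @export
empty_statistics <- function(schema) {
  empty <- stats::setNames(
    rep(list(character()), nrow(schema)), schema$variable
  )
  count_statistics(as.data.frame(empty), schema)
}

#' Add two sufficient-statistics objects
#'
#' Elementwise tensor addition; both operands must live on the same
#' harmonized schema. Commutative and associative with
#' [empty_statistics()] as identity.
#'
#' @param a,b `tan_stats` objects on identical schemas.
#' @return Their sum as a `tan_stats`.
#' @export
stats_add <- function(a, b) {
  if (!identical(schema_to_json(a$schema), schema_to_json(b$schema))) {
    rlang::abort("cannot add statistics computed on different schemas")
  }
  a$n <- a$n + b$n
  a$class_counts <- a$class_counts + b$class_counts
  for (v in names(a$single_counts)) {
    a$single_counts[[v]] <- a$single_counts[[v]] + b$single_counts[[v]]
  }
  for (k in names(a$pair_counts)) {
    a$pair_counts[[k]] <- a$pair_counts[[k]] + b$pair_counts[[k]]
  }
  a
}

#' Conditional mutual information between two features given the class
#'
#' Plug-in estimate in nats from the pooled counts:
#' \deqn{I(X_i; X_j \mid C) = \sum_{c,a,b} \frac{N_{abc}}{N}
#'   \ln \frac{N_{abc} \, N_c}{N_{ac} \, N_{bc}}}
#' with zero-count cells contributing 0. This is the edge weight of the
#' TAN feature tree: a large value means the two features carry shared
#' information about each other beyond what the class explains.
#' Symmetric in its arguments; tiny negative rounding residues are
#' clamped to 0.
#'
#' @param stats A `tan_stats` with `n > 0`.
#' @param xi,xj Distinct feature names.
#' @return Non-negative scalar (nats).
#' @export
conditional_mutual_information <- function(stats, xi, xj) {
  if (identical(xi, xj)) {
    rlang::abort("conditional mutual information needs two distinct features")
  }
  stopifnot(stats$n > 0)
  tab <- pair_tensor(stats, xi, xj) # [c, a, b]
  d <- dim(tab)
  n_c <- array(stats$class_counts, dim = d)
  n_ac <- array(apply(tab, c(1, 2), sum), dim = d)
  n_bc <- aperm(array(apply(tab, c(1, 3), sum), dim = d[c(1, 3, 2)]), c(1, 3, 2))
  pos <- tab > 0
  val <- sum(
    tab[pos] / stats$n * log(tab[pos] * n_c[pos] / (n_ac[pos] * n_bc[pos]))
  )
  max(val, 0)
}
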