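#' Learn a Tree-Augmented Naive Bayes structure
#'
#' Builds the maximum-weight spanning tree over the features with
#' conditional mutual information (given the class) as edge weight —
#' Chow-Liu restricted to the class-conditional case — then orients it
#' away from the root and augments every feature with the class as an
#' extra parent. Kruskal's algorithm is used with deterministic
#' tie-breaking: equal-weight edges are taken in lexicographic order of
#' their (min name, max name) key, and zero-weight edges remain eligible
#' so the result is always a spanning tree. The root defaults to the
#' first feature in canonical schema order; both choices make repeated
#' runs byte-identical.
#'
#' @param stats A `tan_stats` from [count_statistics()] with `n > 0` and
#'   at least two features.
#' @param root Feature to use as tree root; default first in canonical
#'   order.
#' @return A `tan_structure`: list with `class_var`, `features` (canonical
#'   order), `root`, `edges` (tibble `from`, `to`, `weight`, directed away
#'   from the root) and `parent` (named list; `NULL` for the root).
#' @export
learn_tan_structure <- function(stats, root = NULL) {
  schema <- stats$schema
  feats <- feature_vars(schema)
  if (length(feats) < 2) {
    rlang::abort(paste0(
      "TAN needs at least 2 features; with one feature the model ",
      "degenerates to plain naive Bayes, which is out of scope"
    ))
  }
  stopifnot(stats$n > 0)
  if (is.null(root)) root <- feats[1]
  if (!root %in% feats) rlang::abort(paste0("root is not a feature: ", root))

  pairs <- utils::combn(feats, 2)
  cand <- tibble::tibble(
    a = pairs[1, ], b = pairs[2, ],
    weight = vapply(
      seq_len(ncol(pairs)),
      function(k) {
        conditional_mutual_information(stats, pairs[1, k], pairs[2, k])
      },
      0.0
    )
  )
  learn_tan_structure_from_weights(schema, cand, root = root)
}

#' @export
print.tan_structure <- function(x, ...) {
  cat(
    "<tan_structure> class ", x$class_var, ", root ", x$root, "\n",
    sep = ""
  )
  for (i in seq_len(nrow(x$edges))) {
    cat(
      "  ", x$edges$from[i], " -> ", x$edges$to[i],
      sprintf("  (CMI %.4f)\n", x$edges$weight[i]),
      sep = ""
    )
  }
  invisible(x)
}

# features in an order where every parent precedes its child
tan_topological_order <- function(structure) {
  ord <- structure$root
  while (length(ord) < length(structure$features)) {
    nxt <- structure$edges$to[structure$edges$from %in% ord &
      !(structure$edges$to %in% ord)]
    ord <- c(ord, nxt)
  }
  ord
}

# undirected edge set as a canonical sorted key vector, for comparisons
tan_undirected_edges <- function(structure) {
  sort(
    paste(
      pmin(structure$edges$from, structure$edges$to),
      pmax(structure$edges$from, structure$edges$to),
      sep = " -- "
    ),
    method = "radix"
  )
}

#' Fit TAN parameters by Bayesian (Dirichlet) estimation
#'
#' Posterior-mean estimates under a uniform Dirichlet prior whose total
#' pseudo-count is the imaginary sample size `iss`, spread evenly over
#' each conditional probability table:
#' \deqn{\hat\theta(k \mid pa) = \frac{N(k, pa) + iss/(r q)}{N(pa) + iss/q}}
#' where `r` is the child's state count and `q` the number of parent
#' configurations. With `iss -> 0` this recovers the empirical
#' frequencies; large `iss` pulls every row toward uniform. Any `iss > 0`
#' makes every entry strictly positive, so classes or states a station
#' never observed still receive (small) probability — exactly what lets a
#' station reason about a fraud type absent from its own records.
#'
#' @param stats A `tan_stats` (typically pooled across stations).
#' @param structure A `tan_structure` consistent with `stats`' schema.
#' @param iss Imaginary sample size, non-negative; default 1.
#' @return A `tan_model`: list with `structure`, `schema`, `iss`,
#'   `class_prior` (named probability vector) and `cpts` (root feature:
#'   matrix `[state, class]`; other features: array
#'   `[state, class, parent_state]`).
#' @export
fit_tan <- function(stats, structure, iss = 1.0) {
  if (iss < 0) rlang::abort("imaginary sample size must be non-negative")
  schema <- stats$schema
  classes <- schema_states(schema, class_var(schema))
  r_c <- length(classes)

  prior <- (stats$class_counts + iss / r_c) / (stats$n + iss)
  if (iss == 0 && stats$n == 0) {
    rlang::abort("cannot fit with iss = 0 on empty statistics")
  }

  cpts <- list()
  for (v in structure$features) {
    states <- schema_states(schema, v)
    r <- length(states)
    parent <- structure$parent[[v]]
    if (is.null(parent)) {
      counts <- t(stats$single_counts[[v]]) # [state, class]
      q <- r_c
      n_pa <- matrix(stats$class_counts,
        nrow = r, ncol = r_c, byrow = TRUE
      )
      cpts[[v]] <- (counts + iss / (r * q)) / (n_pa + iss / q)
    } else {
      tab <- pair_tensor(stats, v, parent) # [class, v, parent]
      counts <- aperm(tab, c(2, 1, 3)) # [state, class, parent_state]
      p_states <- schema_states(schema, parent)
      q <- r_c * length(p_states)
      n_pa <- apply(counts, c(2, 3), sum) # [class, parent_state]
      n_pa_full <- aperm(
        array(n_pa, dim = c(r_c, length(p_states), r)), c(3, 1, 2)
      )
      cpts[[v]] <- (counts + iss / (r * q)) / (n_pa_full + iss / q)
    }
  }
  base::structure(
    list(
      structure = structure, schema = schema, iss = iss,
      class_prior = stats::setNames(as.numeric(prior), classes),
      cpts = cpts
    ),
    class = "tan_model"
  )
}

#' @export
print.tan_model <- function(x, ...) {
  cat(
    "<tan_model> class ", x$structure$class_var, " (",
    length(x$class_prior), " states), ", length(x$structure$features),
    " features, root ", x$structure$root, ", iss ", x$iss, "\n",
    sep = ""
  )
  invisible(x)
}

#' Posterior class probabilities and class predictions
#'
#' Computes `P(c | x)` proportional to `P(c) * prod_i theta(x_i | pa_i, c)`
#' in log space and normalizes over the model's (harmonized) class space.
#' Records must be complete: a missing feature value is an error, matching
#' the complete-data contract of ingestion. Argmax ties are broken toward
#' the canonically first class state.
#'
#' @param object A `tan_model`.
#' @param newdata Data frame of feature columns (a class column, if
#'   present, is ignored).
#' @param type `"prob"` for a tibble of per-class posteriors (one column
#'   per class state), `"class"` for a character vector of predicted
#'   classes.
#' @param ... Unused.
#' @return A tibble (`type = "prob"`) or character vector
#'   (`type = "class"`).
#' @export
predict.tan_model <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- rlang::arg_match(type)
  schema <- object$schema
  classes <- schema_states(schema, class_var(schema))
  newdata <- tibble::as_tibble(newdata)
  feats <- object$structure$features
  missing_cols <- setdiff(feats, names(newdata))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "missing feature column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  idx <- list()
  for (v in feats) {
    idx[[v]] <- match(newdata[[v]], schema_states(schema, v))
    if (anyNA(idx[[v]])) {
      rlang::abort(paste0(
        "missing or out-of-schema value in feature ", v,
        "; records must be complete"
      ))
    }
  }
  n <- nrow(newdata)
  log_post <- matrix(log(object$class_prior),
    nrow = n, ncol = length(classes), byrow = TRUE
  )
  for (v in feats) {
    cpt <- object$cpts[[v]]
    parent <- object$structure$parent[[v]]
    for (ci in seq_along(classes)) {
      log_post[, ci] <- log_post[, ci] + if (is.null(parent)) {
        log(cpt[idx[[v]], ci])
      } else {
        log(cpt[cbind(idx[[v]], ci, idx[[parent]])])
      }
    }
  }
  log_post <- log_post - apply(log_post, 1, max)
  post <- exp(log_post)
  post <- post / rowSums(post)
  colnames(post) <- classes
  if (type == "class") {
    return(classes[apply(post, 1, which.max)])
  }
  tibble::as_tibble(post)
}

#' @rdname predict.tan_model
#' @param model A `tan_model`.
#' @export
predict_class <- function(model, newdata) {
  predict(model, newdata, type = "class")
}

#' Tidy a TAN model's feature tree
#'
#' One row per directed feature edge with its conditional mutual
#' information weight, plus one row per class->feature edge (weight `NA`).
#'
#' @param x A `tan_model`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
#' @exportS3Method generics::tidy
tidy.tan_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      from = x$structure$class_var, to = x$structure$features,
      weight = NA_real_
    ),
    x$structure$edges
  )
}

#' One-row summary of a TAN model
#'
#' @param x A `tan_model`.
#' @param ... Unused.
#' @return A tibble with class/feature counts, root, iss and the total
#'   tree weight (sum of edge CMIs, nats).
#' @export
#' @exportS3Method generics::glance
glance.tan_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$class_prior),
    n_features = length(x$structure$features),
    root = x$structure$root,
    iss = x$iss,
    tree_weight = sum(x$structure$edges$weight)
  )
}

#' Serialize a TAN model to JSON
#'
#' Writes structure, state spaces, the flattened CPT tensors (row-major
#' with explicit dimensions), the imaginary sample size and the schema
#' fingerprint; [read_tan_model()] restores an identical model.
#'
#' @param model A `tan_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tan_model <- function(model, path) {
  payload <- list(
    format = "fedtan-model", version = 1L,
    schema = jsonlite::fromJSON(schema_to_json(model$schema),
      simplifyVector = FALSE
    ),
    schema_fingerprint = schema_fingerprint(model$schema),
    iss = model$iss,
    root = model$structure$root,
    edges = lapply(seq_len(nrow(model$structure$edges)), function(i) {
      list(
        from = model$structure$edges$from[i],
        to = model$structure$edges$to[i],
        weight = model$structure$edges$weight[i]
      )
    }),
    class_prior = as.list(model$class_prior),
    cpts = lapply(model$cpts, function(cpt) {
      list(dim = dim(cpt), values = as.numeric(cpt))
    })
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_tan_model
#' @export
read_tan_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(payload$format, "fedtan-model")) {
    rlang::abort("not a fedtan model JSON document")
  }
  schema <- schema_from_json(
    as.character(jsonlite::toJSON(payload$schema, auto_unbox = TRUE))
  )
  edges <- tibble::tibble(
    from = vapply(payload$edges, `[[`, "", "from"),
    to = vapply(payload$edges, `[[`, "", "to"),
    weight = vapply(payload$edges, `[[`, 0.0, "weight")
  )
  feats <- feature_vars(schema)
  parent <- stats::setNames(vector("list", length(feats)), feats)
  for (i in seq_len(nrow(edges))) parent[[edges$to[i]]] <- edges$from[i]
  struct <- structure(
    list(
      class_var = class_var(schema), features = feats,
      root = payload$root, edges = edges, parent = parent
    ),
    class = "tan_structure"
  )
  cpts <- lapply(payload$cpts, function(cpt) {
    array(unlist(cpt$values), dim = unlist(cpt$dim))
  })
  structure(
    list(
      structure = struct, schema = schema, iss = payload$iss,
      class_prior = unlist(payload$class_prior),
      cpts = cpts
    ),
    class = "tan_model"
  )
}
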