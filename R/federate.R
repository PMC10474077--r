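#' Wrap a station's local data behind the federation boundary
#'
#' A station node holds raw records that never cross the boundary: the
#' only things a node ever returns are its local schema summary (variable
#' names and observed state lists, no counts) and a serialized
#' sufficient-statistics message. An optional minimum-cell-count policy
#' lets a station refuse to publish statistics when any class it holds has
#' fewer than `policy_threshold` records, since small cells leak
#' near-record-level information.
#'
#' @param data A [station_data()].
#' @param station_id Label; defaults to the dataset's own id.
#' @param policy_threshold Minimum class cell count the station is willing
#'   to publish; 0 (default) disables the policy.
#' @return A `station_node`.
#' @export
station_node <- function(data, station_id = NULL, policy_threshold = 0) {
  if (is.null(station_id)) station_id <- station_id(data)
  structure(
    list(
      data = data, station_id = station_id,
      policy_threshold = policy_threshold
    ),
    class = "station_node"
  )
}

#' @export
print.station_node <- function(x, ...) {
  cat(
    "<station_node> ", x$station_id, ": ", nrow(x$data), " records",
    if (x$policy_threshold > 0) {
      paste0(" (min-cell policy ", x$policy_threshold, ")")
    } else {
      ""
    }, "\n",
    sep = ""
  )
  invisible(x)
}

#' Local schema summary of a station
#'
#' The schema-handshake step: the node reports its variable names, roles
#' and locally observed state lists — no counts, no records — so the
#' coordinator can build the harmonized union schema.
#'
#' @param node A [station_node()].
#' @return A [tan_schema()] whose state lists are the station's observed
#'   supports (empty lists for an empty station).
#' @export
station_local_schema <- function(node) {
  data <- node$data
  schema <- schema_of(data)
  tan_schema(tibble::tibble(
    variable = schema$variable,
    role = schema$role,
    states = lapply(schema$variable, function(v) lex_sort(data[[v]]))
  ))
}

#' Compute a station's statistics message
#'
#' Runs [count_statistics()] over the harmonized state space and wraps
#' the result, the station id, a protocol version and the harmonized
#' schema fingerprint into a message. If the node's minimum-cell-count
#' policy is violated (any locally held class with fewer than
#' `policy_threshold` records) the station abstains and a
#' `station_refusal` is returned instead; the coordinator proceeds
#' without it.
#'
#' @param node A [station_node()].
#' @param harmonized The harmonized [tan_schema()] agreed for the
#'   federation.
#' @return A `stats_message`, or a `station_refusal` when the policy
#'   forbids publishing.
#' @export
station_compute_stats <- function(node, harmonized) {
  local <- count_statistics(
    recast_station(node$data, harmonized), harmonized
  )
  t <- node$policy_threshold
  if (t > 0) {
    small <- local$class_counts > 0 & local$class_counts < t
    if (any(small)) {
      rlang::warn(paste0(
        "station ", node$station_id, " abstains: class cell count below ",
        t, " (", paste(names(local$class_counts)[small], collapse = ", "),
        ")"
      ))
      return(structure(
        list(
          station_id = node$station_id,
          reason = "minimum-cell-count policy"
        ),
        class = "station_refusal"
      ))
    }
  }
  structure(
    list(
      station_id = node$station_id,
      schema_fingerprint = schema_fingerprint(harmonized),
      protocol_version = 1L,
      stats = local
    ),
    class = "stats_message"
  )
}

#' Canonical JSON serialization of a statistics message
#'
#' Sorted keys, explicit tensor shapes, flat row-major count arrays. This
#' is the byte stream that would cross the wire; tests scan it to verify
#' that no record-level tuple ever leaves a station.
#'
#' @param msg A `stats_message`.
#' @return A JSON string.
#' @export
message_to_json <- function(msg) {
  s <- msg$stats
  payload <- list(
    class_counts = as.list(s$class_counts),
    format = "fedtan-stats",
    n = s$n,
    pair_counts = lapply(s$pair_counts, function(tab) {
      list(dim = dim(tab), values = as.integer(tab))
    }),
    protocol_version = msg$protocol_version,
    schema_fingerprint = msg$schema_fingerprint,
    single_counts = lapply(s$single_counts, function(tab) {
      list(dim = dim(tab), values = as.integer(tab))
    }),
    station_id = msg$station_id
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
}

#' Pool statistics messages at the coordinator
#'
#' Elementwise sum of every count tensor; the total `n` is the sum of the
#' stations' record counts. Order-independent. Messages whose schema
#' fingerprint differs from the first are rejected with an error naming
#' the offending station, which catches a station that skipped
#' harmonization.
#'
#' @param messages Non-empty list of `stats_message` objects.
#' @return The pooled `tan_stats`.
#' @export
aggregate_statistics <- function(messages) {
  stopifnot(length(messages) >= 1)
  fp <- messages[[1]]$schema_fingerprint
  for (m in messages[-1]) {
    if (!identical(m$schema_fingerprint, fp)) {
      rlang::abort(paste0(
        "schema fingerprint mismatch from station ", m$station_id
      ))
    }
  }
  Reduce(stats_add, lapply(messages, `[[`, "stats"))
}

#' Train the combined model from statistics messages
#'
#' Pools the messages with [aggregate_statistics()] and runs
#' [learn_tan_structure()] plus [fit_tan()] on the pooled counts. Because
#' the statistics are additive, the result is exactly the model that
#' centralized training on the pooled records would produce.
#'
#' @param messages Non-empty list of `stats_message` objects.
#' @param iss Imaginary sample size passed to [fit_tan()].
#' @param root Optional tree root override.
#' @return A `tan_model`.
#' @export
coordinator_train_combined <- function(messages, iss = 1.0, root = NULL) {
  pooled <- aggregate_statistics(messages)
  fit_tan(pooled, learn_tan_structure(pooled, root = root), iss = iss)
}

#' Run a full federation round
#'
#' Orchestrates the protocol of a federated training round: schema
#' handshake (each station publishes its local schema), harmonization to
#' the union schema, per-station statistics computation under the
#' harmonized state space, aggregation at the coordinator and combined
#' model training. Stations whose minimum-cell-count policy is violated
#' abstain; the round proceeds with the remaining stations and the audit
#' trail records who contributed and how many bytes each message held.
#'
#' With `combine = "average_cpt"` the coordinator instead averages
#' station-fitted conditional probability tables (n-weighted), after
#' building a consensus tree from n-weighted local CMI matrices. This is
#' the lossy alternative to statistics pooling, kept for comparison: it
#' does not reproduce the centralized model.
#'
#' @param stations List of [station_node()] objects (or [station_data()]
#'   objects, wrapped automatically), at least one holding data.
#' @param iss Imaginary sample size.
#' @param root Optional tree root override.
#' @param combine `"pool"` (exact, default) or `"average_cpt"`.
#' @return A `federation_result`: list with `model` (the combined
#'   `tan_model`), `schema` (harmonized), `audit` (tibble: station,
#'   contributed flag, message bytes) and `messages` (the serialized JSON
#'   payloads, as the coordinator saw them).
#' @export
run_federation <- function(stations, iss = 1.0, root = NULL,
                           combine = c("pool", "average_cpt")) {
  combine <- rlang::arg_match(combine)
  stations <- lapply(stations, function(s) {
    if (inherits(s, "station_node")) s else station_node(s)
  })
  if (length(stations) == 0 || all(vapply(stations, function(s) {
    nrow(s$data) == 0
  }, TRUE))) {
    rlang::abort("need at least one station with data")
  }
  harmonized <- harmonize_schemas(lapply(stations, station_local_schema))
  outcomes <- lapply(stations, station_compute_stats, harmonized = harmonized)
  refused <- vapply(outcomes, inherits, TRUE, "station_refusal")
  if (all(refused)) {
    rlang::abort("all stations refused to publish statistics")
  }
  messages <- outcomes[!refused]
  json <- vapply(messages, message_to_json, "")
  bytes <- integer(length(stations))
  bytes[!refused] <- nchar(json, type = "bytes")
  audit <- tibble::tibble(
    station = unname(vapply(stations, `[[`, "", "station_id")),
    contributed = !refused,
    message_bytes = bytes
  )
  model <- if (combine == "pool") {
    coordinator_train_combined(messages, iss = iss, root = root)
  } else {
    combine_average_cpt(messages, iss = iss, root = root)
  }
  structure(
    list(
      model = model, schema = harmonized, audit = audit,
      messages = stats::setNames(
        as.list(json), vapply(messages, `[[`, "", "station_id")
      )
    ),
    class = "federation_result"
  )
}

#' @export
print.federation_result <- function(x, ...) {
  cat(
    "<federation_result> ", sum(x$audit$contributed), "/",
    nrow(x$audit), " stations contributed\n",
    sep = ""
  )
  print(x$model)
  invisible(x)
}

# Lossy comparison mode: consensus tree from n-weighted local CMI, then
# n-weighted arithmetic mean of station-fitted CPT entries (renormalized).
combine_average_cpt <- function(messages, iss, root) {
  all_stats <- lapply(messages, `[[`, "stats")
  w <- vapply(all_stats, `[[`, 0.0, "n")
  w <- w / sum(w)
  schema <- all_stats[[1]]$schema
  feats <- feature_vars(schema)
  pairs <- utils::combn(feats, 2)
  avg_cmi <- vapply(seq_len(ncol(pairs)), function(k) {
    sum(w * vapply(all_stats, function(s) {
      if (s$n == 0) 0 else {
        conditional_mutual_information(s, pairs[1, k], pairs[2, k])
      }
    }, 0.0))
  }, 0.0)
  struct <- learn_tan_structure_from_weights(
    schema,
    tibble::tibble(a = pairs[1, ], b = pairs[2, ], weight = avg_cmi),
    root = root
  )
  models <- lapply(all_stats, fit_tan, structure = struct, iss = iss)
  avg <- models[[1]]
  avg$class_prior <- Reduce(`+`, Map(function(m, wi) wi * m$class_prior,
    models, w))
  for (v in feats) {
    avg$cpts[[v]] <- Reduce(`+`, Map(function(m, wi) wi * m$cpts[[v]],
      models, w))
  }
  avg
}

# Maximum-weight spanning tree from precomputed edge weights (same
# tie-breaking as learn_tan_structure); used by the CPT-averaging mode.
learn_tan_structure_from_weights <- function(schema, cand, root = NULL) {
  feats <- feature_vars(schema)
  if (is.null(root)) root <- feats[1]
  # normalize each edge to its lexicographic (min name, max name) key so
  # equal-weight ties resolve identically whatever the schema order
  normalized <- t(vapply(
    seq_len(nrow(cand)),
    function(k) sort(c(cand$a[k], cand$b[k]), method = "radix"),
    c("", "")
  ))
  cand$a <- normalized[, 1]
  cand$b <- normalized[, 2]
  cand <- cand[order(-cand$weight, cand$a, cand$b, method = "radix"), ]
  comp <- stats::setNames(seq_along(feats), feats)
  chosen <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ra <- comp[[cand$a[k]]]
    rb <- comp[[cand$b[k]]]
    if (ra != rb) {
      comp[comp == rb] <- ra
      chosen[k] <- TRUE
    }
  }
  undirected <- cand[chosen, ]
  adj <- lapply(stats::setNames(feats, feats), function(f) {
    c(undirected$b[undirected$a == f], undirected$a[undirected$b == f])
  })
  parent <- stats::setNames(vector("list", length(feats)), feats)
  visited <- stats::setNames(rep(FALSE, length(feats)), feats)
  queue <- root
  visited[root] <- TRUE
  edges <- tibble::tibble(from = character(), to = character(),
    weight = numeric())
  while (length(queue) > 0) {
    node <- queue[1]
    queue <- queue[-1]
    for (nb in sort(adj[[node]], method = "radix")) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        parent[[nb]] <- node
        w <- undirected$weight[
          (undirected$a == node & undirected$b == nb) |
            (undirected$a == nb & undirected$b == node)
        ]
        edges <- dplyr::bind_rows(
          edges, tibble::tibble(from = node, to = nb, weight = w)
        )
        queue <- c(queue, nb)
      }
    }
  }
  structure(
    list(
      class_var = class_var(schema), features = feats, root = root,
      edges = edges, parent = parent
    ),
    class = "tan_structure"
  )
}
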