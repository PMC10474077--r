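#' Per-station comparison of individual versus combined models
#'
#' The first evaluation design: every station splits its own data 80/20
#' (stratified by fraud type by default, so a single-record class cannot
#' vanish from training), trains an individual TAN on its local training
#' partition, and is also served the combined model federated over all
#' stations' training partitions. Both models are scored on that
#' station's local test partition. All models live on the harmonized
#' class space, so a station that never observed a fraud type still
#' predicts over it — its individual model only through the Dirichlet
#' prior, the combined model through the other stations' counts.
#'
#' Per-station split seeds derive from `seed` as `seed + station index`.
#'
#' @param stations List of [station_data()] objects (>= 2).
#' @param seed Integer seed driving every split.
#' @param fraction Train proportion; default 0.8.
#' @param iss Imaginary sample size; default 1.
#' @param stratify Stratify the per-station splits; default `TRUE`.
#' @return A tibble with one row per (station, model) pair: `station`,
#'   `model` (`"individual"` / `"combined"`), `auc`, `avg_sensitivity`,
#'   `avg_specificity`, `n_train`, `n_test`. The fitted models and
#'   evaluations are attached as attributes `models` and `evaluations`.
#' @export
run_experiment_individual_vs_combined <- function(stations, seed,
                                                  fraction = 0.8,
                                                  iss = 1.0,
                                                  stratify = TRUE) {
  stopifnot(length(stations) >= 2)
  harmonized <- harmonize_schemas(lapply(stations, schema_of))
  stations <- lapply(stations, recast_station, schema = harmonized)
  ids <- purrr::map_chr(stations, station_id)

  too_small <- purrr::map_int(stations, nrow) < 2
  if (any(too_small)) {
    rlang::warn(paste0(
      "station(s) too small to split, excluded: ",
      paste(ids[too_small], collapse = ", ")
    ))
    stations <- stations[!too_small]
    ids <- ids[!too_small]
  }

  splits <- lapply(seq_along(stations), function(i) {
    split_train_test(stations[[i]],
      fraction = fraction,
      seed = seed + i, stratify = stratify
    )
  })
  combined <- run_federation(
    lapply(splits, `[[`, "train"),
    iss = iss
  )$model

  rows <- list()
  models <- list()
  evals <- list()
  for (i in seq_along(stations)) {
    local_stats <- count_statistics(splits[[i]]$train, harmonized)
    individual <- fit_tan(
      local_stats, learn_tan_structure(local_stats),
      iss = iss
    )
    ev_ind <- evaluate_model(individual, splits[[i]]$test)
    ev_com <- evaluate_model(combined, splits[[i]]$test)
    models[[ids[i]]] <- list(individual = individual, combined = combined)
    evals[[ids[i]]] <- list(individual = ev_ind, combined = ev_com)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(
        station = ids[i], model = c("individual", "combined")
      ),
      dplyr::bind_rows(glance(ev_ind), glance(ev_com))
    ) |>
      dplyr::mutate(n_train = nrow(splits[[i]]$train), .before = "n_test")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "models") <- models
  attr(out, "evaluations") <- evals
  out
}

#' Centralized versus federated training on a pooled split
#'
#' The second evaluation design: all stations' records are pooled, split
#' once 80/20 by a plain (unstratified) random draw, and two models are
#' trained on the same training partition — one centrally on the pooled
#' rows, one by federating over the per-station slices of that same
#' partition. Both are scored on the pooled test partition. Under
#' sufficient-statistics pooling the two rows coincide exactly; the
#' comparison quantifies that no information is lost by keeping records
#' at their stations.
#'
#' @param stations List of [station_data()] objects.
#' @param seed Integer seed for the pooled split.
#' @param fraction Train proportion; default 0.8.
#' @param iss Imaginary sample size; default 1.
#' @return A tibble with rows `centralized` and `federated`: `approach`,
#'   `auc`, `avg_sensitivity`, `avg_specificity`, `n_test`. Models and
#'   evaluations attached as attributes.
#' @export
run_experiment_centralized_vs_federated <- function(stations, seed,
                                                    fraction = 0.8,
                                                    iss = 1.0) {
  harmonized <- harmonize_schemas(lapply(stations, schema_of))
  stations <- lapply(stations, recast_station, schema = harmonized)
  ids <- purrr::map_chr(stations, station_id)
  origin <- rep(ids, purrr::map_int(stations, nrow))
  pooled <- station_data(
    dplyr::bind_rows(lapply(stations, tibble::as_tibble)),
    harmonized, "pooled"
  )
  if (nrow(pooled) < 5) rlang::abort("pooled dataset too small to split")

  split <- split_train_test(pooled,
    fraction = fraction, seed = seed,
    stratify = FALSE
  )
  train_origin <- origin[split$train_idx]

  central_stats <- count_statistics(split$train, harmonized)
  centralized <- fit_tan(
    central_stats, learn_tan_structure(central_stats),
    iss = iss
  )
  slices <- lapply(unique(ids), function(id) {
    rows <- tibble::as_tibble(split$train)[train_origin == id, ]
    station_data(rows, harmonized, id)
  })
  slices <- slices[vapply(slices, nrow, 0L) > 0]
  federated <- run_federation(slices, iss = iss)$model

  ev_cen <- evaluate_model(centralized, split$test)
  ev_fed <- evaluate_model(federated, split$test)
  out <- dplyr::bind_cols(
    tibble::tibble(approach = c("centralized", "federated")),
    dplyr::bind_rows(glance(ev_cen), glance(ev_fed))
  )
  attr(out, "models") <- list(centralized = centralized, federated = federated)
  attr(out, "evaluations") <- list(centralized = ev_cen, federated = ev_fed)
  out
}
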