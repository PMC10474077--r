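#' Describe one class's contribution to a synthetic station
#'
#' A class profile fixes an exact record count for one fraud type at one
#' station, a categorical distribution per feature variable, and an
#' inclusive year span. Counts are exact — only attribute values are
#' stochastic — because real surveillance summaries report exact per-class
#' case counts that the generator must reproduce for every seed.
#'
#' @param class_label Class state the records carry.
#' @param count Exact number of records to emit (>= 0).
#' @param attribute_dists Named list: feature variable -> named numeric
#'   vector of state probabilities (must sum to 1 within 1e-9). A `"Year"`
#'   entry overrides `year_range`.
#' @param year_range Inclusive integer year span, drawn uniformly when no
#'   explicit year distribution is given.
#' @return A `class_profile` object.
#' @export
class_profile <- function(class_label, count, attribute_dists,
                          year_range = NULL) {
  stopifnot(count >= 0)
  for (nm in names(attribute_dists)) {
    d <- attribute_dists[[nm]]
    if (abs(sum(d) - 1) > 1e-9) {
      rlang::abort(paste0("distribution for ", nm, " must sum to 1"))
    }
    if (any(d < 0)) rlang::abort("probabilities must be non-negative")
  }
  structure(
    list(
      class_label = class_label, count = as.integer(count),
      attribute_dists = attribute_dists, year_range = year_range
    ),
    class = "class_profile"
  )
}

# Inverse-CDF draw of one categorical value per row of a probability
# matrix (rows sum to 1, columns = states), consuming one uniform per row.
sample_categorical <- function(prob, u) {
  cum <- t(apply(prob, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  pmin(idx, ncol(prob))
}

#' Generate one synthetic station dataset
#'
#' Emits exactly `count` records per profile (deterministic for every
#' seed); feature values are drawn independently per record from the
#' profile's distributions with a single seeded stream, consumed
#' column-by-column in canonical variable order so adding a variable never
#' perturbs the draws of earlier columns. Record order is shuffled with the
#' same stream.
#'
#' @param profiles List of [class_profile()] objects (distinct classes).
#' @param schema A [tan_schema()]; every state with positive probability
#'   mass must be declared in it.
#' @param station_id Label for the generated station.
#' @param seed Integer seed.
#' @return A [station_data()].
#' @export
generate_station <- function(profiles, schema, station_id, seed) {
  cls <- class_var(schema)
  for (p in profiles) {
    for (nm in names(p$attribute_dists)) {
      bad <- setdiff(
        names(p$attribute_dists[[nm]])[p$attribute_dists[[nm]] > 0],
        schema_states(schema, nm)
      )
      if (length(bad) > 0) {
        rlang::abort(paste0(
          "distribution for ", nm, " puts mass on undeclared state(s): ",
          paste(bad, collapse = ", ")
        ))
      }
    }
  }
  labels <- unlist(lapply(profiles, function(p) {
    rep(p$class_label, p$count)
  }))
  n <- length(labels)
  records <- tibble::tibble(!!cls := as.character(labels))
  if (n == 0) {
    for (v in feature_vars(schema)) records[[v]] <- character()
    return(station_data(records[, schema$variable], schema, station_id))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  for (v in feature_vars(schema)) {
    states <- schema_states(schema, v)
    prob <- matrix(0, nrow = n, ncol = length(states))
    for (p in profiles) {
      d <- p$attribute_dists[[v]]
      if (is.null(d)) {
        if (v == "Year" && !is.null(p$year_range)) {
          yrs <- as.character(seq(p$year_range[1], p$year_range[2]))
          d <- stats::setNames(rep(1 / length(yrs), length(yrs)), yrs)
        } else {
          rlang::abort(paste0(
            "profile for class ", p$class_label,
            " has no distribution for ", v
          ))
        }
      }
      rows <- which(labels == p$class_label)
      prob[rows, match(names(d), states)] <- matrix(
        d, nrow = length(rows), ncol = length(d), byrow = TRUE
      )
    }
    records[[v]] <- states[sample_categorical(prob, stats::runif(n))]
  }
  records <- records[sample.int(n), schema$variable]
  station_data(records, schema, station_id)
}

#' Simulate the three-station food fraud case study
#'
#' Generates three synthetic data stations mirroring a documented
#' surveillance composition: two stations of RASFF-style notifications
#' split by period and one station of EMA-style records, with exact
#' per-station fraud-type counts, distinct year spans and strong class
#' imbalance (STATION-2 holds a single "Artificial
#' enhancement/Improvement" case; STATION-1 lacks that fraud type
#' entirely). Feature values (product category, origin country, reporting
#' country) are drawn from built-in class-shifted multinomials so that
#' fraud type is learnable from the features; they do not attempt to
#' reproduce any real product or country marginals.
#'
#' Composition: STATION-1 (2008-2013): Smuggling-Mislabeling-Origin
#' Masking 105, Substitution-Dilution 97; STATION-2 (2014-2018):
#' Artificial enhancement/Improvement 1, Smuggling-Mislabeling-Origin
#' Masking 135, Substitution-Dilution 8; STATION-3 (2008-2018): Artificial
#' enhancement/Improvement 21, Smuggling-Mislabeling-Origin Masking 23,
#' Substitution-Dilution 51. Station totals are therefore 202, 144 and 95.
#'
#' @param seed Integer seed; per-station streams derive from it as
#'   `seed`, `seed + 1`, `seed + 2`.
#' @return Named list of three [station_data()] objects
#'   (`STATION-1..3`), each carrying the full harmonized schema.
#' @export
simulate_case_study <- function(seed = 1) {
  schema <- case_study_schema()
  profiles <- case_study_profiles()
  out <- lapply(seq_along(profiles), function(i) {
    generate_station(
      profiles[[i]], schema, names(profiles)[i],
      seed = seed + i - 1L
    )
  })
  stats::setNames(out, names(profiles))
}

#' @rdname simulate_case_study
#' @export
case_study_schema <- function() {
  tan_schema(tibble::tibble(
    variable = c("Fraud type", "Product", "Year", "Country (O)", "Country (N)"),
    role = c("class", rep("feature", 4)),
    states = list(
      c(
        "Artificial enhancement/Improvement",
        "Smuggling-Mislabeling-Origin Masking",
        "Substitution-Dilution"
      ),
      c(
        "Alcoholic", "Dairy", "Fish_Seafood", "Herbs_Spices", "Meat",
        "Oils_Fats"
      ),
      as.character(2008:2018),
      c(
        "Brazil", "China", "Croatia", "India", "South Korea", "Spain",
        "Turkey", "Vietnam"
      ),
      c(
        "Belgium", "France", "Germany", "Italy", "Netherlands",
        "United Kingdom"
      )
    )
  ))
}

# Class-conditional feature multinomials shared by every station; each
# class peaks on different products/countries (with a small floor on all
# states) so models trained on any station have signal to find.
case_study_class_dists <- function() {
  norm <- function(x) x / sum(x)
  schema <- case_study_schema()
  prods <- schema_states(schema, "Product")
  orig <- schema_states(schema, "Country (O)")
  rep_c <- schema_states(schema, "Country (N)")
  w <- function(states, peaks, peak_w = 6, floor_w = 1) {
    x <- stats::setNames(rep(floor_w, length(states)), states)
    x[peaks] <- peak_w
    norm(x)
  }
  list(
    "Artificial enhancement/Improvement" = list(
      "Product" = w(prods, c("Herbs_Spices", "Oils_Fats")),
      "Country (O)" = w(orig, c("India", "China")),
      "Country (N)" = w(rep_c, c("Germany", "United Kingdom"))
    ),
    "Smuggling-Mislabeling-Origin Masking" = list(
      "Product" = w(prods, c("Fish_Seafood", "Meat")),
      "Country (O)" = w(orig, c("China", "Vietnam")),
      "Country (N)" = w(rep_c, c("United Kingdom", "Netherlands"))
    ),
    "Substitution-Dilution" = list(
      "Product" = w(prods, c("Alcoholic", "Dairy", "Oils_Fats"), peak_w = 4),
      "Country (O)" = w(orig, c("Croatia", "Spain", "Turkey"), peak_w = 4),
      "Country (N)" = w(rep_c, c("France", "Italy"))
    )
  )
}

case_study_profiles <- function() {
  dists <- case_study_class_dists()
  prof <- function(label, count, years) {
    class_profile(label, count, dists[[label]], year_range = years)
  }
  list(
    "STATION-1" = list(
      prof("Smuggling-Mislabeling-Origin Masking", 105, c(2008, 2013)),
      prof("Substitution-Dilution", 97, c(2008, 2013))
    ),
    "STATION-2" = list(
      prof("Artificial enhancement/Improvement", 1, c(2014, 2018)),
      prof("Smuggling-Mislabeling-Origin Masking", 135, c(2014, 2018)),
      prof("Substitution-Dilution", 8, c(2014, 2018))
    ),
    "STATION-3" = list(
      prof("Artificial enhancement/Improvement", 21, c(2008, 2018)),
      prof("Smuggling-Mislabeling-Origin Masking", 23, c(2008, 2018)),
      prof("Substitution-Dilution", 51, c(2008, 2018))
    )
  )
}

#' Sample records from a fitted TAN model
#'
#' Ancestral sampling: the class is drawn from the model prior, then
#' features are drawn in topological order of the feature tree, each
#' conditioned on the class and (for non-root features) its tree parent.
#' One seeded stream is consumed column-by-column.
#'
#' @param model A `tan_model` (see [fit_tan()]).
#' @param n Number of records.
#' @param seed Integer seed.
#' @param station_id Label for the sampled dataset.
#' @return A [station_data()] under the model's schema.
#' @export
simulate_tan <- function(model, n, seed, station_id = "simulated") {
  schema <- model$schema
  cls <- class_var(schema)
  classes <- schema_states(schema, cls)
  empty <- stats::setNames(
    rep(list(character()), nrow(schema)), schema$variable
  )
  if (n == 0) {
    return(station_data(as.data.frame(empty), schema, station_id))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  prior <- matrix(model$class_prior,
    nrow = n, ncol = length(classes),
    byrow = TRUE
  )
  ci <- sample_categorical(prior, stats::runif(n))
  records <- tibble::tibble(!!cls := classes[ci])
  xi <- list()
  for (v in tan_topological_order(model$structure)) {
    states <- schema_states(schema, v)
    parent <- model$structure$parent[[v]]
    cpt <- model$cpts[[v]]
    if (is.null(parent)) {
      prob <- t(cpt)[ci, , drop = FALSE] # [class, state] rows by class
    } else {
      flat <- matrix(aperm(cpt, c(2, 3, 1)), ncol = length(states))
      row_id <- ci + (xi[[parent]] - 1L) * length(classes)
      prob <- flat[row_id, , drop = FALSE]
    }
    xi[[v]] <- sample_categorical(prob, stats::runif(n))
    records[[v]] <- states[xi[[v]]]
  }
  station_data(records[, schema$variable], schema, station_id)
}
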