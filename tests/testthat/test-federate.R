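test_that("station local schemas expose observed support only", {
  stations <- simulate_case_study(seed = 2)
  s1 <- station_local_schema(station_node(stations[["STATION-1"]]))
  expect_length(schema_states(s1, "Fraud type"), 2)
  expect_false(
    "Artificial enhancement/Improvement" %in% schema_states(s1, "Fraud type")
  )

  empty <- station_data(
    tibble::tibble(C = character(), F1 = character(), F2 = character()),
    toy_schema(2, 2, 2), "E"
  )
  es <- station_local_schema(station_node(empty))
  expect_identical(es$variable, c("C", "F1", "F2"))
  expect_true(all(lengths(es$states) == 0))
})

test_that("station stats equal direct computation on the same data", {
  schema <- toy_schema(3, 2, 2)
  ds <- random_station(schema, 40, seed = 12)
  node <- station_node(ds)
  harmonized <- station_local_schema(node)
  msg <- station_compute_stats(node, harmonized)
  direct <- count_statistics(
    station_data(tibble::as_tibble(ds), harmonized, "S"), harmonized
  )
  expect_equal(msg$stats$class_counts, direct$class_counts)
  expect_equal(msg$stats$pair_counts, direct$pair_counts)
  expect_identical(msg$schema_fingerprint, schema_fingerprint(harmonized))
})

test_that("aggregation is identity, commutative, with empty identity", {
  schema <- toy_schema(2, 2, 2)
  a <- random_station(schema, 20, seed = 1, id = "A")
  b <- random_station(schema, 30, seed = 2, id = "B")
  harmonized <- harmonize_schemas(list(
    station_local_schema(station_node(a)),
    station_local_schema(station_node(b))
  ))
  ma <- station_compute_stats(station_node(a), harmonized)
  mb <- station_compute_stats(station_node(b), harmonized)

  expect_equal(aggregate_statistics(list(ma)), ma$stats)
  ab <- aggregate_statistics(list(ma, mb))
  ba <- aggregate_statistics(list(mb, ma))
  expect_equal(ab, ba)
  expect_equal(ab$n, 50)
  expect_equal(stats_add(ab, empty_statistics(harmonized)), ab)
})

test_that("fingerprint mismatches name the offending station", {
  schema <- toy_schema(2, 2, 2)
  a <- random_station(schema, 10, seed = 1, id = "A")
  b <- random_station(schema, 10, seed = 2, id = "B")
  ma <- station_compute_stats(station_node(a), schema)
  mb <- station_compute_stats(station_node(b), schema)
  mb$schema_fingerprint <- "deadbeef"
  expect_error(aggregate_statistics(list(ma, mb)), "station B")
})

test_that("the three-station aggregate holds all 441 records", {
  stations <- simulate_case_study(seed = 4)
  nodes <- lapply(stations, station_node)
  harmonized <- harmonize_schemas(lapply(nodes, station_local_schema))
  msgs <- lapply(nodes, station_compute_stats, harmonized = harmonized)
  pooled <- aggregate_statistics(msgs)
  expect_equal(pooled$n, 441)
  expect_length(pooled$class_counts, 3)
})

test_that("federated training equals centralized training exactly", {
  # the headline property: for random datasets and random partitions into
  # stations, pooling statistics reproduces the centralized model to
  # machine precision
  for (seed in 1:10) {
    set.seed(seed)
    n_feat <- sample(3:6, 1)
    n_cls <- sample(2:4, 1)
    n <- sample(50:300, 1)
    k <- sample(1:4, 1)
    schema <- toy_schema(n_feat, n_states = sample(2:3, 1), n_cls)
    pooled_ds <- random_station(schema, n, seed = seed * 13, id = "all")
    parts <- partition_station(pooled_ds, k, seed = seed * 7)

    central_stats <- count_statistics(pooled_ds)
    centralized <- fit_tan(
      central_stats, learn_tan_structure(central_stats),
      iss = 1
    )
    fed <- run_federation(parts, iss = 1)

    expect_identical(
      fed$model$structure$edges[, c("from", "to")],
      centralized$structure$edges[, c("from", "to")]
    )
    expect_lte(max_cpt_diff(fed$model, centralized), 1e-12)
  }
})

test_that("a single station federation equals local training", {
  schema <- toy_schema(3, 2, 3)
  ds <- random_station(schema, 80, seed = 20)
  fed <- run_federation(list(ds), iss = 1)
  # the harmonized schema is the station's own observed support
  local_schema <- station_local_schema(station_node(ds))
  local_stats <- count_statistics(
    station_data(tibble::as_tibble(ds), local_schema, "S"), local_schema
  )
  local <- fit_tan(local_stats, learn_tan_structure(local_stats), iss = 1)
  expect_lte(max_cpt_diff(fed$model, local), 1e-15)
})

test_that("min-cell-count policy makes small stations abstain", {
  stations <- simulate_case_study(seed = 6)
  nodes <- list(
    station_node(stations[["STATION-1"]]),
    station_node(stations[["STATION-2"]], policy_threshold = 5),
    station_node(stations[["STATION-3"]])
  )
  # STATION-2 holds a single Artificial enhancement/Improvement record
  expect_warning(fed <- run_federation(nodes, iss = 1), "STATION-2 abstains")
  expect_equal(sum(fed$audit$contributed), 2)
  expect_false(fed$audit$contributed[fed$audit$station == "STATION-2"])
  # threshold 0 switches the policy off
  fed_all <- run_federation(lapply(stations, station_node), iss = 1)
  expect_equal(sum(fed_all$audit$contributed), 3)

  refusing <- lapply(stations, station_node, policy_threshold = 1000)
  expect_error(
    suppressWarnings(run_federation(refusing)),
    "all stations refused"
  )
})

test_that("serialized traffic contains no record-level tuples", {
  stations <- simulate_case_study(seed = 8)
  fed <- run_federation(stations, iss = 1)
  all_bytes <- paste(unlist(fed$messages), collapse = "\n")
  for (ds in stations) {
    tuples <- do.call(paste, c(tibble::as_tibble(ds), sep = ","))
    expect_false(any(vapply(
      unique(tuples), grepl, TRUE, x = all_bytes, fixed = TRUE
    )))
  }
  # while schema-level state labels legitimately appear
  expect_true(grepl("Substitution-Dilution", all_bytes, fixed = TRUE))
})

test_that("CPT averaging is lossy relative to statistic pooling", {
  schema <- toy_schema(3, 2, 2)
  ds <- random_station(schema, 120, seed = 30)
  parts <- partition_station(ds, 3, seed = 31)
  exact <- run_federation(parts, iss = 1)$model
  avg <- run_federation(parts, iss = 1, combine = "average_cpt")$model
  central_stats <- count_statistics(ds)
  centralized <- fit_tan(
    central_stats, learn_tan_structure(central_stats),
    iss = 1
  )
  expect_lte(max_cpt_diff(exact, centralized), 1e-12)
  expect_gt(max_cpt_diff(avg, centralized), 1e-12)
})
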