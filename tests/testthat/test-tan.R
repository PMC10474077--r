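test_that("sufficient statistics match a brute-force tally", {
  schema <- toy_schema(3, 2, 3)
  ds <- random_station(schema, 20, seed = 2)
  st <- count_statistics(ds)
  expect_equal(st$n, 20)
  for (pair in list(c("F1", "F2"), c("F1", "F3"), c("F2", "F3"))) {
    expect_equal(
      unname(unclass(st$pair_counts[[paste(pair[1], pair[2],
        sep = " || ")]])),
      brute_counts(ds, schema, "C", pair[1], pair[2]),
      ignore_attr = TRUE
    )
  }
  # pair tensors marginalize to the single tensors and class counts
  for (f in c("F1", "F2", "F3")) {
    expect_equal(
      unname(rowSums(st$single_counts[[f]])),
      unname(st$class_counts)
    )
  }
  expect_equal(
    unname(apply(st$pair_counts[["F1 || F2"]], c(1, 2), sum)),
    unname(unclass(st$single_counts[["F1"]])),
    ignore_attr = TRUE
  )
  expect_equal(sum(st$class_counts), st$n)
})

test_that("empty and single-record statistics are exact", {
  schema <- toy_schema(2, 2, 2)
  empty <- empty_statistics(schema)
  expect_equal(empty$n, 0)
  expect_true(all(unlist(empty$pair_counts) == 0))

  one <- count_statistics(
    station_data(tibble::tibble(C = "c1", F1 = "b", F2 = "a"), schema, "S")
  )
  expect_equal(sum(one$class_counts), 1)
  for (tab in one$pair_counts) {
    expect_equal(sum(tab == 1), 1)
    expect_equal(sum(tab), 1)
  }
})

test_that("out-of-schema records are a hard error at counting time", {
  schema <- toy_schema(2, 2, 2)
  bad <- tibble::tibble(C = "c0", F1 = "zzz", F2 = "a")
  expect_error(count_statistics(bad, schema), "outside the schema")
})

test_that("CMI is zero under conditional independence, ln 2 at identity", {
  schema <- toy_schema(2, 2, 2)
  # per class, a 2x2 table with all cells equal -> exact independence
  grid <- expand.grid(
    C = c("c0", "c1"), F1 = c("a", "b"), F2 = c("a", "b"),
    stringsAsFactors = FALSE
  )
  ds <- station_data(
    grid[rep(seq_len(nrow(grid)), each = 25), ], schema, "S"
  )
  st <- count_statistics(ds)
  expect_equal(conditional_mutual_information(st, "F1", "F2"), 0)

  # single observed class, F1 == F2, 50/50 marginal -> ln 2
  ds2 <- station_data(
    tibble::tibble(
      C = rep("c0", 100),
      F1 = rep(c("a", "b"), each = 50),
      F2 = rep(c("a", "b"), each = 50)
    ),
    schema, "S"
  )
  st2 <- count_statistics(ds2)
  expect_equal(conditional_mutual_information(st2, "F1", "F2"), log(2),
    tolerance = 1e-12)
})

test_that("CMI equals direct triple summation, is symmetric, non-negative", {
  schema <- toy_schema(3, 3, 2)
  for (seed in 1:10) {
    ds <- random_station(schema, 60, seed = seed)
    st <- count_statistics(ds)
    pairs <- list(c("F1", "F2"), c("F1", "F3"), c("F2", "F3"))
    for (p in pairs) {
      got <- conditional_mutual_information(st, p[1], p[2])
      tab <- brute_counts(ds, schema, "C", p[1], p[2])
      expect_equal(got, brute_cmi(tab), tolerance = 1e-12)
      expect_equal(got, conditional_mutual_information(st, p[2], p[1]),
        tolerance = 1e-15)
      expect_gte(got, 0)
    }
  }
  expect_error(conditional_mutual_information(
    count_statistics(random_station(schema, 5, 1)), "F1", "F1"
  ), "distinct")
})

test_that("two features force the unique tree", {
  schema <- toy_schema(2, 2, 2)
  st <- count_statistics(random_station(schema, 30, seed = 4))
  struct <- learn_tan_structure(st)
  expect_equal(struct$root, "F1")
  expect_identical(struct$edges$from, "F1")
  expect_identical(struct$edges$to, "F2")
  expect_null(struct$parent$F1)
  expect_equal(struct$parent$F2, "F1")
})

test_that("the learned tree maximizes weight over all labeled trees", {
  schema <- toy_schema(4, 2, 2)
  feats <- paste0("F", 1:4)
  for (seed in 1:8) {
    # non-uniform class-dependent data so CMI weights are generic
    set.seed(seed)
    n <- 80
    cls <- sample(c("c0", "c1"), n, replace = TRUE)
    cols <- lapply(1:4, function(i) {
      p <- stats::runif(1, 0.2, 0.8)
      ifelse(stats::runif(n) < ifelse(cls == "c0", p, 1 - p), "a", "b")
    })
    names(cols) <- feats
    ds <- station_data(
      tibble::as_tibble(c(list(C = cls), cols)), schema, "S"
    )
    st <- count_statistics(ds)
    w <- function(i, j) {
      conditional_mutual_information(st, feats[i], feats[j])
    }
    best <- brute_best_tree(4, w)
    best_key <- sort(apply(best, 1, function(e) {
      paste(feats[min(e)], feats[max(e)], sep = " -- ")
    }), method = "radix")
    struct <- learn_tan_structure(st)
    expect_identical(fedtan:::tan_undirected_edges(struct), best_key)
    expect_equal(nrow(struct$edges), 3)
  }
})

test_that("equal weights give the deterministic lexicographic star", {
  schema <- tan_schema(tibble::tibble(
    variable = c("C", "Fb", "Fa", "Fc", "Fd"),
    role = c("class", rep("feature", 4)),
    states = c(list(c("c0", "c1")), rep(list(c("a", "b")), 4))
  ))
  # one record per full configuration of one class: everything independent,
  # all CMI weights exactly 0
  grid <- expand.grid(
    C = "c0", Fb = c("a", "b"), Fa = c("a", "b"), Fc = c("a", "b"),
    Fd = c("a", "b"), stringsAsFactors = FALSE
  )
  st <- count_statistics(station_data(grid, schema, "S"))
  s1 <- learn_tan_structure(st)
  s2 <- learn_tan_structure(st)
  expect_identical(s1$edges, s2$edges)
  expect_true(all(s1$edges$weight == 0))
  # Kruskal takes ties lexicographically: Fa -- Fb, Fa -- Fc, Fa -- Fd,
  # i.e. a star centred on the lexicographically first feature
  expect_identical(
    fedtan:::tan_undirected_edges(s1),
    c("Fa -- Fb", "Fa -- Fc", "Fa -- Fd")
  )
  # root stays the first feature in canonical schema order
  expect_equal(s1$root, "Fb")
})

test_that("fewer than two features is a hard error", {
  schema <- toy_schema(1, 2, 2)
  st <- count_statistics(random_station(schema, 10, 1))
  expect_error(learn_tan_structure(st), "naive Bayes")
})

test_that("Dirichlet fitting matches the closed form", {
  schema <- toy_schema(2, 2, 2)
  # class counts (3, 1): with iss -> 0 the prior is the MLE (0.75, 0.25)
  ds <- station_data(
    tibble::tibble(
      C = c("c0", "c0", "c0", "c1"),
      F1 = c("a", "a", "b", "a"), F2 = c("a", "b", "a", "a")
    ),
    schema, "S"
  )
  st <- count_statistics(ds)
  struct <- learn_tan_structure(st)
  mle <- fit_tan(st, struct, iss = 0)
  expect_equal(unname(mle$class_prior), c(0.75, 0.25))

  # counts (2, 0), r = 2, q = 1, iss = 1 -> (2.5/3, 0.5/3); the class
  # prior has q = 1, so engineer class counts (2, 0)
  ds2 <- station_data(
    tibble::tibble(C = c("c0", "c0"), F1 = c("a", "b"), F2 = c("a", "a")),
    schema, "S"
  )
  st2 <- count_statistics(ds2)
  m2 <- fit_tan(st2, learn_tan_structure(st2), iss = 1)
  expect_equal(unname(m2$class_prior), c(2.5 / 3, 0.5 / 3))

  # all-zero counts with iss = 1 give the uniform prior
  m0 <- fit_tan(empty_statistics(schema), struct, iss = 1)
  expect_equal(unname(m0$class_prior), c(0.5, 0.5))
  expect_true(all(abs(m0$cpts$F1 - 0.5) < 1e-12))

  # every CPT row normalizes and is strictly positive for iss > 0
  m1 <- fit_tan(st, struct, iss = 1)
  expect_true(all(m1$cpts$F1 > 0))
  expect_equal(colSums(m1$cpts$F1), c(1, 1), ignore_attr = TRUE)
  expect_equal(apply(m1$cpts$F2, c(2, 3), sum),
    matrix(1, 2, 2), ignore_attr = TRUE)
  expect_error(fit_tan(st, struct, iss = -1), "non-negative")
})

test_that("iss interpolates between empirical frequencies and uniform", {
  schema <- toy_schema(2, 2, 2)
  ds <- random_station(schema, 50, seed = 6)
  st <- count_statistics(ds)
  struct <- learn_tan_structure(st)
  small <- fit_tan(st, struct, iss = 1e-9)
  emp <- t(st$single_counts$F1 / rowSums(st$single_counts$F1))
  expect_equal(unname(small$cpts$F1), unname(emp), tolerance = 1e-6)
  huge <- fit_tan(st, struct, iss = 1e9)
  expect_true(all(abs(huge$cpts$F1 - 0.5) < 1e-6))
})

test_that("posteriors equal full-joint enumeration", {
  # hand-specified model: every posterior checked against the explicit
  # joint distribution over all configurations
  model <- toy_chain_model(follow = 0.8, signal = 0.7)
  grid <- expand.grid(
    F1 = c("a", "b"), F2 = c("a", "b"), F3 = c("a", "b"),
    stringsAsFactors = FALSE
  )
  post <- predict(model, grid, type = "prob")
  for (r in seq_len(nrow(grid))) {
    expect_equal(
      unlist(post[r, ]), brute_posterior(model, grid[r, ]),
      tolerance = 1e-12
    )
  }
  # and for a model learned from data
  schema <- toy_schema(3, 2, 2)
  ds <- random_station(schema, 40, seed = 8)
  st <- count_statistics(ds)
  m <- fit_tan(st, learn_tan_structure(st), iss = 1)
  post2 <- predict(m, grid, type = "prob")
  for (r in seq_len(nrow(grid))) {
    expect_equal(
      unlist(post2[r, ]), brute_posterior(m, grid[r, ]),
      tolerance = 1e-10
    )
  }
  expect_identical(
    predict_class(m, grid),
    c("c0", "c1")[max.col(as.matrix(post2), ties.method = "first")]
  )
})

test_that("degenerate posteriors and tie-breaks are deterministic", {
  model <- toy_chain_model()
  # uniform CPTs -> uniform posterior, argmax tie -> first class state
  uniform <- model
  uniform$cpts$F1[] <- 0.5
  uniform$cpts$F2[] <- 0.5
  uniform$cpts$F3[] <- 0.5
  rec <- tibble::tibble(F1 = "a", F2 = "b", F3 = "a")
  expect_equal(unlist(predict(uniform, rec)), c(c0 = 0.5, c1 = 0.5))
  expect_equal(predict_class(uniform, rec), "c0")

  # point-mass prior propagates to a point-mass posterior
  point <- uniform
  point$class_prior <- c(c0 = 0, c1 = 1)
  expect_equal(unlist(predict(point, rec)), c(c0 = 0, c1 = 1))

  expect_error(predict(model, tibble::tibble(F1 = "a", F2 = "b")), "F3")
  expect_error(
    predict(model, tibble::tibble(F1 = "a", F2 = NA, F3 = "b")),
    "complete"
  )
})

test_that("model JSON serialization round-trips predictions", {
  schema <- toy_schema(3, 2, 3)
  ds <- random_station(schema, 60, seed = 10)
  st <- count_statistics(ds)
  m <- fit_tan(st, learn_tan_structure(st), iss = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_tan_model(m, path)
  m2 <- read_tan_model(path)
  grid <- tibble::as_tibble(ds)[1:10, ]
  expect_equal(predict(m, grid), predict(m2, grid), tolerance = 1e-15)
  expect_identical(
    fedtan:::tan_undirected_edges(m$structure),
    fedtan:::tan_undirected_edges(m2$structure)
  )
})

test_that("structure and parameters are recovered from samples", {
  model <- toy_chain_model(follow = 0.9, signal = 0.85)
  truth <- fedtan:::tan_undirected_edges(model$structure)
  ok <- 0L
  for (rep in 1:5) {
    ds <- simulate_tan(model, 5000, seed = 100 + rep)
    st <- count_statistics(ds)
    learned <- fit_tan(st, learn_tan_structure(st), iss = 1)
    if (identical(fedtan:::tan_undirected_edges(learned$structure), truth) &&
      max_cpt_diff(learned, model) <= 0.05) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 4L)
})

test_that("tidy and glance summarize models", {
  schema <- toy_schema(3, 2, 2)
  st <- count_statistics(random_station(schema, 50, seed = 3))
  m <- fit_tan(st, learn_tan_structure(st), iss = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 3 + 2) # class->feature edges + tree edges
  gl <- glance(m)
  expect_equal(gl$n_features, 3)
  expect_equal(gl$root, "F1")
})
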