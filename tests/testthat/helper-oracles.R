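# Fixtures built in code plus independent brute-force oracles used to
# freeze expected values. Oracles are deliberately naive (nested loops,
# exhaustive enumeration) and share no code with the implementation.

toy_schema <- function(n_features = 3, n_states = 2, n_classes = 2) {
  tan_schema(tibble::tibble(
    variable = c("C", paste0("F", seq_len(n_features))),
    role = c("class", rep("feature", n_features)),
    states = c(
      list(paste0("c", seq_len(n_classes) - 1)),
      rep(list(letters[seq_len(n_states)]), n_features)
    )
  ))
}

# random complete dataset conforming to a schema (uniform cell draws)
random_station <- function(schema, n, seed, id = "S") {
  set.seed(seed)
  cols <- lapply(schema$variable, function(v) {
    sample(schema_states(schema, v), n, replace = TRUE)
  })
  names(cols) <- schema$variable
  station_data(tibble::as_tibble(cols), schema, id)
}

# nested-loop contingency tally, the oracle for count_statistics
brute_counts <- function(data, schema, cls, xi, xj) {
  cs <- schema_states(schema, cls)
  si <- schema_states(schema, xi)
  sj <- schema_states(schema, xj)
  out <- array(0L, dim = c(length(cs), length(si), length(sj)))
  for (r in seq_len(nrow(data))) {
    a <- match(data[[cls]][r], cs)
    b <- match(data[[xi]][r], si)
    d <- match(data[[xj]][r], sj)
    out[a, b, d] <- out[a, b, d] + 1L
  }
  out
}

# direct triple-sum CMI from a [class, xi, xj] count tensor
brute_cmi <- function(tab) {
  n <- sum(tab)
  total <- 0
  for (c in seq_len(dim(tab)[1])) {
    n_c <- sum(tab[c, , ])
    for (a in seq_len(dim(tab)[2])) {
      for (b in seq_len(dim(tab)[3])) {
        n_abc <- tab[c, a, b]
        if (n_abc > 0) {
          n_ac <- sum(tab[c, a, ])
          n_bc <- sum(tab[c, , b])
          total <- total + n_abc / n * log(n_abc * n_c / (n_ac * n_bc))
        }
      }
    }
  }
  total
}

# all labeled spanning trees on n nodes via Pruefer sequences (n^(n-2))
all_spanning_trees <- function(n) {
  decode <- function(seq) {
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, nrow = n - 1, ncol = 2)
    k <- 1L
    for (s in seq) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, s)
      k <- k + 1L
      degree[leaf] <- degree[leaf] - 1L
      degree[s] <- degree[s] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  }
  if (n == 2) {
    return(list(matrix(c(1L, 2L), nrow = 1)))
  }
  seqs <- expand.grid(rep(list(seq_len(n)), n - 2))
  lapply(seq_len(nrow(seqs)), function(i) decode(as.integer(seqs[i, ])))
}

# max-weight spanning tree by exhaustive search; weight_of(i, j) scalar
brute_best_tree <- function(n, weight_of) {
  trees <- all_spanning_trees(n)
  weights <- vapply(trees, function(e) {
    sum(vapply(seq_len(nrow(e)), function(k) weight_of(e[k, 1], e[k, 2]), 0.0))
  }, 0.0)
  trees[[which.max(weights)]]
}

# pooled-pair concordance probability with ties counted one half
brute_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# posterior by materializing the full joint over every configuration
brute_posterior <- function(model, record) {
  schema <- model$schema
  classes <- schema_states(schema, class_var(schema))
  feats <- model$structure$features
  grids <- c(
    list(classes),
    lapply(feats, function(f) schema_states(schema, f))
  )
  names(grids) <- c("..class", feats)
  joint <- expand.grid(grids, stringsAsFactors = FALSE)
  joint$p <- vapply(seq_len(nrow(joint)), function(r) {
    ci <- match(joint[["..class"]][r], classes)
    p <- model$class_prior[ci]
    for (f in feats) {
      fi <- match(joint[[f]][r], schema_states(schema, f))
      parent <- model$structure$parent[[f]]
      p <- p * if (is.null(parent)) {
        model$cpts[[f]][fi, ci]
      } else {
        model$cpts[[f]][fi, ci, match(
          joint[[parent]][r], schema_states(schema, parent)
        )]
      }
    }
    unname(p)
  }, 0.0)
  stopifnot(abs(sum(joint$p) - 1) < 1e-9) # the joint is a distribution
  keep <- rep(TRUE, nrow(joint))
  for (f in feats) keep <- keep & joint[[f]] == record[[f]]
  slice <- joint[keep, ]
  stats::setNames(
    slice$p[match(classes, slice[["..class"]])] / sum(slice$p), classes
  )
}

# hand-buildable TAN model over toy_schema(3, 2, 2): chain F1 -> F2 -> F3
# with strong dependence along every tree edge
toy_chain_model <- function(follow = 0.9, signal = 0.85, iss = 1) {
  schema <- toy_schema(3, 2, 2)
  feats <- c("F1", "F2", "F3")
  edges <- tibble::tibble(
    from = c("F1", "F2"), to = c("F2", "F3"), weight = NA_real_
  )
  struct <- structure(
    list(
      class_var = "C", features = feats, root = "F1", edges = edges,
      parent = list(F1 = NULL, F2 = "F1", F3 = "F2")
    ),
    class = "tan_structure"
  )
  # F1 tracks the class; F2 and F3 copy their parent with prob `follow`
  cpt_root <- matrix(c(signal, 1 - signal, 1 - signal, signal), nrow = 2)
  cpt_follow <- array(0, dim = c(2, 2, 2))
  for (ci in 1:2) {
    cpt_follow[, ci, 1] <- c(follow, 1 - follow)
    cpt_follow[, ci, 2] <- c(1 - follow, follow)
  }
  structure(
    list(
      structure = struct, schema = schema, iss = iss,
      class_prior = c(c0 = 0.5, c1 = 0.5),
      cpts = list(F1 = cpt_root, F2 = cpt_follow, F3 = cpt_follow)
    ),
    class = "tan_model"
  )
}

max_cpt_diff <- function(m1, m2) {
  stopifnot(identical(names(m1$cpts), names(m2$cpts)))
  max(c(
    abs(m1$class_prior - m2$class_prior),
    unlist(lapply(names(m1$cpts), function(v) {
      abs(m1$cpts[[v]] - m2$cpts[[v]])
    }))
  ))
}

# split a dataset's rows into k stations at given break proportions
partition_station <- function(data, k, seed) {
  set.seed(seed)
  assign_to <- sample(rep_len(seq_len(k), nrow(data)))
  schema <- schema_of(data)
  lapply(seq_len(k), function(i) {
    station_data(
      tibble::as_tibble(data)[assign_to == i, , drop = FALSE],
      schema, paste0("part-", i)
    )
  })
}
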