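#' Confusion matrix and one-vs-rest class rates
#'
#' Tabulates observed (rows) against predicted (columns) labels over a
#' fixed class-state order and derives per-class one-vs-rest rates:
#' sensitivity `TP / (TP + FN)` and specificity `TN / (TN + FP)`. A class
#' never observed in the test labels has undefined sensitivity; it is
#' flagged (`observed = FALSE`) and excluded from the unweighted
#' averages.
#'
#' @param observed,predicted Equal-length character vectors of class
#'   labels, all contained in `classes`.
#' @param classes Class-state order (the model's harmonized class space).
#' @return A list with `confusion` (integer matrix), `rates` (tibble:
#'   `class`, `sensitivity`, `specificity`, `support`, `observed`),
#'   `avg_sensitivity`, `avg_specificity`.
#' @export
confusion_and_rates <- function(observed, predicted, classes) {
  if (length(observed) == 0) rlang::abort("no labels to evaluate")
  stopifnot(length(observed) == length(predicted))
  if (!all(c(observed, predicted) %in% classes)) {
    rlang::abort("labels outside the declared class states")
  }
  obs_f <- factor(observed, levels = classes)
  pred_f <- factor(predicted, levels = classes)
  confusion <- unclass(table(obs_f, pred_f, dnn = NULL))
  dimnames(confusion) <- list(observed = classes, predicted = classes)
  n <- length(observed)
  rates <- tibble::tibble(
    class = classes,
    support = as.integer(rowSums(confusion)),
    tp = unname(diag(confusion)),
    fn = unname(rowSums(confusion) - diag(confusion)),
    fp = unname(colSums(confusion) - diag(confusion))
  ) |>
    dplyr::mutate(
      tn = n - .data$tp - .data$fn - .data$fp,
      observed = .data$support > 0,
      sensitivity = ifelse(.data$observed,
        .data$tp / (.data$tp + .data$fn), NA_real_
      ),
      specificity = .data$tn / (.data$tn + .data$fp)
    ) |>
    dplyr::select(
      "class", "sensitivity", "specificity", "support", "observed"
    )
  list(
    confusion = confusion,
    rates = rates,
    avg_sensitivity = mean(rates$sensitivity[rates$observed]),
    avg_specificity = mean(rates$specificity[rates$observed])
  )
}

#' Micro-average ROC curve and AUC
#'
#' One-vs-rest binarization pooled over every (record, class) pair: each
#' pair contributes a binary label (is this the observed class?) and the
#' model's posterior score for that class. Thresholds sweep the distinct
#' pooled scores in descending order with ties grouped, so records whose
#' scores tie move together; the area is the trapezoidal rule over the
#' resulting staircase, which equals the concordance probability with
#' ties counted one half. Classes the model knows but the test set never
#' shows contribute negative pairs only.
#'
#' @param observed Character vector of observed class labels.
#' @param scores Data frame or matrix of per-record class posteriors, one
#'   column per class in `classes` order; rows must sum to 1 within 1e-6.
#' @param classes Class-state order.
#' @return A `roc_curve`: tibble of `fpr`, `tpr` points from (0,0) to
#'   (1,1) with the AUC in `attr(, "auc")` (also via [glance()]).
#' @export
micro_average_roc <- function(observed, scores, classes) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(observed), ncol(scores) == length(classes))
  if (any(abs(rowSums(scores) - 1) > 1e-6)) {
    rlang::abort("posterior rows must sum to 1")
  }
  if (!all(observed %in% classes)) {
    rlang::abort("observed labels outside the declared class states")
  }
  y <- as.integer(rep(classes, each = length(observed)) == observed)
  if (all(y == 1) || all(y == 0)) {
    rlang::abort("pooled binarization needs both positives and negatives")
  }
  s <- as.numeric(scores)
  ord <- order(-s)
  y <- y[ord]
  s <- s[ord]
  grp <- cumsum(!duplicated(s)) # ties share a threshold group
  # cumulative counts at the END of each tie group
  last_of_group <- which(diff(c(grp, max(grp) + 1L)) > 0)
  tp <- cumsum(y)[last_of_group]
  fp <- last_of_group - tp
  pos <- sum(y)
  neg <- length(y) - pos
  curve <- tibble::tibble(
    fpr = c(0, fp / neg),
    tpr = c(0, tp / pos)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
    utils::tail(curve$tpr, -1)) / 2)
  tibble::new_tibble(curve, auc = auc, class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(
    "<roc_curve> micro-average, ", nrow(x), " points, AUC = ",
    format(attr(x, "auc"), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname micro_average_roc
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::glance
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_points = nrow(x))
}

#' Plot a micro-average ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$fpr, y = .data$tpr)
  ) +
    ggplot2::geom_abline(
      intercept = 0, slope = 1, linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_step(colour = "#d55e00", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf(
        "Micro-average ROC curve (area = %.2f)", attr(object, "auc")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Evaluate a TAN model on a test dataset
#'
#' Applies [predict.tan_model()] to every test record and assembles the
#' confusion matrix, per-class and average one-vs-rest sensitivity and
#' specificity, and the micro-average ROC/AUC over the model's class
#' space (a class the model knows but the test set lacks contributes
#' negatives only).
#'
#' @param model A `tan_model`.
#' @param test A [station_data()] conforming to the model's schema.
#' @return A `tan_evaluation`: list with `confusion`, `rates`, `roc`,
#'   `auc`, `avg_sensitivity`, `avg_specificity`, `n_test`, `model_id`,
#'   `test_id`. [glance()] gives the one-row summary.
#' @export
evaluate_model <- function(model, test) {
  if (nrow(test) == 0) rlang::abort("cannot evaluate on an empty test set")
  classes <- schema_states(model$schema, class_var(model$schema))
  observed <- test[[class_var(model$schema)]]
  post <- predict(model, test, type = "prob")
  predicted <- classes[apply(as.matrix(post), 1, which.max)]
  cr <- confusion_and_rates(observed, predicted, classes)
  roc <- micro_average_roc(observed, post, classes)
  structure(
    list(
      confusion = cr$confusion, rates = cr$rates, roc = roc,
      auc = attr(roc, "auc"),
      avg_sensitivity = cr$avg_sensitivity,
      avg_specificity = cr$avg_specificity,
      n_test = nrow(test),
      model_id = paste0("tan-", model$structure$root, "-iss", model$iss),
      test_id = station_id(test) %||% "test"
    ),
    class = "tan_evaluation"
  )
}

#' @export
print.tan_evaluation <- function(x, ...) {
  cat(
    "<tan_evaluation> n = ", x$n_test,
    sprintf(
      ": AUC %.3f, avg sensitivity %.3f, avg specificity %.3f\n",
      x$auc, x$avg_sensitivity, x$avg_specificity
    ),
    sep = ""
  )
  invisible(x)
}

#' @rdname evaluate_model
#' @param x A `tan_evaluation`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::glance
glance.tan_evaluation <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    avg_sensitivity = x$avg_sensitivity,
    avg_specificity = x$avg_specificity,
    n_test = x$n_test
  )
}

#' @rdname evaluate_model
#' @export
#' @exportS3Method generics::tidy
tidy.tan_evaluation <- function(x, ...) x$rates
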