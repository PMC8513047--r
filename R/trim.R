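#' Neuron trimming: hidden-layer size selection with overfit checks
#'
#' Trains one network per (hidden-neuron count, seed) combination, evaluates
#' training and testing stages, and flags configurations that violate the
#' no-overfit rule: the training MSE must not exceed the testing MSE
#' (`"underfit-suspect"` otherwise), and testing accuracy must lie within 10
#' percentage points of training accuracy (`"overfit-suspect"` otherwise).
#' The recommended configuration is the flag-free one with the highest
#' overall (count-weighted) accuracy.
#'
#' @param table Labeled feature data.frame.
#' @param neuron_counts Hidden-layer sizes to try (default `c(10, 7, 5, 3)`).
#' @param seeds Seeds per size, giving the replicate retrainings.
#' @param train_fraction Split fraction (default 0.7).
#' @param control See [grain_net_control()].
#' @return Object of class `trim_report`: data.frame `results` (one row per
#'   configuration with accuracies, MSEs and flags) plus `recommended`, the
#'   row index of the recommended configuration (NA if all are flagged).
#' @export
trim_neurons <- function(table, neuron_counts = c(10, 7, 5, 3),
                         seeds = c(1, 2), train_fraction = 0.7,
                         control = grain_net_control()) {
  if (length(neuron_counts) == 0) stop("neuron_counts must be non-empty")
  rows <- list()
  for (nh in neuron_counts) for (s in seeds) {
    sp <- split_dataset(table, train_fraction, seed = s)
    model <- grain_net(class_id ~ ., sp$train, n_hidden = nh, seed = s,
                       control = control)
    tr <- evaluate_model(model, sp$train, "training")
    te <- evaluate_model(model, sp$test, "testing")
    flags <- character(0)
    if (tr$mse > te$mse) flags <- c(flags, "underfit-suspect")
    if (tr$accuracy - te$accuracy > 10) flags <- c(flags, "overfit-suspect")
    rows[[length(rows) + 1L]] <- data.frame(
      n_hidden = nh, seed = s,
      train_accuracy = tr$accuracy, test_accuracy = te$accuracy,
      train_mse = tr$mse, test_mse = te$mse,
      overall_accuracy = overall_accuracy(c(tr$n, te$n),
                                          c(tr$accuracy, te$accuracy)),
      flags = paste(flags, collapse = ";"))
  }
  results <- do.call(rbind, rows)
  clean <- which(results$flags == "")
  recommended <- if (length(clean)) clean[which.max(results$overall_accuracy[clean])]
                 else NA_integer_
  structure(list(results = results, recommended = recommended),
            class = "trim_report")
}

#' @export
print.trim_report <- function(x, ...) {
  print(x$results, row.names = FALSE)
  if (!is.na(x$recommended))
    cat(sprintf("recommended: %d hidden neurons (seed %d), overall %.1f%%\n",
                x$results$n_hidden[x$recommended], x$results$seed[x$recommended],
                x$results$overall_accuracy[x$recommended]))
  else cat("no flag-free configuration\n")
  invisible(x)
}

#' Retrain a model on the union of an old and a new dataset
#'
#' Concatenates both tables (schemas must match), applies the standard
#' random split, and trains from scratch on the combined training set — the
#' route by which a model fitted under one imaging condition is extended to
#' a second condition. Warm-starting from the old model's weights is
#' available but off by default.
#'
#' @param old_table,new_table Labeled feature data.frames with identical
#'   column sets (`new_table` may be empty).
#' @param n_hidden Hidden-layer size (default 10).
#' @param seed Integer seed for the split and initialization.
#' @param train_fraction Split fraction (default 0.7).
#' @param control See [grain_net_control()].
#' @return List with `model` (`grain_net`) and `reports` (training, testing
#'   and overall `eval_report`s on the combined data).
#' @export
retrain_model <- function(old_table, new_table, n_hidden = 10, seed = NULL,
                          train_fraction = 0.7,
                          control = grain_net_control()) {
  if (nrow(new_table) > 0 && !identical(sort(names(old_table)), sort(names(new_table))))
    stop("schema mismatch between old and new tables")
  combined <- if (nrow(new_table) > 0)
    rbind(old_table, new_table[names(old_table)]) else old_table
  sp <- split_dataset(combined, train_fraction, seed = seed)
  model <- grain_net(class_id ~ ., sp$train, n_hidden = n_hidden, seed = seed,
                     control = control)
  tr <- evaluate_model(model, sp$train, "training")
  te <- evaluate_model(model, sp$test, "testing")
  ov <- evaluate_model(model, combined, "overall")
  list(model = model, reports = list(training = tr, testing = te, overall = ov))
}
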