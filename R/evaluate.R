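# Evaluation: 70/30 splits, accuracy/MSE/confusion/ROC reports, and the
# aggregation rules used for overall and deployment summaries.

#' Randomly split a labeled feature table into training and testing sets
#'
#' Unstratified random partition; the training set receives
#' `floor(train_fraction * N)` rows. Deterministic for a fixed seed. A
#' stratified variant (per-class floors) is available via `stratify`.
#'
#' @param table Labeled feature data.frame.
#' @param train_fraction Proportion in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @param stratify Split within each class instead of globally.
#' @return List with elements `train` and `test`.
#' @examples
#' tab <- sample_feature_table(read_class_specs(), 10, seed = 1)
#' sp <- split_dataset(tab, 0.7, seed = 1)
#' nrow(sp$train)  # floor(0.7 * 150) = 105
#' @export
split_dataset <- function(table, train_fraction = 0.7, seed = NULL,
                          stratify = FALSE) {
  if (nrow(table) == 0) stop("cannot split an empty table")
  stopifnot(train_fraction > 0, train_fraction < 1)
  with_seed(seed, {
    if (stratify) {
      idx <- unlist(lapply(split(seq_len(nrow(table)), table$class_id),
                           function(i) sample(i, floor(train_fraction * length(i)))))
    } else {
      idx <- sample(seq_len(nrow(table)), floor(train_fraction * nrow(table)))
    }
    list(train = table[sort(idx), , drop = FALSE],
         test = table[setdiff(seq_len(nrow(table)), idx), , drop = FALSE])
  })
}

#' Evaluate a fitted network on a labeled table
#'
#' @param model A `grain_net`.
#' @param table Labeled feature data.frame (must contain `class_id`).
#' @param stage Stage name for the report (`"training"`, `"testing"`,
#'   `"overall"`, `"deployment"`, or free text).
#' @return Object of class `eval_report`: `stage`, `n`, `accuracy` and
#'   `error` in percent (summing to 100), `mse` (mean squared difference
#'   between score vectors and one-hot targets over all rows and classes),
#'   `confusion` (K x K count matrix, rows = true class), and `roc`
#'   (per-class data.frames of monotone (fpr, tpr) points).
#' @export
evaluate_model <- function(model, table, stage = "testing") {
  if (!"class_id" %in% names(table)) stop("table has no class_id labels")
  scores <- predict(model, table, type = "scores")
  pred <- model$classes[apply(scores, 1, which.max)]
  truth <- table$class_id
  K <- length(model$classes)
  Tmat <- outer(truth, model$classes, `==`) * 1
  acc <- 100 * mean(pred == truth)
  confusion <- base::table(factor(truth, levels = model$classes),
                           factor(pred, levels = model$classes))
  dimnames(confusion) <- list(true = as.character(model$classes),
                              predicted = as.character(model$classes))
  roc <- lapply(seq_len(K), function(k) roc_points(scores[, k], Tmat[, k]))
  names(roc) <- as.character(model$classes)
  structure(list(stage = stage, n = nrow(table), accuracy = acc,
                 error = 100 - acc, mse = mean((scores - Tmat)^2),
                 confusion = unclass(confusion), roc = roc),
            class = "eval_report")
}

# one-vs-rest ROC: thresholds swept over the sorted scores; points are
# cumulative and therefore monotone in both coordinates, from (0,0) to (1,1)
roc_points <- function(score, positive) {
  o <- order(score, decreasing = TRUE)
  tp <- cumsum(positive[o] == 1)
  fp <- cumsum(positive[o] == 0)
  np <- sum(positive == 1); nn <- sum(positive == 0)
  # collapse threshold ties: keep the last point of each distinct score
  keep <- c(diff(score[o]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / max(nn, 1)),
             tpr = c(0, tp[keep] / max(np, 1)))
}

#' Area under a per-class ROC curve
#' @param roc Data.frame of (fpr, tpr) points from an `eval_report`.
#' @return AUC by trapezoidal integration.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%-10s n = %-6d accuracy %.1f%%  error %.1f%%  MSE %.4f\n",
              x$stage, x$n, x$accuracy, x$error, x$mse))
  invisible(x)
}

#' Count-weighted overall accuracy of several evaluation stages
#'
#' The overall stage of a report combines training and testing by weighting
#' each stage's accuracy with its sample count.
#'
#' @param n Vector of per-stage sample counts.
#' @param accuracy Vector of per-stage accuracies (percent).
#' @return Overall accuracy in percent.
#' @examples
#' overall_accuracy(c(6887, 2952), c(91.6, 88.5))  # 90.67
#' @export
overall_accuracy <- function(n, accuracy) {
  stopifnot(length(n) == length(accuracy))
  sum(n * accuracy) / sum(n)
}

#' Mean deployment accuracy over per-class accuracies
#'
#' The deployment summary row is the unweighted arithmetic mean of the
#' per-class accuracies.
#'
#' @param per_class Numeric vector of per-class accuracies (percent).
#' @return Mean accuracy in percent.
#' @export
deployment_mean <- function(per_class) mean(per_class)

#' Write an evaluation report set as CSV and JSON
#'
#' @param reports List of `eval_report` objects.
#' @param csv_path Stage-summary CSV path (stage, n, accuracy, error, mse).
#' @param json_path Optional JSON path including confusion matrices.
#' @param roc_csv_path Optional CSV of all per-class ROC points.
#' @return Invisibly, the paths written.
#' @export
write_eval_reports <- function(reports, csv_path, json_path = NULL,
                               roc_csv_path = NULL) {
  summ <- do.call(rbind, lapply(reports, function(r)
    data.frame(stage = r$stage, n = r$n, accuracy = r$accuracy,
               error = r$error, mse = r$mse)))
  write.csv(summ, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(lapply(reports, function(r)
      list(stage = r$stage, n = r$n, accuracy = r$accuracy, error = r$error,
           mse = r$mse, confusion = r$confusion)),
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_csv_path)) {
    roc <- do.call(rbind, unlist(lapply(reports, function(r)
      lapply(names(r$roc), function(k)
        cbind(stage = r$stage, class_id = k, r$roc[[k]]))), recursive = FALSE))
    write.csv(roc, roc_csv_path, row.names = FALSE)
  }
  invisible(c(csv_path, json_path, roc_csv_path))
}
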