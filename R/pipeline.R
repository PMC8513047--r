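# End-to-end orchestration: images in, feature tables / models / decision
# images and reports out.

#' Segment and extract features from a batch of images
#'
#' Runs segmentation and descriptor extraction per image and combines the
#' results into one table with an `image_id` column. APIdx is normalized
#' per image. Unreadable files are reported and skipped; the run continues.
#'
#' @param image_paths Character vector of PNG paths, or a list of
#'   `grain_scene` objects.
#' @param polarity,min_area,h_frac Segmentation options, see
#'   [label_grains()].
#' @param out_csv Optional CSV output path for the combined table.
#' @return Combined feature data.frame with `image_id` first; attribute
#'   `failures` lists files that could not be processed.
#' @export
run_extract <- function(image_paths, polarity = "auto", min_area = 50,
                        h_frac = 0.3, out_csv = NULL) {
  tabs <- list(); failures <- character(0)
  for (i in seq_along(image_paths)) {
    item <- if (is.list(image_paths)) image_paths[[i]] else image_paths[i]
    id <- if (is.character(item)) basename(item) else sprintf("scene_%03d", i)
    tab <- tryCatch({
      img <- if (is.character(item)) png::readPNG(item)
             else if (inherits(item, "grain_scene")) item$image
             else item
      lr <- label_grains(img, polarity = polarity, min_area = min_area,
                         h_frac = h_frac)
      extract_features(img, lr)
    }, error = function(e) {
      failures <<- c(failures, paste0(id, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(tab) && nrow(tab)) tabs[[length(tabs) + 1L]] <- cbind(image_id = id, tab)
  }
  out <- if (length(tabs)) do.call(rbind, tabs)
         else data.frame(image_id = character(0))
  if (length(failures))
    message("run_extract: ", length(failures), " file(s) failed:\n  ",
            paste(failures, collapse = "\n  "))
  if (!is.null(out_csv)) write_feature_table(out, out_csv)
  structure(out, failures = failures)
}

#' Train and evaluate a classifier from a labeled feature table
#'
#' Splits the table 70/30 (by default), optionally runs the neuron-trimming
#' sweep first, trains the Bayesian-regularized network, and evaluates
#' training, testing and overall stages.
#'
#' @param feature_table Labeled feature data.frame (`class_id` required).
#' @param n_hidden Hidden neurons (default 10); ignored when `trim = TRUE`,
#'   where the recommended trimmed size is used.
#' @param seed Integer seed (split + initialization).
#' @param trim Run [trim_neurons()] first and adopt its recommendation.
#' @param train_fraction Split fraction (default 0.7).
#' @param control See [grain_net_control()].
#' @param model_path Optional JSON path for the fitted model.
#' @param report_csv Optional CSV path for the stage report.
#' @return List: `model`, `reports` (training/testing/overall
#'   `eval_report`s), and `trim` (a `trim_report` or NULL).
#' @export
run_train <- function(feature_table, n_hidden = 10, seed = NULL, trim = FALSE,
                      train_fraction = 0.7, control = grain_net_control(),
                      model_path = NULL, report_csv = NULL) {
  if (length(unique(feature_table$class_id)) < 2)
    stop("need at least 2 classes to train")
  trim_rep <- NULL
  if (trim) {
    trim_rep <- trim_neurons(feature_table, seeds = seed %||% 1,
                             train_fraction = train_fraction, control = control)
    if (!is.na(trim_rep$recommended))
      n_hidden <- trim_rep$results$n_hidden[trim_rep$recommended]
  }
  sp <- split_dataset(feature_table, train_fraction, seed = seed)
  model <- grain_net(class_id ~ ., sp$train[c(FEATURE_NAMES, "class_id")],
                     n_hidden = n_hidden, seed = seed, control = control)
  reports <- list(training = evaluate_model(model, sp$train, "training"),
                  testing = evaluate_model(model, sp$test, "testing"),
                  overall = evaluate_model(model, feature_table, "overall"))
  if (!is.null(model_path)) write_grain_net(model, model_path)
  if (!is.null(report_csv)) write_eval_reports(reports, report_csv)
  list(model = model, reports = reports, trim = trim_rep)
}

#' Deploy a model on one image: segment, extract, classify, annotate
#'
#' @param image A PNG path, a `grain_scene`, or an RGB array.
#' @param model A `grain_net` or the path of a model JSON.
#' @param truth Optional ground truth: either a `grain_scene` truth
#'   data.frame (grains matched to detections by nearest centroid) or a
#'   vector of true class ids in detection order.
#' @param polarity,min_area,h_frac Segmentation options.
#' @param annotated_path Optional PNG path for the decision image.
#' @return Object of class `deployment_result`: `predictions` (grain_id,
#'   centroid, predicted class and score), `annotated_image` (RGB array
#'   with class ids drawn at grain centroids), and — when truth is given —
#'   `per_class_accuracy` and `mean_accuracy` (arithmetic mean of the
#'   per-class values).
#' @export
run_deploy <- function(image, model, truth = NULL, polarity = "auto",
                       min_area = 50, h_frac = 0.3, annotated_path = NULL) {
  if (is.character(model)) model <- read_grain_net(model)
  truth_df <- NULL
  if (inherits(image, "grain_scene")) {
    truth_df <- image$truth
    image <- image$image
  } else if (is.character(image)) {
    image <- png::readPNG(image)
  }
  if (is.data.frame(truth)) truth_df <- truth
  lr <- label_grains(image, polarity = polarity, min_area = min_area,
                     h_frac = h_frac)
  if (lr$n_grains == 0) {
    warning("no grains detected")
    return(structure(list(predictions = data.frame(), annotated_image = image,
                          per_class_accuracy = NULL, mean_accuracy = NA_real_),
                     class = "deployment_result"))
  }
  feats <- extract_features(image, lr)
  scores <- predict(model, feats[FEATURE_NAMES], type = "scores")
  pred <- model$classes[apply(scores, 1, which.max)]
  cents <- t(vapply(seq_len(lr$n_grains), function(k) {
    px <- which(lr$labels == k, arr.ind = TRUE)
    colMeans(px)
  }, numeric(2)))
  predictions <- data.frame(grain_id = feats$grain_id,
                            row = cents[, 1], col = cents[, 2],
                            class_id = pred,
                            score = scores[cbind(seq_len(nrow(scores)),
                                                 match(pred, model$classes))])
  # resolve true classes
  true_class <- NULL
  if (!is.null(truth_df) && nrow(truth_df)) {
    true_class <- vapply(seq_len(nrow(predictions)), function(i) {
      d2 <- (truth_df$row - predictions$row[i])^2 +
            (truth_df$col - predictions$col[i])^2
      truth_df$class_id[which.min(d2)]
    }, numeric(1))
  } else if (!is.null(truth) && !is.data.frame(truth)) {
    true_class <- truth
  }
  per_class <- NULL; mean_acc <- NA_real_
  if (!is.null(true_class)) {
    predictions$true_class_id <- true_class
    correct <- predictions$class_id == true_class
    per_class <- 100 * vapply(split(correct, true_class), mean, numeric(1))
    mean_acc <- deployment_mean(per_class)
  }
  annotated <- annotate_decision_image(image, predictions)
  if (!is.null(annotated_path)) png::writePNG(annotated, annotated_path)
  structure(list(predictions = predictions, annotated_image = annotated,
                 per_class_accuracy = per_class, mean_accuracy = mean_acc,
                 n_grains = lr$n_grains),
            class = "deployment_result")
}

#' @export
print.deployment_result <- function(x, ...) {
  cat(sprintf("deployment_result: %d grains classified\n",
              nrow(x$predictions)))
  if (!is.null(x$per_class_accuracy)) {
    for (k in names(x$per_class_accuracy))
      cat(sprintf("  class %-3s %.1f%%\n", k, x$per_class_accuracy[k]))
    cat(sprintf("  mean accuracy %.1f%%\n", x$mean_accuracy))
  }
  invisible(x)
}

# --- decision-image annotation: tiny 3x5 digit font drawn at centroids ---

digit_font <- function() {
  rows <- c("111101101101111", "010110010010111", "111001111100111",
            "111001111001111", "101101111001001", "111100111001111",
            "111100111101111", "111001001001001", "111101111101111",
            "111101111001111")
  lapply(rows, function(r) matrix(as.integer(strsplit(r, "")[[1]]) == 1,
                                  5, 3, byrow = TRUE))
}

#' Draw predicted class ids onto an image at grain centroids
#'
#' @param image RGB array in \[0,1\].
#' @param predictions Data.frame with `row`, `col`, `class_id`.
#' @param scale Integer pixel scale of the 3x5 digit glyphs (default 2).
#' @param color RGB triple for the text (default red).
#' @return The annotated RGB array.
#' @export
annotate_decision_image <- function(image, predictions, scale = 2,
                                    color = c(1, 0.1, 0.1)) {
  font <- digit_font()
  H <- dim(image)[1]; W <- dim(image)[2]
  for (i in seq_len(nrow(predictions))) {
    digits <- strsplit(as.character(predictions$class_id[i]), "")[[1]]
    x0 <- round(predictions$col[i]) - (length(digits) * 4 * scale) %/% 2
    y0 <- round(predictions$row[i]) - (5 * scale) %/% 2
    for (d in seq_along(digits)) {
      glyph <- font[[as.integer(digits[d]) + 1L]]
      px <- which(glyph, arr.ind = TRUE)
      for (s1 in seq_len(scale)) for (s2 in seq_len(scale)) {
        rr <- y0 + (px[, 1] - 1) * scale + s1
        cc <- x0 + (d - 1) * 4 * scale + (px[, 2] - 1) * scale + s2
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        for (ch in 1:3) image[cbind(rr[ok], cc[ok], ch)] <- color[ch]
      }
    }
  }
  image
}

#' Render a batch of scenes with manifest logging
#'
#' Thin wrapper over [render_grain_scene()] that writes each scene as PNG
#' plus truth sidecar, extracts an aggregate truth-label feature table by
#' direct sampling if requested, and writes a manifest listing every file
#' with its seed and MD5 hash. Deterministic per seed.
#'
#' @param config List with elements `n_images`, `n_per_class`,
#'   `image_size`, `touching_fraction`, `seed`, and optionally `classes`
#'   (indices into the default catalogue) and `specs_path`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data.frame (`file`, `seed`, `md5`); also
#'   written to `manifest.json` in `out_dir`.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- if (!is.null(config$specs_path)) read_class_specs(config$specs_path)
           else read_class_specs()
  if (!is.null(config$classes)) specs <- structure(specs[config$classes],
                                                   class = "class_specs")
  n_images <- config$n_images %||% 1
  manifest <- list()
  for (i in seq_len(n_images)) {
    seed_i <- (config$seed %||% 0) + i
    sc <- render_grain_scene(specs,
                             n_per_class = config$n_per_class %||% 10,
                             image_size = unlist(config$image_size %||% c(480, 640)),
                             touching_fraction = config$touching_fraction %||% 0,
                             seed = seed_i)
    png_path <- file.path(out_dir, sprintf("scene_%03d.png", i))
    paths <- write_scene(sc, png_path)
    tab <- cbind(image_id = basename(png_path),
                 sc$truth[c("grain_id", "class_id")],
                 sc$truth[setdiff(names(sc$truth), c("grain_id", "class_id"))])
    truth_csv <- file.path(out_dir, sprintf("scene_%03d.truth.csv", i))
    write.csv(tab, truth_csv, row.names = FALSE)
    for (p in c(paths, truth_csv))
      manifest[[length(manifest) + 1L]] <-
        data.frame(file = basename(p), seed = seed_i,
                   md5 = unname(tools::md5sum(p)))
  }
  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest
}
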