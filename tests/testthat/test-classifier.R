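test_that("dataset splitting reproduces exact 70/30 subset sizes", {
  dummy <- function(n) data.frame(class_id = rep_len(1:15, n), x = seq_len(n))
  sp <- split_dataset(dummy(3839), 0.7, seed = 1)
  expect_equal(nrow(sp$train), 2687)
  expect_equal(nrow(sp$test), 1152)
  sp <- split_dataset(dummy(9839), 0.7, seed = 1)
  expect_equal(nrow(sp$train), 6887)
  expect_equal(nrow(sp$test), 2952)
  sp <- split_dataset(dummy(10), 0.7, seed = 1)
  expect_equal(c(nrow(sp$train), nrow(sp$test)), c(7, 3))

  # deterministic per seed, disjoint and exhaustive
  a <- split_dataset(dummy(100), 0.7, seed = 5)
  b <- split_dataset(dummy(100), 0.7, seed = 5)
  expect_identical(a, b)
  expect_length(intersect(a$train$x, a$test$x), 0)
  expect_setequal(c(a$train$x, a$test$x), 1:100)

  expect_error(split_dataset(dummy(0), 0.7), "empty")
})

test_that("BR trainer separates well-separated classes and obeys the
           evidence-framework bounds", {
  tab <- sample_feature_table(the_specs, 40, seed = 42, sd_scale = 0.15)
  sp <- split_dataset(tab, 0.7, seed = 1)
  fit <- grain_net(class_id ~ ., sp$train, n_hidden = 10, seed = 1,
                   control = test_control)
  expect_s3_class(fit, "grain_net")
  expect_equal(fit$n_weights, 10 * 10 + 15 * 11)

  # monotone objective across accepted LM steps, under the then-current
  # hyperparameters
  expect_true(all(fit$trace$F_new <= fit$trace$F_old))
  # 0 <= gamma <= N_w at every epoch
  expect_true(all(fit$trace$gamma >= 0 & fit$trace$gamma <= fit$n_weights))

  te <- evaluate_model(fit, sp$test, "testing")
  expect_gte(te$accuracy, 95)

  # seed determinism of the whole LM path
  fit2 <- grain_net(class_id ~ ., sp$train, n_hidden = 10, seed = 1,
                    control = test_control)
  expect_identical(coef(fit), coef(fit2))
  fit3 <- grain_net(class_id ~ ., sp$train, n_hidden = 10, seed = 2,
                    control = test_control)
  expect_false(identical(coef(fit), coef(fit3)))
})

test_that("a tiny two-class problem trains to ceiling with 3 neurons", {
  set.seed(3)
  x <- rbind(matrix(rnorm(50 * 9, 0, 1), 50, 9),
             matrix(rnorm(50 * 9, 6, 1), 50, 9))
  tab <- data.frame(x, class_id = rep(1:2, each = 50))
  names(tab)[1:9] <- paste0("f", 1:9)
  fit <- grain_net(class_id ~ ., tab, n_hidden = 3, seed = 1,
                   control = test_control)
  tr <- evaluate_model(fit, tab, "training")
  expect_gte(tr$accuracy, 99)
  expect_gte(fit$gamma, 0)
  expect_lte(fit$gamma, fit$n_weights)
})

test_that("prediction is schema-strict and breaks ties toward low ids", {
  tab <- sample_feature_table(the_specs[1:3], 20, seed = 2, sd_scale = 0.2)
  fit <- grain_net(class_id ~ ., tab, n_hidden = 3, seed = 1,
                   control = test_control)

  expect_error(predict(fit, tab[, -1]), "missing feature")
  extra <- cbind(tab, bogus = 1)
  expect_error(predict(fit, extra), "unknown columns")

  scores <- predict(fit, tab, type = "scores")
  expect_true(all(scores >= 0 & scores <= 1))
  expect_equal(dim(scores), c(60, 3))

  # symmetric degenerate model: all scores equal, lowest class id wins
  tie <- fit
  tie$W2[] <- 0; tie$b2[] <- 0
  expect_true(all(predict(tie, tab) == fit$classes[1]))
})

test_that("evaluation reports accuracy, MSE, confusion and ROC correctly", {
  tab <- sample_feature_table(the_specs, 30, seed = 13, sd_scale = 0.1)
  sp <- split_dataset(tab, 0.7, seed = 3)
  fit <- grain_net(class_id ~ ., sp$train, n_hidden = 10, seed = 3,
                   control = test_control)
  rep <- evaluate_model(fit, sp$test, "testing")

  expect_equal(rep$accuracy + rep$error, 100)
  expect_equal(sum(rep$confusion), nrow(sp$test))
  counts <- as.vector(base::table(factor(sp$test$class_id,
                                         levels = fit$classes)))
  expect_equal(unname(rowSums(rep$confusion)), counts)

  # ROC curves: start (0,0), end (1,1), monotone in both coordinates
  for (r in rep$roc) {
    expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
  }
  # near-perfect separation: per-class AUC ~ 1
  expect_gte(min(vapply(rep$roc, roc_auc, numeric(1))), 0.99)

  expect_error(evaluate_model(fit, sp$test[setdiff(names(sp$test), "class_id")]),
               "class_id")
})

test_that("ROC points agree with an independent implementation", {
  skip_if_not_installed("pROC")
  tab <- sample_feature_table(the_specs[1:4], 25, seed = 9)
  fit <- grain_net(class_id ~ ., tab, n_hidden = 4, seed = 1,
                   control = test_control)
  rep <- evaluate_model(fit, tab, "overall")
  scores <- predict(fit, tab, type = "scores")
  for (k in c(1, 3)) {
    ours <- roc_auc(rep$roc[[as.character(k)]])
    theirs <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(tab$class_id == k, scores[, as.character(k)]))))
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("shuffled labels drop accuracy to chance level", {
  tab <- sample_feature_table(the_specs, 20, seed = 5, sd_scale = 0.3)
  shuffled <- tab
  set.seed(99)
  shuffled$class_id <- sample(shuffled$class_id)
  fit <- grain_net(class_id ~ ., shuffled, n_hidden = 5, seed = 1,
                   control = grain_net_control(max_epochs = 30))
  fresh <- sample_feature_table(the_specs, 20, seed = 6, sd_scale = 0.3)
  set.seed(100)
  fresh$class_id <- sample(fresh$class_id)
  rep <- evaluate_model(fit, fresh, "testing")
  expect_lt(abs(rep$accuracy - 100 / 15), 5)
})

test_that("neuron trimming sweeps the requested sizes and flags overfits", {
  tab <- sample_feature_table(the_specs[1:5], 30, seed = 8, sd_scale = 0.3)
  rep <- trim_neurons(tab, neuron_counts = c(5, 3), seeds = 1,
                      control = test_control)
  expect_s3_class(rep, "trim_report")
  expect_setequal(rep$results$n_hidden, c(5, 3))
  # flags are consistent with the reported statistics
  for (i in seq_len(nrow(rep$results))) {
    r <- rep$results[i, ]
    expect_equal(grepl("underfit-suspect", r$flags), r$train_mse > r$test_mse)
    expect_equal(grepl("overfit-suspect", r$flags),
                 r$train_accuracy - r$test_accuracy > 10)
  }
  if (!is.na(rep$recommended)) {
    expect_equal(rep$results$flags[rep$recommended], "")
    clean <- rep$results$flags == ""
    expect_equal(rep$results$overall_accuracy[rep$recommended],
                 max(rep$results$overall_accuracy[clean]))
  }
  expect_error(trim_neurons(tab, neuron_counts = integer(0)), "non-empty")
})

test_that("retraining unions the datasets and improves cross-condition use", {
  old <- sample_feature_table(the_specs[1:5], 40, seed = 11, sd_scale = 0.25)
  new <- sample_feature_table(the_specs[1:5], 40, seed = 12, sd_scale = 0.25)
  new$L <- new$L + 4   # second imaging condition: a lightness shift
  new$YI <- 142.86 * new$b / new$L

  res <- retrain_model(old, new, n_hidden = 5, seed = 1, control = test_control)
  expect_equal(res$reports$overall$n, 400)
  expect_equal(res$reports$training$n + res$reports$testing$n, 400)

  # empty new data: same fit as training on the old table alone
  res0 <- retrain_model(old, new[0, ], n_hidden = 5, seed = 1,
                        control = test_control)
  sp <- split_dataset(old, 0.7, seed = 1)
  direct <- grain_net(class_id ~ ., sp$train, n_hidden = 5, seed = 1,
                      control = test_control)
  expect_equal(coef(res0$model), coef(direct))

  expect_error(retrain_model(old, data.frame(a = 1)), "schema mismatch")

  # the union model serves the new condition at least as well as the
  # old-only model does
  fresh_new <- sample_feature_table(the_specs[1:5], 30, seed = 13,
                                    sd_scale = 0.25)
  fresh_new$L <- fresh_new$L + 4
  fresh_new$YI <- 142.86 * fresh_new$b / fresh_new$L
  acc_union <- evaluate_model(res$model, fresh_new)$accuracy
  acc_old <- evaluate_model(res0$model, fresh_new)$accuracy
  expect_gte(acc_union, acc_old - 1e-9)
})

test_that("models survive JSON serialization bit-for-bit", {
  tab <- sample_feature_table(the_specs[1:3], 15, seed = 4)
  fit <- grain_net(class_id ~ ., tab, n_hidden = 3, seed = 2,
                   control = test_control)
  f <- tempfile(fileext = ".json")
  write_grain_net(fit, f)
  back <- read_grain_net(f)
  expect_equal(predict(back, tab, type = "scores"),
               predict(fit, tab, type = "scores"), tolerance = 1e-12)
  expect_equal(back$classes, fit$classes)
  expect_error(read_grain_net(system.file("extdata", "rice_classes.json",
                                          package = "grainclass")),
               "not a grainclass network")
})

test_that("the gradient-descent baseline learns separable data", {
  tab <- sample_feature_table(the_specs[1:3], 30, seed = 21, sd_scale = 0.1)
  fit <- grain_net(class_id ~ ., tab, n_hidden = 5, algorithm = "gdm", seed = 1,
                   control = grain_net_control(max_epochs = 300))
  acc <- evaluate_model(fit, tab, "training")$accuracy
  expect_gt(acc, 80)  # clearly above the 33% chance level
})

test_that("degenerate inputs are rejected", {
  tab <- sample_feature_table(the_specs[1:2], 10, seed = 1)
  tab$FD[1] <- NaN
  expect_error(grain_net(class_id ~ ., tab, seed = 1), "non-finite")
  one <- sample_feature_table(the_specs[1], 10, seed = 1)
  expect_error(grain_net(class_id ~ ., one, seed = 1), "at least 2 classes")
  big <- sample_feature_table(the_specs[1:2], 5, seed = 1)
  expect_warning(grain_net(class_id ~ ., big, n_hidden = 20, seed = 1,
                           control = grain_net_control(max_epochs = 3)),
                 "over-parameterized")
})
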