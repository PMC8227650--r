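# small separable segment-feature table: feature shift per label, subjects
# nested (all segments of a subject stay together)
make_features <- function(n_sub = 8, n_ev = 6, shift = 3, seed = 1,
                          prefix = "s") {
  set.seed(seed)
  seg <- tidyr::expand_grid(subject_id = paste0(prefix, seq_len(n_sub)),
                            event = seq_len(n_ev), label = 0:1)
  seg$dataset <- prefix
  for (f in edapain:::feature_names()) {
    seg[[f]] <- rnorm(nrow(seg), sd = 1) +
      seg$label * shift * (f %in% c("mtvsymp_max", "dpheda_mean"))
  }
  seg
}

test_that("metrics follow their definitions with NA for empty denominators", {
  expect_equal(unlist(metrics_from_confusion(5, 5, 0, 0)), c(accuracy = 1,
               sensitivity = 1, specificity = 1))
  expect_equal(unlist(metrics_from_confusion(1, 1, 1, 1)), c(accuracy = 0.5,
               sensitivity = 0.5, specificity = 0.5))
  m <- metrics_from_confusion(0, 3, 2, 0)
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 0.6)
  expect_error(metrics_from_confusion(-1, 0, 0, 0))
})

test_that("classifier grids match the evaluation protocol", {
  expect_equal(classifier_spec("L-SVM")$grid$C, c(1, 10, 100, 1000))
  rsvm <- classifier_spec("R-SVM")$grid
  expect_equal(nrow(rsvm), 12L)
  expect_setequal(unique(rsvm$gamma), c(1e-4, 1e-3, 0.1))
  expect_equal(classifier_spec("KNN")$grid$K, c(3, 5, 7, 9))
  expect_equal(nrow(classifier_spec("MLP")$grid), 81L)
  expect_equal(classifier_spec("MLP")$score, "cross_entropy")
  expect_false(classifier_spec("RandomForest")$standardize)
  expect_true(classifier_spec("L-SVM")$standardize)
  expect_setequal(classifier_spec("DecisionTree")$grid$criterion,
                  c("gini", "entropy"))
})

test_that("grid search returns the single row of a trivial grid, is seeded, and
           recovers separable data", {
  seg <- make_features()
  spec1 <- classifier_spec("KNN")
  spec1$grid <- spec1$grid[2, , drop = FALSE]
  gs <- grid_search_subjectwise(seg, spec1, seed = 1)
  expect_equal(gs$params$K, 5)

  spec <- classifier_spec("KNN")
  g1 <- grid_search_subjectwise(seg, spec, seed = 3)
  g2 <- grid_search_subjectwise(seg, spec, seed = 3)
  expect_identical(g1$params, g2$params)
  expect_gte(g1$score, 0.9)

  few <- dplyr::filter(seg, subject_id %in% paste0("s", 1:3))
  expect_warning(grid_search_subjectwise(few, spec, seed = 1),
                 "leave-one-subject-out")
})

test_that("protocol 1 runs one fold per subject without test-subject leakage", {
  seg <- make_features(n_sub = 8)
  spec <- classifier_spec("LogisticRegression")
  res <- evaluate_protocol1(seg, spec, seed = 2)
  folds <- tidy(res)
  expect_equal(nrow(folds), 8L)
  expect_setequal(folds$subject_id, unique(seg$subject_id))
  expect_gte(res$summary$mean[res$summary$metric == "accuracy"], 0.9)

  # leakage instrumentation: fold for subject s must be reproducible from a
  # pipeline that never sees s (same grid search, same standardizer, same fit)
  s <- folds$subject_id[1]
  train <- dplyr::filter(seg, subject_id != s)
  test <- dplyr::filter(seg, subject_id == s)
  gs <- grid_search_subjectwise(train, spec, seed = 2)
  expect_identical(gs$params, folds$params[[1]])
  d_tr <- edapain:::seg_xy(train); d_te <- edapain:::seg_xy(test)
  sc <- edapain:::standardizer(d_tr$X)
  mod <- edapain:::fit_classifier(spec$family, gs$params, sc$apply(d_tr$X),
                                  d_tr$y, seed = 2)
  pr <- edapain:::predict_classifier(mod, sc$apply(d_te$X))
  cm <- edapain:::confusion(d_te$y, pr$class)
  expect_equal(folds$accuracy[1],
               metrics_from_confusion(cm$tp, cm$tn, cm$fp, cm$fn)$accuracy)

  expect_error(evaluate_protocol1(make_features(n_sub = 4), spec, seed = 1),
               "at least 6")
})

test_that("permuted labels bring protocol-1 accuracy to chance", {
  seg <- make_features(n_sub = 8, seed = 4)
  set.seed(11)
  seg <- seg %>%
    dplyr::group_by(.data$subject_id) %>%
    dplyr::mutate(label = sample(.data$label)) %>%
    dplyr::ungroup()
  res <- evaluate_protocol1(seg, classifier_spec("KNN"), seed = 1)
  acc <- res$summary$mean[res$summary$metric == "accuracy"]
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("cross-dataset evaluation honors symmetry and input contracts", {
  train <- make_features(n_sub = 8, seed = 5, prefix = "tr")
  test <- make_features(n_sub = 5, seed = 6, prefix = "te")
  spec <- classifier_spec("LogisticRegression")
  res <- evaluate_cross_dataset(train, test, spec, seed = 1, n_boot = 200)
  acc <- res$summary$mean[res$summary$metric == "accuracy"]
  expect_gte(acc, 0.9)

  flipped <- dplyr::mutate(test, label = 1L - label)
  res_f <- evaluate_cross_dataset(train, flipped, spec, seed = 1, n_boot = 200)
  acc_f <- res_f$summary$mean[res_f$summary$metric == "accuracy"]
  expect_equal(acc_f, 1 - acc, tolerance = 1e-12)

  expect_error(evaluate_cross_dataset(train, train[0, ], spec), "empty")
  expect_error(evaluate_cross_dataset(train, train, spec), "share subject")
})

test_that("the MLP learns with each solver and honors its options", {
  set.seed(3)
  X <- matrix(rnorm(160 * 4), 160, 4)
  y <- as.integer(X[, 1] + X[, 2] + rnorm(160, 0, 0.3) > 0)
  for (sv in c("lbfgs", "adam", "sgd")) {
    m <- mlp_fit(X, y, hidden_layers = 2, activation = "tanh", solver = sv,
                 learning_rate = 0.01, hidden_units = 20, seed = 1)
    expect_gte(mean(predict(m, X, type = "class") == y), 0.85)
    p <- predict(m, X, type = "prob")
    expect_true(all(p >= 0 & p <= 1))
  }
  m1 <- mlp_fit(X, y, hidden_layers = 1, activation = "relu", solver = "adam",
                learning_rate = 0.01, hidden_units = 10, seed = 7)
  m2 <- mlp_fit(X, y, hidden_layers = 1, activation = "relu", solver = "adam",
                learning_rate = 0.01, hidden_units = 10, seed = 7)
  expect_identical(m1$par, m2$par)
  expect_equal(length(m1$par$W), 2L)  # 1 hidden + output layer
})

test_that("analytic MLP gradients match finite differences", {
  set.seed(4)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- rbinom(20, 1, 0.5)
  sizes <- c(3, 5, 1)
  par <- edapain:::mlp_init(sizes, seed = 2)
  act <- edapain:::mlp_activations[["tanh"]]
  theta <- edapain:::mlp_flatten(par)
  g <- edapain:::mlp_loss_grad(edapain:::mlp_unflatten(theta, sizes), X, y, act)
  ga <- unlist(c(g$gW, g$gb))
  fn <- function(th) edapain:::mlp_loss_grad(
    edapain:::mlp_unflatten(th, sizes), X, y, act)$loss
  idx <- sample(length(theta), 8)
  for (i in idx) {
    e <- numeric(length(theta)); e[i] <- 1e-6
    num <- (fn(theta + e) - fn(theta - e)) / 2e-6
    expect_equal(ga[i], num, tolerance = 1e-5)
  }
})
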