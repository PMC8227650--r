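# Classifier-evaluation harness: subject-wise nested grid search,
# leave-one-subject-out (LOSO) and cross-dataset protocols, and the
# accuracy/sensitivity/specificity metrics. The classifiers themselves come
# from established packages (e1071, rpart, randomForest, class, stats::glm)
# plus the package's own small MLP; this module owns the protocol: splits,
# leakage rules, hyperparameter grids and confidence intervals.

#' Classifier specification with its hyperparameter grid
#'
#' Families and candidate grids follow the evaluation protocol: SVMs with
#' linear, 3rd-order polynomial and RBF kernels (C in 1/10/100/1000, gamma in
#' 1e-4/1e-3/0.1 for kernels that use it), decision tree and random forest
#' (split criterion gini/entropy), an MLP (1-3 hidden layers of 100 units,
#' logistic/tanh/relu, sgd/adam/lbfgs, initial learning rate
#' 1e-4/1e-3/1e-2), logistic regression (solver labels newton-cg, lbfgs,
#' liblinear, sag, saga; all fit the same convex objective, via IRLS here),
#' and KNN (K in 3/5/7/9). Non-tree families are standardized (zero mean,
#' unit variance, statistics fitted on training data only). The random-forest
#' backend supports only the Gini criterion; both grid values map to it.
#'
#' @param family One of `"L-SVM"`, `"P-SVM"`, `"R-SVM"`, `"DecisionTree"`,
#'   `"RandomForest"`, `"MLP"`, `"LogisticRegression"`, `"KNN"`.
#' @return A list of class `classifier_spec` with elements `family`, `grid`
#'   (tibble of candidate hyperparameter rows, in tie-break order),
#'   `standardize`, and `score` (`"accuracy"` maximized, or
#'   `"cross_entropy"` minimized, used for the MLP).
#' @export
classifier_spec <- function(family = c("L-SVM", "P-SVM", "R-SVM",
                                       "DecisionTree", "RandomForest", "MLP",
                                       "LogisticRegression", "KNN")) {
  family <- match.arg(family)
  Cs <- c(1, 10, 100, 1000)
  gammas <- c(1e-4, 1e-3, 0.1)
  grid <- switch(family,
    "L-SVM" = tidyr::expand_grid(C = Cs),
    "P-SVM" = tidyr::expand_grid(C = Cs, gamma = gammas),
    "R-SVM" = tidyr::expand_grid(C = Cs, gamma = gammas),
    "DecisionTree" = tibble(criterion = c("gini", "entropy")),
    "RandomForest" = tibble(criterion = c("gini", "entropy")),
    "MLP" = tidyr::expand_grid(hidden_layers = 1:3,
                               activation = c("logistic", "tanh", "relu"),
                               solver = c("sgd", "adam", "lbfgs"),
                               learning_rate = c(1e-4, 1e-3, 1e-2)),
    "LogisticRegression" = tibble(solver = c("newton-cg", "lbfgs", "liblinear",
                                             "sag", "saga")),
    "KNN" = tibble(K = c(3, 5, 7, 9))
  )
  structure(list(family = family, grid = grid,
                 standardize = !family %in% c("DecisionTree", "RandomForest"),
                 score = if (family == "MLP") "cross_entropy" else "accuracy"),
            class = "classifier_spec")
}

# Fit one classifier; X is a numeric matrix (already standardized when the
# spec asks for it), y is 0/1.
fit_classifier <- function(family, params, X, y, seed = 1L) {
  keep <- .Random.seed_exists(); set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(family,
    "L-SVM" = e1071::svm(X, yf, kernel = "linear", cost = params$C,
                         scale = FALSE),
    "P-SVM" = e1071::svm(X, yf, kernel = "polynomial", degree = 3,
                         cost = params$C, gamma = params$gamma, coef0 = 0,
                         scale = FALSE),
    "R-SVM" = e1071::svm(X, yf, kernel = "radial", cost = params$C,
                         gamma = params$gamma, scale = FALSE),
    "DecisionTree" = {
      d <- data.frame(X, .y = yf)
      rpart::rpart(.y ~ ., d, method = "class",
                   parms = list(split = if (params$criterion == "entropy")
                                  "information" else "gini"))
    },
    "RandomForest" = randomForest::randomForest(X, yf, ntree = 500),
    "MLP" = mlp_fit(X, y, hidden_layers = params$hidden_layers,
                    activation = params$activation, solver = params$solver,
                    learning_rate = params$learning_rate, seed = seed),
    "LogisticRegression" = suppressWarnings(
      glm(y ~ ., data = data.frame(X, y = y), family = binomial())),
    "KNN" = list(X = X, y = yf, K = params$K)
  )
  if (keep$had) assign(".Random.seed", keep$seed, envir = globalenv())
  structure(list(family = family, params = params, fit = fit),
            class = "edapain_clf")
}

# Predict 0/1 classes (and probabilities where the family provides them).
predict_classifier <- function(model, X) {
  f <- model$fit
  switch(model$family,
    "L-SVM" = , "P-SVM" = , "R-SVM" =
      list(class = as.integer(as.character(predict(f, X))), prob = NULL),
    "DecisionTree" = {
      p <- predict(f, data.frame(X), type = "prob")[, "1"]
      list(class = as.integer(p >= 0.5), prob = p)
    },
    "RandomForest" = {
      p <- predict(f, X, type = "prob")[, "1"]
      list(class = as.integer(p >= 0.5), prob = p)
    },
    "MLP" = {
      p <- predict(f, X, type = "prob")
      list(class = as.integer(p >= 0.5), prob = p)
    },
    "LogisticRegression" = {
      p <- suppressWarnings(predict(f, data.frame(X), type = "response"))
      list(class = as.integer(p >= 0.5), prob = as.numeric(p))
    },
    "KNN" = {
      cl <- class::knn(f$X, X, f$y, k = f$K)
      list(class = as.integer(as.character(cl)), prob = NULL)
    }
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`. A zero denominator yields `NA` (undefined), never 0.
#'
#' @param tp,tn,fp,fn Nonnegative confusion counts.
#' @return Tibble with columns `accuracy`, `sensitivity`, `specificity`.
#' @export
metrics_from_confusion <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tot <- tp + tn + fp + fn
  tibble(
    accuracy = if (tot > 0) (tp + tn) / tot else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

confusion <- function(truth, pred) {
  list(tp = sum(truth == 1 & pred == 1), tn = sum(truth == 0 & pred == 0),
       fp = sum(truth == 0 & pred == 1), fn = sum(truth == 1 & pred == 0))
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sig <- apply(X, 2, sd); sig[!is.finite(sig) | sig == 0] <- 1
  list(mu = mu, sig = sig,
       apply = function(Z) sweep(sweep(Z, 2, mu, `-`), 2, sig, `/`))
}

seg_xy <- function(segments) {
  list(X = as.matrix(segments[feature_names()]),
       y = as.integer(segments$label),
       subject = as.character(segments$subject_id))
}

cross_entropy <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Subject-wise grid search
#'
#' Scores every grid row of a [classifier_spec()] by subject-wise inner
#' cross-validation: subjects are shuffled (seeded) and assigned round-robin
#' to 5 folds, all segments of a subject staying together. Standardization is
#' fitted on each inner-training split only. The score is mean validation
#' accuracy (maximized), or mean cross-entropy for the MLP (minimized); ties
#' break toward the earlier grid row. With fewer than 5 training subjects the
#' inner CV falls back to leave-one-subject-out, with a warning.
#'
#' @param train A segment feature table.
#' @param spec A [classifier_spec()].
#' @param seed Seed controlling the fold assignment and stochastic learners.
#' @param inner_folds Number of inner folds (default 5).
#' @return A list: `params` (best grid row), `score`, `scores` (per-row).
#' @export
grid_search_subjectwise <- function(train, spec, seed = 1L, inner_folds = 5L) {
  stopifnot(inherits(spec, "classifier_spec"))
  d <- seg_xy(train)
  subs <- sort(unique(d$subject))
  if (length(subs) < inner_folds) {
    warning("fewer than ", inner_folds,
            " training subjects; using leave-one-subject-out inner CV",
            call. = FALSE)
    inner_folds <- length(subs)
  }
  keep <- .Random.seed_exists(); set.seed(seed)
  shuffled <- sample(subs)
  if (keep$had) assign(".Random.seed", keep$seed, envir = globalenv())
  fold_of <- setNames(rep_len(seq_len(inner_folds), length(shuffled)), shuffled)

  score_row <- function(params) {
    vals <- vapply(seq_len(inner_folds), function(fd) {
      va <- names(fold_of)[fold_of == fd]
      tr_i <- which(!d$subject %in% va); va_i <- which(d$subject %in% va)
      if (!length(va_i) || length(unique(d$y[tr_i])) < 2) return(NA_real_)
      Xtr <- d$X[tr_i, , drop = FALSE]; Xva <- d$X[va_i, , drop = FALSE]
      if (spec$standardize) {
        sc <- standardizer(Xtr); Xtr <- sc$apply(Xtr); Xva <- sc$apply(Xva)
      }
      mod <- fit_classifier(spec$family, params, Xtr, d$y[tr_i], seed = seed)
      pr <- predict_classifier(mod, Xva)
      if (spec$score == "cross_entropy") cross_entropy(d$y[va_i], pr$prob)
      else mean(pr$class == d$y[va_i])
    }, 0)
    mean(vals, na.rm = TRUE)
  }

  scores <- vapply(seq_len(nrow(spec$grid)), function(i)
    score_row(spec$grid[i, , drop = FALSE]), 0)
  best <- if (spec$score == "cross_entropy") which.min(scores) else which.max(scores)
  list(params = spec$grid[best, , drop = FALSE], score = scores[best],
       scores = dplyr::mutate(spec$grid, score = scores))
}

#' Protocol 1: pooled leave-one-subject-out evaluation
#'
#' For each held-out subject: hyperparameters are chosen by subject-wise grid
#' search on the remaining subjects (the test subject is excluded from every
#' decision, including standardization statistics), the model is refitted on
#' all remaining subjects and evaluated on the held-out one. Fold metrics are
#' averaged; the 95% CI is the normal approximation over folds.
#'
#' @param pooled A (pooled) segment feature table with >= 6 subjects.
#' @param spec A [classifier_spec()].
#' @param seed Seed.
#' @return An object of class `pain_eval` with per-fold and averaged metrics;
#'   see [tidy.pain_eval()] / [glance.pain_eval()].
#' @export
evaluate_protocol1 <- function(pooled, spec, seed = 1L) {
  d <- seg_xy(pooled)
  subs <- sort(unique(d$subject))
  if (length(subs) < 6) stop("protocol 1 needs at least 6 subjects", call. = FALSE)
  folds <- purrr::map_dfr(seq_along(subs), function(si) {
    s <- subs[si]
    te_i <- which(d$subject == s); tr_i <- which(d$subject != s)
    train_tbl <- pooled[tr_i, , drop = FALSE]
    gs <- grid_search_subjectwise(train_tbl, spec, seed = seed)
    Xtr <- d$X[tr_i, , drop = FALSE]; Xte <- d$X[te_i, , drop = FALSE]
    if (spec$standardize) {
      sc <- standardizer(Xtr); Xtr <- sc$apply(Xtr); Xte <- sc$apply(Xte)
    }
    mod <- fit_classifier(spec$family, gs$params, Xtr, d$y[tr_i], seed = seed)
    pr <- predict_classifier(mod, Xte)
    cm <- confusion(d$y[te_i], pr$class)
    dplyr::bind_cols(
      tibble(subject_id = s, n_test = length(te_i)),
      metrics_from_confusion(cm$tp, cm$tn, cm$fp, cm$fn),
      tibble(params = list(gs$params))
    )
  })
  structure(list(protocol = 1L, family = spec$family, folds = folds,
                 summary = summarize_folds(folds)),
            class = "pain_eval")
}

summarize_folds <- function(folds) {
  purrr::map_dfr(c("accuracy", "sensitivity", "specificity"), function(m) {
    v <- folds[[m]]; v <- v[is.finite(v)]
    tibble(metric = m, mean = mean(v),
           ci_low = mean(v) - 1.96 * sd(v) / sqrt(length(v)),
           ci_high = mean(v) + 1.96 * sd(v) / sqrt(length(v)),
           n_folds = length(v))
  })
}

#' Protocols 2 and 3: cross-dataset evaluation
#'
#' Grid search (subject-wise 5-fold) within the training table only, one fit
#' on the full training table, one evaluation on the test table. Subjects
#' must be disjoint between the tables. The 95% CI is a percentile bootstrap
#' over test segments (2000 resamples).
#'
#' @param train,test Segment feature tables with disjoint subjects.
#' @param spec A [classifier_spec()].
#' @param seed Seed.
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @return An object of class `pain_eval`.
#' @export
evaluate_cross_dataset <- function(train, test, spec, seed = 1L, n_boot = 2000) {
  if (nrow(test) == 0) stop("empty test table", call. = FALSE)
  overlap <- intersect(unique(train$subject_id), unique(test$subject_id))
  if (length(overlap)) {
    stop("train and test share subject id(s): ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  dtr <- seg_xy(train); dte <- seg_xy(test)
  gs <- grid_search_subjectwise(train, spec, seed = seed)
  Xtr <- dtr$X; Xte <- dte$X
  if (spec$standardize) {
    sc <- standardizer(Xtr); Xtr <- sc$apply(Xtr); Xte <- sc$apply(Xte)
  }
  mod <- fit_classifier(spec$family, gs$params, Xtr, dtr$y, seed = seed)
  pr <- predict_classifier(mod, Xte)
  cm <- confusion(dte$y, pr$class)
  point <- metrics_from_confusion(cm$tp, cm$tn, cm$fp, cm$fn)

  keep <- .Random.seed_exists(); set.seed(seed)
  boots <- purrr::map_dfr(seq_len(n_boot), function(b) {
    i <- sample.int(length(dte$y), replace = TRUE)
    cb <- confusion(dte$y[i], pr$class[i])
    metrics_from_confusion(cb$tp, cb$tn, cb$fp, cb$fn)
  })
  if (keep$had) assign(".Random.seed", keep$seed, envir = globalenv())

  summary <- purrr::map_dfr(c("accuracy", "sensitivity", "specificity"),
    function(m) {
      qs <- quantile(boots[[m]], c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      tibble(metric = m, mean = point[[m]], ci_low = qs[1], ci_high = qs[2],
             n_folds = 1L)
    })
  folds <- dplyr::bind_cols(
    tibble(subject_id = "all", n_test = length(dte$y)), point,
    tibble(params = list(gs$params)))
  structure(list(protocol = NA_integer_, family = spec$family, folds = folds,
                 summary = summary),
            class = "pain_eval")
}

#' @export
print.pain_eval <- function(x, ...) {
  cat("Pain-detection evaluation (", x$family, ", protocol ",
      ifelse(is.na(x$protocol), "cross-dataset", x$protocol), ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy/glance methods for evaluation results
#'
#' `tidy()` returns per-fold metrics; `glance()` the averaged metrics with
#' their 95% confidence intervals, one row per metric.
#'
#' @param x A `pain_eval` from [evaluate_protocol1()] or
#'   [evaluate_cross_dataset()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pain_eval <- function(x, ...) x$folds

#' @rdname tidy.pain_eval
#' @export
glance.pain_eval <- function(x, ...) {
  dplyr::mutate(x$summary, family = x$family, protocol = x$protocol,
                .before = 1)
}
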