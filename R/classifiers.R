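# Classifier families, nested grid search and the CV driver.

#' Classifier specifications
#'
#' The four supervised families evaluated by the pipeline, each with its
#' default hyperparameter grid ordered from simplest to most complex model
#' (the grid-search tie-break): K-nearest neighbours (k in 1/3/5/7/11),
#' RBF support vector machine (C in 0.1-100, gamma in 0.01-1), random
#' forest (100/300 trees, depth 6/unlimited) and gradient-boosted trees
#' (100/300 rounds, depth 3/6, learning rate 0.1/0.3).
#'
#' @param name One of `"knn"`, `"svm"`, `"rf"`, `"xgb"`.
#' @return A list with the classifier `name`, its `grid`, and `fit_predict`
#'   function.
#' @export
classifier_spec <- function(name = c("knn", "svm", "rf", "xgb")) {
  name <- match.arg(name)
  grid <- switch(name,
    knn = tibble(k = c(1, 3, 5, 7, 11)),
    svm = tidyr::expand_grid(cost = c(0.1, 1, 10, 100),
                             gamma = c(0.01, 0.1, 1)),
    rf = tidyr::expand_grid(num_trees = c(100, 300), max_depth = c(6, 0)),
    xgb = tidyr::expand_grid(nrounds = c(100, 300), max_depth = c(3, 6),
                             eta = c(0.1, 0.3))
  )
  default <- switch(name,
    knn = tibble(k = 5),
    svm = tibble(cost = 10, gamma = 0.1),
    rf = tibble(num_trees = 300, max_depth = 0),
    xgb = tibble(nrounds = 100, max_depth = 3, eta = 0.1)
  )
  fit_predict_fun <- switch(name,
    knn = function(xtr, ytr, xte, hyper, seed) {
      k <- hyper$k
      pr <- class::knn(xtr, xte, factor(ytr, levels = c(0, 1)), k = k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    svm = function(xtr, ytr, xte, hyper, seed) {
      fit <- with_seed(seed, e1071::svm(
        x = xtr, y = factor(ytr, levels = c(0, 1)), kernel = "radial",
        cost = hyper$cost, gamma = hyper$gamma, probability = TRUE,
        scale = FALSE))
      pr <- with_seed(seed, stats::predict(fit, xte, probability = TRUE))
      attr(pr, "probabilities")[, "1"]
    },
    rf = function(xtr, ytr, xte, hyper, seed) {
      d <- as.data.frame(xtr)
      d$.y <- factor(ytr, levels = c(0, 1))
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = d, probability = TRUE,
        num.trees = hyper$num_trees, max.depth = hyper$max_depth,
        seed = seed, num.threads = 1)
      stats::predict(fit, as.data.frame(xte),
                     num.threads = 1)$predictions[, "1"]
    },
    xgb = function(xtr, ytr, xte, hyper, seed) {
      fit <- fit_xgb(xtr, ytr, hyper, seed)
      stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(xte)))
    }
  )
  list(name = name, grid = grid, default = default,
       fit_predict = fit_predict_fun)
}

fit_xgb <- function(xtr, ytr, hyper, seed) {
  dtr <- xgboost::xgb.DMatrix(as.matrix(xtr), label = as.numeric(ytr))
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hyper$max_depth,
                  eta = hyper$eta, nthread = 1, tree_method = "exact"),
    data = dtr, nrounds = hyper$nrounds, verbose = 0))
}

#' Fit one classifier and score a test set
#'
#' Trains on normalized training features and returns continuous scores in
#' `[0, 1]` plus hard labels at the 0.5 threshold. A single-class training
#' fold yields a constant score of that class (with a warning).
#'
#' @param spec A [classifier_spec()].
#' @param train,test Normalized feature tibbles with a `label` column.
#' @param hyper A one-row hyperparameter tibble (default: the family's
#'   documented default point).
#' @param seed Integer seed for stochastic learners.
#' @param threshold Decision threshold on the score.
#' @return A tibble with `score` and `pred` for the test rows.
#' @export
fit_predict <- function(spec, train, test, hyper = NULL, seed = 1,
                        threshold = 0.5) {
  hyper <- hyper %||% spec$default
  cols <- feature_cols(train)
  ytr <- train$label
  if (length(unique(ytr)) < 2) {
    warn("single-class training fold; returning constant scores")
    sc <- rep(as.numeric(unique(ytr)), nrow(test))
  } else {
    sc <- spec$fit_predict(as.matrix(train[cols]), ytr,
                           as.matrix(test[cols]), hyper, seed)
  }
  tibble(score = as.numeric(sc), pred = as.integer(sc >= threshold))
}

#' Nested grid search over a classifier's hyperparameters
#'
#' Evaluates every grid point by stratified k-fold cross-validation inside
#' the training set only (normalization refitted on each inner training
#' fold, so there is no selection leakage) and returns the
#' accuracy-maximizing point; ties go to the earlier (simpler) grid row.
#'
#' @param spec A [classifier_spec()].
#' @param train Training feature tibble (un-normalized).
#' @param inner_k Number of inner folds (default 5).
#' @param seed Integer seed for fold assignment and learners.
#' @return The chosen one-row hyperparameter tibble, with the inner-CV
#'   accuracies of all grid points attached as attribute `accuracy`.
#' @export
grid_search <- function(spec, train, inner_k = 5, seed = 1) {
  n <- nrow(train)
  if (nrow(spec$grid) == 1) return(spec$grid[1, ])
  y <- train$label
  inner_k <- min(inner_k, max(2L, min(table(y))))
  folds <- with_seed(seed, {
    f <- integer(n)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(inner_k), length(idx)))
    }
    f
  })
  acc <- vapply(seq_len(nrow(spec$grid)), function(g) {
    correct <- 0
    for (k in seq_len(inner_k)) {
      tr <- train[folds != k, , drop = FALSE]
      te <- train[folds == k, , drop = FALSE]
      if (length(unique(tr$label)) < 2 || nrow(te) == 0) next
      nm <- minmax_normalize(tr, te)
      pr <- suppressWarnings(
        fit_predict(spec, nm$train, nm$test, spec$grid[g, ], seed))
      correct <- correct + sum(pr$pred == te$label)
    }
    correct / n
  }, numeric(1))
  best <- spec$grid[which.max(acc), ]
  attr(best, "accuracy") <- acc
  best
}

#' Evaluate classifiers under a cross-validation protocol
#'
#' Runs the full evaluation harness: folds are built by the chosen protocol
#' (leave-one-epoch-out or leave-one-subject-out), min-max normalization is
#' fitted on each training fold only, hyperparameters are (optionally)
#' chosen by nested stratified grid search inside each training fold,
#' out-of-fold scores are pooled, and accuracy/sensitivity/specificity/F1
#' and the pooled-score AUC are reported per classifier. For the
#' gradient-boosted family, per-fold split-count feature importances are
#' averaged and normalized to sum to 1.
#'
#' @param features A feature table from [extract_feature_table()].
#' @param protocol `"loso"` (subject-independent) or `"loo"`.
#' @param classifiers Subset of `c("knn", "svm", "rf", "xgb")`.
#' @param tune Run the nested grid search (`TRUE`) or use each family's
#'   default hyperparameters.
#' @param inner_k Inner folds for the grid search.
#' @param seed Integer seed controlling fold assignment and stochastic
#'   learners.
#' @param threshold Decision threshold on the pooled scores.
#' @return An object of class `hf_cv`: a list with `results` (one row per
#'   classifier: metrics, confusion counts, ROC, chosen hyperparameters,
#'   importance), `predictions` (pooled out-of-fold scores), `protocol`,
#'   and `seed`. Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
evaluate_classifiers <- function(features, protocol = c("loso", "loo"),
                                 classifiers = c("knn", "svm", "rf", "xgb"),
                                 tune = TRUE, inner_k = 5, seed = 1,
                                 threshold = 0.5) {
  protocol <- match.arg(protocol)
  folds <- if (protocol == "loso") loso_split(features) else loo_split(features)
  fold_seeds <- derive_seeds(seed, length(folds))

  res_rows <- list()
  pred_rows <- list()
  for (cls in classifiers) {
    spec <- classifier_spec(cls)
    scores <- rep(NA_real_, nrow(features))
    fold_of <- rep(NA_integer_, nrow(features))
    hypers <- list()
    imps <- list()
    for (f in seq_along(folds)) {
      te_idx <- folds[[f]]
      tr <- features[-te_idx, , drop = FALSE]
      te <- features[te_idx, , drop = FALSE]
      hyper <- if (tune) grid_search(spec, tr, inner_k, fold_seeds[f]) else spec$default
      nm <- minmax_normalize(tr, te)
      pr <- fit_predict(spec, nm$train, nm$test, hyper, fold_seeds[f], threshold)
      scores[te_idx] <- pr$score
      fold_of[te_idx] <- f
      hypers[[f]] <- hyper
      if (cls == "xgb") {
        fit <- fit_xgb(as.matrix(nm$train[feature_cols(nm$train)]),
                       nm$train$label, hyper, fold_seeds[f])
        im <- xgboost::xgb.importance(model = fit)
        vec <- stats::setNames(rep(0, 33), sprintf("t%02d", 1:33))
        if (!is.null(im) && nrow(im) > 0) vec[im$Feature] <- im$Frequency
        imps[[f]] <- vec
      }
    }
    pred <- as.integer(scores >= threshold)
    y <- features$label
    conf <- c(tp = sum(pred == 1 & y == 1), tn = sum(pred == 0 & y == 0),
              fp = sum(pred == 1 & y == 0), fn = sum(pred == 0 & y == 1))
    metrics <- compute_metrics(conf)
    roc <- compute_roc_auc(scores, y)
    importance <- if (cls == "xgb") {
      m <- colMeans(do.call(rbind, imps))
      if (sum(m) > 0) m / sum(m) else m
    } else NULL
    res_rows[[cls]] <- dplyr::bind_cols(
      tibble(classifier = cls, protocol = protocol),
      metrics, tibble(auc = roc$auc),
      tibble(confusion = list(conf), roc = list(roc$roc),
             hyper = list(dplyr::bind_rows(hypers)),
             importance = list(importance)))
    pred_rows[[cls]] <- tibble(classifier = cls,
                               subject_id = features$subject_id,
                               epoch_index = features$epoch_index,
                               label = y, score = scores, pred = pred,
                               fold = fold_of)
  }
  structure(list(results = dplyr::bind_rows(res_rows),
                 predictions = dplyr::bind_rows(pred_rows),
                 protocol = protocol, seed = seed,
                 n_epochs = nrow(features),
                 n_subjects = length(unique(features$subject_id))),
            class = "hf_cv")
}

#' @export
print.hf_cv <- function(x, ...) {
  cat(sprintf("<hf_cv> %s over %d epochs / %d subjects\n",
              toupper(x$protocol), x$n_epochs, x$n_subjects))
  print(tidy(x))
  invisible(x)
}
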