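# Normalization, folds, metrics, classifiers, importance, group tests.

test_that("min-max normalization is train-fitted, clipped and idempotent", {
  tr <- tibble::tibble(t01 = c(2, 4, 6), t02 = c(0, 5, 10), label = c(0, 1, 0))
  te <- tibble::tibble(t01 = c(8, 1), t02 = c(5, 5), label = c(1, 0))
  nm <- minmax_normalize(tr, te)
  expect_equal(nm$train$t01, c(0, 0.5, 1))
  expect_equal(nm$test$t01, c(1, 0)) # clipped to [0, 1]
  nm2 <- minmax_normalize(nm$train)
  expect_equal(nm2$train$t01, nm$train$t01)
  trc <- tibble::tibble(t01 = c(3, 3, 3), label = c(0, 1, 0))
  expect_warning(nmc <- minmax_normalize(trc), "constant")
  expect_equal(nmc$train$t01, c(0, 0, 0))
})

test_that("LOO and LOSO folds partition the table correctly", {
  ft <- synth_feature_table(n_subjects = 5, epochs = 4)
  loo <- loo_split(ft)
  expect_length(loo, 20)
  loso <- loso_split(ft)
  expect_length(loso, 5)
  for (f in loso) {
    expect_length(intersect(ft$subject_id[f], ft$subject_id[-f]), 0)
  }
  expect_setequal(unlist(loso), seq_len(nrow(ft)))
  expect_equal(sum(lengths(loso)), nrow(ft))
})

test_that("confusion metrics match hand arithmetic and symmetries", {
  m <- compute_metrics(90, 85, 15, 10)
  expect_equal(m$acc, 87.5)
  expect_equal(m$sen, 90)
  expect_equal(m$spe, 85)
  expect_equal(m$f1, 180 / 205 * 100, tolerance = 1e-9)
  p <- compute_metrics(50, 50, 0, 0)
  expect_equal(unlist(p), c(acc = 100, sen = 100, spe = 100, f1 = 100))
  # inverting labels and predictions swaps sensitivity and specificity
  m2 <- compute_metrics(85, 90, 10, 15)
  expect_equal(m2$sen, m$spe)
  expect_equal(m2$spe, m$sen)
})

test_that("AUC equals the rank-sum statistic and handles extremes", {
  expect_equal(compute_roc_auc(1:10, c(rep(0, 5), rep(1, 5)))$auc, 100)
  withr::with_seed(10, {
    sc <- rnorm(500)
    lb <- rbinom(500, 1, 0.5)
    r <- compute_roc_auc(sc, lb)
    expect_equal(r$auc, auc_oracle(sc, lb), tolerance = 1e-9)
    expect_equal(r$auc, 50, tolerance = 5)
    # independent cross-check against pROC
    expect_equal(r$auc / 100,
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
                 tolerance = 1e-9)
    # ROC endpoints
    expect_equal(r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  })
})

test_that("all four classifier families separate a separable table", {
  # class clusters separated by a wide empty margin relative to all spread
  ft <- synth_feature_table(n_subjects = 6, epochs = 5,
                            informative = sprintf("t%02d", 1:33),
                            effect = 1, subject_sd = 0.03, noise_sd = 0.005,
                            seed = 2)
  for (cls in c("knn", "svm", "rf", "xgb")) {
    cv <- evaluate_classifiers(ft, protocol = "loso", classifiers = cls,
                               tune = FALSE, seed = 3)
    expect_equal(cv$results$acc, 100, info = cls)
  }
})

test_that("identical seeds give identical predictions", {
  ft <- synth_feature_table(n_subjects = 6, epochs = 4, effect = 1, seed = 4)
  a <- evaluate_classifiers(ft, protocol = "loso", classifiers = c("rf", "xgb"),
                            tune = FALSE, seed = 7)
  b <- evaluate_classifiers(ft, protocol = "loso", classifiers = c("rf", "xgb"),
                            tune = FALSE, seed = 7)
  expect_identical(a$predictions$score, b$predictions$score)
})

test_that("single-class training folds fall back to constant scores", {
  ft <- synth_feature_table(n_subjects = 4, epochs = 3, seed = 5)
  ft$label <- 0L
  ft$label[ft$subject_id == "S01"] <- 1L
  spec <- classifier_spec("knn")
  tr <- ft[ft$subject_id != "S01", ]
  tr$label <- 0L
  te <- ft[ft$subject_id == "S01", ]
  expect_warning(pr <- fit_predict(spec, tr, te), "single-class")
  expect_true(all(pr$score == 0))
})

test_that("grid search honours the argmax contract and prefers simpler models", {
  ft <- synth_feature_table(n_subjects = 6, epochs = 5, effect = 8,
                            subject_sd = 0.1, seed = 6)
  spec <- classifier_spec("knn")
  chosen <- grid_search(spec, ft, seed = 1)
  acc <- attr(chosen, "accuracy")
  expect_equal(max(acc), acc[which(spec$grid$k == chosen$k)])
  # several k reach 100% on a separable table; the smallest is returned
  expect_equal(chosen$k, spec$grid$k[which.max(acc)])
  expect_equal(which.max(acc), min(which(acc == max(acc))))
  one <- list(name = "knn", grid = spec$grid[3, ], fit_predict = spec$fit_predict)
  expect_equal(grid_search(one, ft, seed = 1), spec$grid[3, ])
})

test_that("normalization and model selection never see the test fold", {
  ft <- synth_feature_table(n_subjects = 6, epochs = 4, effect = 2, seed = 7)
  folds <- loso_split(ft)
  te_idx <- folds[[1]]
  tr <- ft[-te_idx, ]
  te <- ft[te_idx, ]
  te_bad <- te
  te_bad$label <- 1L - te_bad$label
  te_bad[feature_cols(te_bad)] <- te_bad[feature_cols(te_bad)] + 100
  nm1 <- minmax_normalize(tr, te)
  nm2 <- minmax_normalize(tr, te_bad)
  expect_identical(nm1$ranges, nm2$ranges)
  spec <- classifier_spec("xgb")
  h1 <- grid_search(spec, tr, seed = 2)
  h2 <- grid_search(spec, tr, seed = 2) # test rows never enter
  expect_identical(h1, h2)
})

test_that("label permutation drives LOSO accuracy to chance", {
  ft <- synth_feature_table(n_subjects = 10, epochs = 5, effect = 6,
                            subject_sd = 0.2, seed = 8)
  ftp <- ft
  withr::with_seed(9, ftp$label <- sample(ftp$label))
  cv <- evaluate_classifiers(ftp, protocol = "loso", classifiers = "knn",
                             tune = FALSE, seed = 1)
  expect_gte(cv$results$acc, 30)
  expect_lte(cv$results$acc, 70)
})

test_that("LOSO is no easier than LOO under subject heterogeneity", {
  wins <- 0
  for (s in 1:5) {
    ft <- synth_feature_table(n_subjects = 8, epochs = 4, effect = 1.5,
                              subject_sd = 1, seed = 100 + s)
    loso <- evaluate_classifiers(ft, protocol = "loso", classifiers = "knn",
                                 tune = FALSE, seed = 1)
    loo <- evaluate_classifiers(ft, protocol = "loo", classifiers = "knn",
                                tune = FALSE, seed = 1)
    if (loso$results$acc <= loo$results$acc) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("importance ranks the informative feature first and normalizes", {
  ft <- synth_feature_table(n_subjects = 8, epochs = 5, informative = "t28",
                            effect = 6, subject_sd = 0.2, seed = 9)
  cv <- evaluate_classifiers(ft, protocol = "loso", classifiers = "xgb",
                             tune = FALSE, seed = 2)
  imp <- rank_importance(cv)
  expect_equal(imp$feature[1], "t28")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_length(attr(imp, "top"), 10)
  # a pure-noise feature never outranks the informative one
  expect_gt(imp$importance[imp$feature == "t28"],
            max(imp$importance[imp$feature != "t28"]))
})

test_that("rank-sum group tests behave on null, shifted and transformed data", {
  ft0 <- tibble::tibble(label = rep(c(0L, 1L), each = 20),
                        t01 = rep(seq_len(20), 2))
  expect_gt(feature_group_test(ft0, "t01"), 0.99)
  withr::with_seed(11, {
    ft1 <- tibble::tibble(label = rep(c(0L, 1L), each = 100),
                          t01 = c(rnorm(100), rnorm(100, 2)))
    p <- feature_group_test(ft1, "t01")
    expect_lt(p, 1e-4)
    # invariance to monotone transforms
    ft2 <- ft1
    ft2$t01 <- exp(ft2$t01)
    expect_equal(feature_group_test(ft2, "t01"), p, tolerance = 1e-12)
  })
})
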