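test_that("stratified folds partition every index with balanced classes", {
  labels <- rep(c("PD_OFF", "HC"), each = 50)
  folds <- kfold_indices(100, 10, labels, seed = 5)
  test_sets <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), 1:100)
  expect_true(all(lengths(test_sets) == 10))
  for (f in folds) {
    expect_equal(sum(labels[f$test] == "PD_OFF"), 5)
    expect_length(intersect(f$train, f$test), 0)
  }
  folds2 <- kfold_indices(100, 10, labels, seed = 5)
  expect_identical(folds, folds2)
  folds3 <- kfold_indices(100, 10, labels, seed = 6)
  expect_false(identical(folds, folds3))
  # both classes are smaller than k, so each raises its own warning
  expect_warning(expect_warning(
    kfold_indices(12, 10, rep(c("a", "b"), c(3, 9)), seed = 1),
    "best-effort"), "best-effort")
})

test_that("confusion metrics reproduce the percent-scale formulas", {
  counts <- list(TP = 90, FN = 10, TN = 80, FP = 20)
  met <- confusion_metrics(counts)
  expect_equal(met$accuracy, 85)
  expect_equal(met$sensitivity, 90)
  expect_equal(met$specificity, 80)
  expect_equal(met$precision, 100 * 90 / 110)
  expect_equal(met$f_score, 2 * met$precision * met$sensitivity /
                 (met$precision + met$sensitivity))
  expect_equal(round(met$f_score, 3), 85.714)

  perfect <- confusion_metrics(list(TP = 10, FN = 0, TN = 10, FP = 0))
  expect_true(all(unlist(perfect) == 100))

  sym <- confusion_metrics(list(TP = 5, FN = 5, TN = 7, FP = 7))
  expect_equal(sym$accuracy, 50)

  # zero denominators are undefined, not zero
  none_pos <- confusion_metrics(list(TP = 0, FN = 0, TN = 8, FP = 2))
  expect_true(is.na(none_pos$sensitivity))

  cc <- confusion_counts(c("PD_OFF", "PD_OFF", "HC"), c("PD_OFF", "HC", "HC"),
                         positive = "PD_OFF")
  expect_equal(unclass(cc), list(TP = 1L, FP = 0L, TN = 1L, FN = 1L),
               ignore_attr = TRUE)
})

test_that("trapezoidal AUC equals the Mann-Whitney pair-count oracle", {
  # perfect separation and degenerate ties
  expect_equal(roc_auc(c(3, 4, 1, 2), c("P", "P", "N", "N"), "P")$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("P", "N"), 3), "P")$auc, 0.5)

  set.seed(40)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    labels <- sample(c("P", "N"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("P", "N")
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    got <- roc_auc(scores, labels, "P")
    expect_equal(got$auc, auc_pair_oracle(scores, labels, "P"),
                 tolerance = 1e-12)
    expect_true(all(got$roc$FPR >= 0 & got$roc$FPR <= 1))
    expect_equal(got$roc$TPR[nrow(got$roc)], 1)
  }
})

test_that("AUC agrees with an independent ROC package on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- rnorm(60)
  labels <- sample(c("P", "N"), 60, replace = TRUE)
  got <- roc_auc(scores, labels, "P")$auc
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = labels, predictor = scores, levels = c("N", "P"),
              direction = "<"))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("all classifier kinds separate well-separated clusters and score sanely", {
  set.seed(42)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, mean = 0), ncol = 2),
             matrix(rnorm(n * 2, mean = 10), ncol = 2))
  labels <- rep(c("PD_OFF", "HC"), each = n)
  for (kind in c("KNN", "RF", "LDA", "QDA", "SVM")) {
    clf <- train_classifier(classifier_spec(kind), x, labels,
                            class_A = "PD_OFF")
    pred <- predict_classifier(clf, x)
    expect_equal(mean(pred$class == labels), 1, info = kind)
    # scores must rank the positive class above the negative one
    expect_equal(roc_auc(pred$score, labels, "PD_OFF")$auc, 1, info = kind)
  }
  expect_error(classifier_spec("KNN", knn_k = 4), "odd")
})

test_that("cross-validation is deterministic and near chance under label shuffling", {
  set.seed(43)
  segs <- toy_segment_set(ch = 4, n_per_class = 60, N = 64, spread = 1)
  segs$labels <- sample(segs$labels)   # break any real structure
  res <- run_cv(segs, feature = feature_config("VAR"),
                classifier = classifier_spec("KNN"), k = 10, seed = 7)
  acc <- res$summary$accuracy["mean"]
  expect_gt(acc, 35)
  expect_lt(acc, 65)

  res2 <- run_cv(segs, feature = feature_config("VAR"),
                 classifier = classifier_spec("KNN"), k = 10, seed = 7)
  expect_identical(res$summary, res2$summary)
})

test_that("fold-mean accuracy matches pooled accuracy for equal fold sizes", {
  set.seed(44)
  segs <- toy_segment_set(ch = 4, n_per_class = 50, N = 64)
  res <- run_cv(segs, k = 10, seed = 2)
  pooled <- Reduce(function(a, f) {
    a + c(f$counts$TP + f$counts$TN,
          f$counts$TP + f$counts$TN + f$counts$FP + f$counts$FN)
  }, res$per_fold, c(0, 0))
  expect_equal(unname(res$summary$accuracy["mean"]),
               100 * pooled[1] / pooled[2])
  # percentages and AUC live on their stated scales
  for (f in res$per_fold) {
    expect_true(f$auc >= 0 && f$auc <= 1)
    expect_true(f$accuracy >= 0 && f$accuracy <= 100)
  }
})

test_that("the CSP projection never sees test-fold data", {
  set.seed(45)
  segs <- toy_segment_set(ch = 4, n_per_class = 30, N = 64)
  M <- length(segs$segments)
  res <- run_cv(segs, k = 5, seed = 9)
  folds <- kfold_indices(M, 5, segs$labels, seed = 9)

  # corrupt fold 1's test segments with a huge-amplitude sentinel
  segs_evil <- segs
  for (i in folds[[1]]$test)
    segs_evil$segments[[i]] <- segs$segments[[i]] * 1e6 + 1e6
  res_evil <- run_cv(segs_evil, k = 5, seed = 9)
  expect_identical(res_evil$per_fold[[1]]$model$W_full,
                   res$per_fold[[1]]$model$W_full)

  # whereas refitting on train+test would move the projection
  W_all <- fit_csp(segs_evil, class_A = "PD_OFF", class_B = "HC")$W_full
  expect_gt(max(abs(W_all - res$per_fold[[1]]$model$W_full)), 1e-6)
})

test_that("subject-level folds keep each subject's segments together", {
  set.seed(46)
  mk <- function(g, id) recording(matrix(rnorm(2 * 1000), 2), fs = 100,
                                  group = g, subject_id = id)
  recs <- c(lapply(1:6, function(i) mk("PD_OFF", paste0("p", i))),
            lapply(1:6, function(i) mk("HC", paste0("h", i))))
  segs <- segment_recordings(recs, T_s = 1)
  res <- run_cv(segs, k = 3, seed = 1, cv_mode = "subject",
                classifier = classifier_spec("KNN"))
  folds_subjects <- lapply(res$per_fold, function(f) f$fold)
  expect_length(res$per_fold, 3)
  # rebuild the fold map and check no subject straddles train and test
  uniq <- sort(unique(segs$subjects))
  sfolds <- kfold_indices(length(uniq), 3, segs$labels[match(uniq, segs$subjects)],
                          seed = 1)
  for (f in sfolds) {
    test_subj <- uniq[f$test]
    expect_length(intersect(test_subj, uniq[f$train]), 0)
  }
})

test_that("evaluation results export to JSON and CSV", {
  set.seed(47)
  segs <- toy_segment_set(ch = 4, n_per_class = 20, N = 64)
  res <- run_cv(segs, k = 5, seed = 3)
  jp <- withr::local_tempfile(fileext = ".json")
  sp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  write_eval_result(res, jp, summary_csv = sp, roc_csv = rp)
  obj <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(obj$seed, 3)
  expect_equal(nrow(obj$per_fold), 5)
  s <- read.csv(sp)
  expect_true("accuracy" %in% s$metric)
  roc <- read.csv(rp)
  expect_true(all(c("fold", "FPR", "TPR") %in% names(roc)))
})
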