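# Cross-validated evaluation: stratified fold construction, confusion-count
# metrics on the percent scale, threshold-sweep ROC with trapezoidal AUC,
# and the leakage-safe train/test pipeline (CSP refit per training fold).

#' Stratified k-fold partition
#'
#' Shuffles indices within each class (reproducibly from `seed`) and deals
#' them round-robin into k folds, so per-class test counts differ by at
#' most one across folds. Classes with fewer than k members are spread over
#' as many folds as they have members, with a warning.
#'
#' @param M number of samples.
#' @param k number of folds (default 10).
#' @param labels class tag per sample (length M).
#' @param seed integer seed for the shuffle.
#' @return List of k elements, each `list(train = idx, test = idx)`; test
#'   sets are disjoint and their union is `1:M`.
#' @export
kfold_indices <- function(M, k = 10, labels = NULL, seed = 1) {
  stopifnot(k >= 2, M >= k)
  if (is.null(labels)) labels <- rep("all", M)
  stopifnot(length(labels) == M)
  fold_of <- integer(M)
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      warning("class '", cl, "' has fewer members (", length(idx),
              ") than folds (", k, "); stratification is best-effort")
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- (seq_along(idx) - 1L) %% k + 1L
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Confusion counts and derived percent metrics
#'
#' `confusion_counts` tallies TP/FP/TN/FN treating `positive` as the
#' disease class; `confusion_metrics` converts counts to accuracy,
#' sensitivity (recall), specificity, precision and F-score, all on the
#' 0--100 percent scale. A metric whose denominator is zero is reported as
#' `NA` (undefined), never as 0.
#'
#' @param truth,predicted class tag vectors of equal length.
#' @param positive the positive-class tag.
#' @param counts a `confusion_counts` object (or list with TP, FP, TN, FN).
#' @return `confusion_counts`: list of the four counts.
#'   `confusion_metrics`: list of the five percent metrics.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  stopifnot(length(truth) == length(predicted))
  structure(list(
    TP = sum(truth == positive & predicted == positive),
    FP = sum(truth != positive & predicted == positive),
    TN = sum(truth != positive & predicted != positive),
    FN = sum(truth == positive & predicted != positive)),
    class = "confusion_counts")
}

#' @rdname confusion_counts
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    acc <- safe(TP + TN, TP + TN + FP + FN)
    sens <- safe(TP, TP + FN)
    spec <- safe(TN, TN + FP)
    prec <- safe(TP, TP + FP)
    f <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
         else 2 * prec * sens / (prec + sens)
    list(accuracy = acc, sensitivity = sens, specificity = spec,
         precision = prec, f_score = f)
  })
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps every distinct score as a threshold (predict positive when score
#' >= threshold), yielding the (FPR, TPR) staircase from (0,0) to (1,1);
#' the AUC is the trapezoidal area under it, which equals the
#' Mann--Whitney probability that a random positive outscores a random
#' negative (ties counted half).
#'
#' @param scores numeric scores, larger meaning more positive-like.
#' @param labels class tags.
#' @param positive positive-class tag.
#' @return List with `roc` (data.frame of FPR, TPR) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("need both classes to compute a ROC")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}

summarize_folds <- function(per_fold) {
  metrics <- c("accuracy", "sensitivity", "specificity", "precision",
               "f_score", "auc")
  out <- lapply(metrics, function(m) {
    v <- vapply(per_fold, function(f) f[[m]], numeric(1))
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  })
  names(out) <- metrics
  out
}

#' Cross-validated evaluation of a segment set
#'
#' For each fold, the CSP projection is fit on the training segments only
#' and reduced to `2m` filters, features are extracted for train and test
#' segments with that fold's model, the classifier is trained on the
#' training features and evaluated on the held-out fold. The positive
#' class is the patient group (`class_A`).
#'
#' @param segment_set a `segment_set` with exactly two classes.
#' @param m CSP filter pairs to keep; default `ch/2` (no reduction).
#' @param feature a [feature_config()].
#' @param classifier a [classifier_spec()].
#' @param k folds (default 10).
#' @param seed integer; drives fold assignment and any classifier
#'   randomness, making the whole evaluation reproducible.
#' @param class_A positive class tag; defaults to the PD group when present
#'   else the first class in sorted order.
#' @param cv_mode `"segment"` (stratified over segments, the default) or
#'   `"subject"` (folds hold out whole subjects, avoiding within-subject
#'   leakage across folds).
#' @param center,reg passed to [fit_csp()].
#' @return An `eval_result`: `per_fold` (counts, metrics, AUC, ROC points,
#'   the fold's `csp_model`), `summary` (mean and sd per metric), and the
#'   configuration.
#' @export
run_cv <- function(segment_set, m = NULL, feature = feature_config(),
                   classifier = classifier_spec(), k = 10, seed = 1,
                   class_A = NULL, cv_mode = c("segment", "subject"),
                   center = TRUE, reg = 0) {
  stopifnot(inherits(segment_set, "segment_set"))
  cv_mode <- match.arg(cv_mode)
  labels <- segment_set$labels
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    stop("run_cv needs exactly two classes, got: ",
         paste(classes, collapse = ", "))
  if (is.null(class_A)) {
    pd <- classes[startsWith(classes, "PD")]
    class_A <- if (length(pd) >= 1) pd[1] else classes[1]
  }
  class_B <- setdiff(classes, class_A)
  if (is.null(m)) m <- segment_set$ch %/% 2

  M <- length(segment_set$segments)
  if (cv_mode == "segment") {
    folds <- kfold_indices(M, k, labels, seed)
  } else {
    subj <- segment_set$subjects
    uniq <- sort(unique(subj))
    subj_lab <- labels[match(uniq, subj)]
    sfolds <- kfold_indices(length(uniq), k, subj_lab, seed)
    folds <- lapply(sfolds, function(f)
      list(train = which(subj %in% uniq[f$train]),
           test = which(subj %in% uniq[f$test])))
  }

  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (length(te) == 0) next
    train_set <- subset_segments(segment_set, tr)
    test_set <- subset_segments(segment_set, te)
    model <- tryCatch(
      csp_reduce(fit_csp(train_set, class_A = class_A, class_B = class_B,
                         center = center, reg = reg), m),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
    ftr <- extract_features(model, train_set, feature)
    fte <- extract_features(model, test_set, feature)
    set.seed(seed + f)   # classifier-internal randomness (RF bootstrap)
    clf <- train_classifier(classifier, ftr$values, ftr$labels,
                            class_A = class_A)
    pred <- predict_classifier(clf, fte$values)
    counts <- confusion_counts(fte$labels, pred$class, positive = class_A)
    met <- confusion_metrics(counts)
    roc <- roc_auc(pred$score, fte$labels, positive = class_A)
    per_fold[[f]] <- c(list(fold = f, counts = counts, auc = roc$auc,
                            roc = roc$roc, model = model), met)
  }
  per_fold <- Filter(Negate(is.null), per_fold)
  structure(list(per_fold = per_fold, summary = summarize_folds(per_fold),
                 class_A = class_A, class_B = class_B, m = m,
                 feature = feature, classifier = classifier, k = k,
                 seed = seed, cv_mode = cv_mode),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s vs %s | %s + %s | %d-fold (%s-level)\n",
              x$class_A, x$class_B, x$feature$metric, x$classifier$kind,
              x$k, x$cv_mode))
  s <- x$summary
  for (mname in names(s))
    cat(sprintf("  %-12s %7.3f +/- %.3f\n", mname, s[[mname]]["mean"],
                s[[mname]]["sd"]))
  invisible(x)
}

#' Full pipeline: band-pass, segment, cross-validate
#'
#' Convenience wrapper running [bandpass()] on every recording,
#' [segment_recordings()], then [run_cv()].
#'
#' @param recordings list of `eeg_recording` objects (two groups).
#' @param band a [band_spec()].
#' @param T_s segment duration in seconds.
#' @param ... passed on to [run_cv()] (`m`, `feature`, `classifier`, `k`,
#'   `seed`, `class_A`, `cv_mode`, ...).
#' @return An `eval_result`.
#' @export
run_pipeline <- function(recordings, band = band_spec(), T_s = 2, ...) {
  filtered <- lapply(recordings, bandpass, band = band)
  segs <- segment_recordings(filtered, T_s = T_s, band = band)
  run_cv(segs, ...)
}

#' Export an evaluation result
#'
#' Writes the full result as JSON and, optionally, a per-fold ROC-point CSV
#' and a one-row-per-metric summary CSV.
#'
#' @param result an `eval_result`.
#' @param json_path,summary_csv,roc_csv output paths (`NULL` to skip).
#' @return `json_path`, invisibly.
#' @export
write_eval_result <- function(result, json_path, summary_csv = NULL,
                              roc_csv = NULL) {
  stopifnot(inherits(result, "eval_result"))
  obj <- list(
    class_A = result$class_A, class_B = result$class_B, m = result$m,
    feature = unclass(result$feature),
    classifier = unclass(result$classifier),
    k = result$k, seed = result$seed, cv_mode = result$cv_mode,
    summary = result$summary,
    per_fold = lapply(result$per_fold, function(f)
      list(fold = f$fold, counts = unclass(f$counts), accuracy = f$accuracy,
           sensitivity = f$sensitivity, specificity = f$specificity,
           precision = f$precision, f_score = f$f_score, auc = f$auc)))
  jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(summary_csv)) {
    s <- result$summary
    df <- data.frame(metric = names(s),
                     mean = vapply(s, `[[`, numeric(1), "mean"),
                     sd = vapply(s, `[[`, numeric(1), "sd"))
    utils::write.csv(df, summary_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(roc_csv)) {
    rocs <- do.call(rbind, lapply(result$per_fold, function(f)
      cbind(fold = f$fold, f$roc)))
    utils::write.csv(rocs, roc_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
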