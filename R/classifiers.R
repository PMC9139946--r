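# Thin uniform wrappers around the standard classifiers so the evaluation
# loop can treat them interchangeably: every trained model yields a class
# prediction and a real score where larger means "more class-A-like".

CLASSIFIER_KINDS <- c("KNN", "RF", "LDA", "QDA", "SVM")

#' Classifier specification
#'
#' @param kind one of `"KNN"` (k-nearest neighbors, Euclidean), `"RF"`
#'   (bagged random forest), `"LDA"`, `"QDA"`, `"SVM"` (quadratic-kernel,
#'   i.e. degree-2 polynomial, support vector machine).
#' @param knn_k neighbor count for KNN (default 3; must be odd so binary
#'   votes cannot tie).
#' @param rf_trees number of trees for RF (default 100).
#' @param svm_cost SVM soft-margin cost (default 1).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = "KNN", knn_k = 3, rf_trees = 100,
                            svm_cost = 1) {
  kind <- match.arg(toupper(kind), CLASSIFIER_KINDS)
  if (kind == "KNN" && knn_k %% 2 == 0)
    stop("`knn_k` must be odd to avoid vote ties in a binary problem")
  structure(list(kind = kind, knn_k = as.integer(knn_k),
                 rf_trees = as.integer(rf_trees), svm_cost = svm_cost),
            class = "classifier_spec")
}

#' Train a classifier on a feature matrix
#'
#' @param spec a [classifier_spec()].
#' @param x numeric matrix of training features (rows = segments).
#' @param labels class tag per row (exactly two distinct values).
#' @param class_A the positive class; its score is the one reported by
#'   [predict_classifier()]. Defaults to the first label in sorted order.
#' @return An opaque `trained_classifier`.
#' @export
train_classifier <- function(spec, x, labels, class_A = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(x),
            nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("need exactly two classes, got ",
                                 length(classes))
  if (is.null(class_A)) class_A <- classes[1]
  stopifnot(class_A %in% classes)
  class_B <- setdiff(classes, class_A)
  y <- factor(labels, levels = c(class_A, class_B))
  fit <- switch(spec$kind,
    KNN = list(train = x, y = y),
    RF = randomForest::randomForest(x, y, ntree = spec$rf_trees),
    LDA = MASS::lda(x, grouping = y),
    QDA = MASS::qda(x, grouping = y),
    SVM = e1071::svm(x, y, kernel = "polynomial", degree = 2, coef0 = 1,
                     cost = spec$svm_cost, probability = FALSE, scale = TRUE))
  structure(list(spec = spec, fit = fit, class_A = class_A, class_B = class_B),
            class = "trained_classifier")
}

#' Predict classes and class-A scores
#'
#' Scores: KNN reports the fraction of the k nearest training neighbors in
#' class A; RF the tree-vote fraction for class A; LDA/QDA the posterior
#' probability of class A; SVM the signed decision value oriented so larger
#' favors class A.
#'
#' @param model a `trained_classifier`.
#' @param x numeric matrix of feature vectors.
#' @return A list with `class` (character vector) and `score` (numeric).
#' @export
predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "trained_classifier"), is.matrix(x))
  spec <- model$spec
  switch(spec$kind,
    KNN = {
      pred <- class::knn(model$fit$train, x, model$fit$y, k = spec$knn_k,
                         prob = TRUE, use.all = TRUE)
      pwin <- attr(pred, "prob")
      score <- ifelse(pred == model$class_A, pwin, 1 - pwin)
      list(class = as.character(pred), score = as.numeric(score))
    },
    RF = {
      votes <- stats::predict(model$fit, x, type = "prob")
      score <- votes[, model$class_A]
      cls <- ifelse(score >= 0.5, model$class_A, model$class_B)
      list(class = as.character(cls), score = as.numeric(score))
    },
    LDA = ,
    QDA = {
      pr <- stats::predict(model$fit, x)
      list(class = as.character(pr$class),
           score = as.numeric(pr$posterior[, model$class_A]))
    },
    SVM = {
      pr <- stats::predict(model$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient the margin so positive favors class_A
      flip <- if (startsWith(colnames(dv)[1], paste0(model$class_A, "/"))) 1 else -1
      list(class = as.character(pr), score = as.numeric(flip * dv[, 1]))
    })
}
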