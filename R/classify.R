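#' Seeded stratified train/test split of a feature table
#'
#' Draws exactly `n_train_per_class` training rows and `n_test_per_class`
#' disjoint test rows from each class, by seeded sampling without
#' replacement. The default 150/150 per class mirrors a balanced 300-train
#' / 300-test protocol.
#'
#' @param features Data frame with a `label` column (two classes).
#' @param n_train_per_class,n_test_per_class Rows per class in each part.
#' @param seed Integer seed for the draw.
#' @return A list with data frames `train` and `test`.
#' @export
split_features <- function(features, n_train_per_class = 150L,
                           n_test_per_class = 150L, seed = 1L) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  labs <- unique(features$label)
  if (length(labs) != 2) stop("exactly two classes required")
  need <- n_train_per_class + n_test_per_class
  idx <- with_seed(seed, lapply(labs, function(l) {
    rows <- which(features$label == l)
    if (length(rows) < need)
      stop(sprintf("class '%s' has %d epochs, need %d (%d train + %d test)",
                   l, length(rows), need, n_train_per_class,
                   n_test_per_class))
    picked <- sample(rows, need)
    list(train = picked[seq_len(n_train_per_class)],
         test = picked[n_train_per_class + seq_len(n_test_per_class)])
  }))
  train <- features[sort(c(idx[[1]]$train, idx[[2]]$train)), , drop = FALSE]
  test <- features[sort(c(idx[[1]]$test, idx[[2]]$test)), , drop = FALSE]
  rownames(train) <- NULL; rownames(test) <- NULL
  list(train = train, test = test)
}

#' Confusion-matrix counts
#'
#' @param truth,predicted Vectors of class labels.
#' @param positive The label counted as positive.
#' @return A list of class `confusion_matrix` with counts `tn`, `fp`,
#'   `fn`, `tp`.
#' @export
confusion_matrix <- function(truth, predicted, positive) {
  tpos <- truth == positive
  ppos <- predicted == positive
  structure(list(tn = sum(!tpos & !ppos), fp = sum(!tpos & ppos),
                 fn = sum(tpos & !ppos), tp = sum(tpos & ppos),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (positive = %s)\n", x$positive))
  cat(sprintf("              predicted NO  predicted YES\n"))
  cat(sprintf("  actual NO  %12d  %13d\n", x$tn, x$fp))
  cat(sprintf("  actual YES %12d  %13d\n", x$fn, x$tp))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' `accuracy = (tp + tn) / total`, `sensitivity = tp / (tp + fn)` (recall
#' of the positive class), `specificity = tn / (tn + fp)` (recall of the
#' negative class). A metric whose denominator is zero is returned as `NA`
#' with a warning rather than silently as zero.
#'
#' @param cm A `confusion_matrix`, or `tn` given all four counts.
#' @param tn,fp,fn,tp Counts (used when `cm` is missing).
#' @return A list with `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' confusion_metrics(tn = 143, fp = 7, fn = 0, tp = 150)  # accuracy 293/300
#' @export
confusion_metrics <- function(cm = NULL, tn = NULL, fp = NULL, fn = NULL,
                              tp = NULL) {
  if (!is.null(cm)) {
    stopifnot(inherits(cm, "confusion_matrix"))
    tn <- cm$tn; fp <- cm$fp; fn <- cm$fn; tp <- cm$tp
  }
  total <- tn + fp + fn + tp
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  list(accuracy = (tp + tn) / total,
       sensitivity = safe_div(tp, tp + fn, "sensitivity"),
       specificity = safe_div(tn, tn + fp, "specificity"))
}

#' Train and evaluate an SVM on chaotic features
#'
#' Standardises the feature columns using training-set statistics only,
#' fits a C-classification support vector machine (radial kernel by
#' default) on the training rows, and evaluates on the held-out test rows.
#' Positive class is `"encephalopathy"` by convention.
#'
#' @param train,test Data frames from [split_features()] containing the
#'   feature columns and `label`.
#' @param feature_cols Feature columns used by the model.
#' @param positive Positive-class label.
#' @param kernel,cost,gamma SVM hyperparameters (passed to
#'   [e1071::svm()]; `gamma = NULL` uses 1/n_features).
#' @return A list of class `classifier_report`: `matrix`
#'   (a [confusion_matrix()]), `accuracy`, `sensitivity`, `specificity`,
#'   `model` (descriptor list) and the fitted `fit`.
#' @export
svm_classify <- function(train, test, feature_cols = c("cd", "lle"),
                         positive = "encephalopathy", kernel = "radial",
                         cost = 1, gamma = NULL) {
  stopifnot(all(feature_cols %in% names(train)),
            all(feature_cols %in% names(test)))
  if (length(unique(train$label)) < 2)
    stop("degenerate training set: only one class present")
  if (is.null(gamma)) gamma <- 1 / length(feature_cols)
  xtr <- as.matrix(train[, feature_cols, drop = FALSE])
  ctr <- colMeans(xtr)
  str_ <- apply(xtr, 2, sd)
  if (any(str_ == 0)) stop("a feature is constant on the training set")
  scale_mat <- function(x) sweep(sweep(x, 2, ctr), 2, str_, "/")
  ytr <- factor(train$label)
  fit <- e1071::svm(scale_mat(xtr), ytr, type = "C-classification",
                    kernel = kernel, cost = cost, gamma = gamma,
                    scale = FALSE)
  xte <- as.matrix(test[, feature_cols, drop = FALSE])
  pred <- predict(fit, scale_mat(xte))
  cm <- confusion_matrix(test$label, as.character(pred), positive)
  met <- confusion_metrics(cm)
  structure(c(list(matrix = cm), met,
              list(model = list(kernel = kernel, cost = cost, gamma = gamma,
                                scaling = "train-set z-score",
                                features = feature_cols),
                   fit = fit)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  print(x$matrix)
  cat(sprintf("  accuracy    %.2f%%  ((tp + tn) / total)\n", 100 * x$accuracy))
  cat(sprintf("  sensitivity %.2f%%  (tp / (tp + fn))\n", 100 * x$sensitivity))
  cat(sprintf("  specificity %.2f%%  (tn / (tn + fp))\n", 100 * x$specificity))
  cat(sprintf("  model: %s-kernel SVM, cost %g, gamma %g, %s\n",
              x$model$kernel, x$model$cost, x$model$gamma, x$model$scaling))
  invisible(x)
}
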