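#' Train a ski sub-technique recognizer
#'
#' Fits the classification stage of the pipeline: center standardization
#' of the feature matrix followed by a support vector machine with
#' calibrated class probabilities (`sign(w' k(x) + b)` decision per class
#' pair, Platt-scaled scores in \[0, 1\]). A k-nearest-neighbour model on
#' the same standardized features is kept alongside for optional score
#' fusion at prediction time. The kernel is radial by default with the
#' standard `1/d` bandwidth heuristic; a linear kernel is available.
#'
#' @param x numeric feature matrix (rows = cycles or sequences, columns =
#'   features as built by [build_feature_vector()]).
#' @param y class labels (factor or character; e.g. `"DP"`, `"DS"`, `"DT"`).
#' @param kernel `"radial"` or `"linear"`.
#' @param cost SVM cost parameter.
#' @param gamma radial-kernel bandwidth; default `1/ncol(x)`.
#' @param knn_k neighbours for the fused KNN vote (default 5, Euclidean).
#' @return object of class `ski_recognizer`: the fitted SVM, the
#'   standardizer, the retained training set for KNN, class levels, the
#'   frozen feature names and a feature-schema version.
#' @seealso [predict.ski_recognizer()], [cross_validate()]
#' @export
ski_recognizer <- function(x, y, kernel = c("radial", "linear"),
                           cost = 1, gamma = NULL, knn_k = 5) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("training error: need at least 2 classes")
  if (any(table(y) < 5)) {
    stop("training error: need at least 5 samples per class")
  }
  if (nrow(x) != length(y)) stop("x and y lengths differ")
  z <- center_standardize(x, fit = TRUE)
  std <- attr(z, "standardizer")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  svm_fit <- e1071::svm(z, y, kernel = kernel, cost = cost, gamma = gamma,
                        probability = TRUE, scale = FALSE)
  structure(
    list(svm = svm_fit, standardizer = std, train_z = z, train_y = y,
         levels = levels(y), knn_k = knn_k, kernel = kernel,
         feature_names = colnames(x),
         feature_version = "skitrax-features-1"),
    class = "ski_recognizer")
}

#' Predict sub-technique labels
#'
#' Standardizes `newdata` with the training-set parameters stored in the
#' model and scores it with the SVM. With `fuse_knn = TRUE` the calibrated
#' SVM class probabilities are averaged with the KNN vote fractions and
#' the fused argmax wins; an exact tie falls back to the SVM's class.
#'
#' @param object a [ski_recognizer()].
#' @param newdata raw (unstandardized) feature matrix with the training
#'   feature columns.
#' @param fuse_knn average SVM scores with KNN vote fractions.
#' @param ... unused.
#' @return list with `labels` (factor) and `scores` (matrix of per-class
#'   scores in \[0, 1\], rows summing to 1).
#' @export
predict.ski_recognizer <- function(object, newdata, fuse_knn = FALSE, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    stop("feature mismatch: columns differ from the training features")
  }
  if (ncol(newdata) != length(object$standardizer$mean)) {
    stop("feature mismatch: expected ", length(object$standardizer$mean),
         " columns, got ", ncol(newdata))
  }
  z <- center_standardize(newdata, fit = FALSE, params = object$standardizer)
  pr <- predict(object$svm, z, probability = TRUE)
  svm_scores <- attr(pr, "probabilities")[, object$levels, drop = FALSE]
  scores <- svm_scores
  if (fuse_knn) {
    knn_scores <- knn_vote_fractions(object$train_z, object$train_y, z,
                                     k = object$knn_k)[, object$levels,
                                                       drop = FALSE]
    scores <- (svm_scores + knn_scores) / 2
  }
  labels <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    best <- which(scores[i, ] == max(scores[i, ]))
    if (length(best) > 1) {
      svm_cls <- which.max(svm_scores[i, ])
      best <- if (svm_cls %in% best) svm_cls else best[1]
    }
    labels[i] <- object$levels[best]
  }
  list(labels = factor(labels, levels = object$levels), scores = scores)
}

# Per-class vote fractions of the k nearest training rows (Euclidean).
# Ties in distance keep earlier training rows, so results are stable.
knn_vote_fractions <- function(train_z, train_y, z, k = 5) {
  k <- min(k, nrow(train_z))
  out <- matrix(0, nrow(z), nlevels(train_y),
                dimnames = list(NULL, levels(train_y)))
  for (i in seq_len(nrow(z))) {
    d <- sqrt(colSums((t(train_z) - z[i, ])^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    tab <- table(train_y[nn]) / k
    out[i, names(tab)] <- as.numeric(tab)
  }
  out
}

#' @export
print.ski_recognizer <- function(x, ...) {
  cat("Ski sub-technique recognizer (", x$kernel, "-kernel SVM, ",
      length(x$levels), " classes: ", paste(x$levels, collapse = ", "),
      ")\n", sep = "")
  cat("  trained on ", nrow(x$train_z), " samples x ",
      ncol(x$train_z), " features\n", sep = "")
  invisible(x)
}

#' @export
summary.ski_recognizer <- function(object, ...) {
  print(object)
  cat("  support vectors:", object$svm$tot.nSV, "\n")
  cat("  class counts:", paste(names(table(object$train_y)),
                               table(object$train_y), collapse = ", "),
      "\n")
  invisible(object)
}

#' Stratified k-fold cross-validation with a final holdout
#'
#' Reserves `holdout` of the data (stratified) as a validation set,
#' splits the remaining pool into `k` stratified folds, and for each fold
#' trains on the other k-1 (standardization is fitted inside each
#' training split -- no leakage) and scores the held-out fold. The pooled
#' fold predictions give the confusion matrix. A final model trained on
#' the whole pool is evaluated once on the holdout.
#'
#' @param x raw feature matrix.
#' @param y class labels.
#' @param k number of folds (>= 2).
#' @param holdout fraction reserved for the final validation set
#'   (0 disables it).
#' @param seed integer seed controlling the fold assignment.
#' @param fuse_knn passed to [predict.ski_recognizer()].
#' @param ... passed to [ski_recognizer()].
#' @return list of class `ski_cv`: `mean_accuracy`, `fold_accuracy`,
#'   `confusion`, `holdout_accuracy`, `model` (fitted on the pool),
#'   `fold_of` (pool fold assignment).
#' @export
cross_validate <- function(x, y, k = 5, holdout = 0.10, seed = 1,
                           fuse_knn = FALSE, ...) {
  x <- as.matrix(x)
  y <- factor(y)
  if (k < 2) stop("need k >= 2 folds")
  set.seed(seed)
  n <- length(y)
  idx_holdout <- integer(0)
  if (holdout > 0) {
    for (cl in levels(y)) {
      ic <- which(y == cl)
      idx_holdout <- c(idx_holdout,
                       sample(ic, max(1, round(holdout * length(ic)))))
    }
  }
  pool <- setdiff(seq_len(n), idx_holdout)
  fold_of <- integer(n)
  for (cl in levels(y)) {
    ic <- sample(intersect(pool, which(y == cl)))
    if (length(ic) < k) {
      stop("stratification error: class '", cl,
           "' has fewer pool samples than folds")
    }
    fold_of[ic] <- rep_len(seq_len(k), length(ic))
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- pool[fold_of[pool] != f]
    te <- pool[fold_of[pool] == f]
    m <- ski_recognizer(x[tr, , drop = FALSE], y[tr], ...)
    p <- predict(m, x[te, , drop = FALSE], fuse_knn = fuse_knn)
    pred[te] <- p$labels
    fold_acc[f] <- mean(p$labels == y[te])
  }
  confusion <- table(truth = y[pool], predicted = pred[pool])
  model <- ski_recognizer(x[pool, , drop = FALSE], y[pool], ...)
  holdout_acc <- NA_real_
  if (length(idx_holdout)) {
    ph <- predict(model, x[idx_holdout, , drop = FALSE], fuse_knn = fuse_knn)
    holdout_acc <- mean(ph$labels == y[idx_holdout])
  }
  structure(list(mean_accuracy = mean(fold_acc), fold_accuracy = fold_acc,
                 confusion = confusion, holdout_accuracy = holdout_acc,
                 model = model, fold_of = fold_of),
            class = "ski_cv")
}

#' @export
print.ski_cv <- function(x, ...) {
  cat("Stratified ", length(x$fold_accuracy), "-fold cross-validation\n",
      sep = "")
  cat("  fold accuracies:",
      paste(sprintf("%.3f", x$fold_accuracy), collapse = " "), "\n")
  cat(sprintf("  mean accuracy: %.1f%%\n", 100 * x$mean_accuracy))
  if (!is.na(x$holdout_accuracy)) {
    cat(sprintf("  holdout accuracy: %.1f%%\n", 100 * x$holdout_accuracy))
  }
  cat("  confusion matrix (pooled fold predictions):\n")
  print(x$confusion)
  invisible(x)
}
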