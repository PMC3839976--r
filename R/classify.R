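#' Classifier specification
#'
#' @param method `"dadf"` (diagonal quadratic discriminant / Gaussian
#'   naive Bayes), `"knn"` or `"svm_linear"`.
#' @param k Neighbour count for `"knn"` (odd, >= 1; the study battery
#'   uses 1 and 3).
#' @param C Soft-margin cost for the linear SVM (default 1).
#' @param standardize Z-score features with training-fold statistics
#'   (default on for the SVM, off otherwise, mirroring the usual
#'   toolbox defaults).
#' @return An object of class `micf_classifier`.
#' @export
classifier_spec <- function(method = c("dadf", "knn", "svm_linear"),
                            k = 1, C = 1,
                            standardize = identical(method, "svm_linear")) {
  method <- match.arg(method)
  if (method == "knn") {
    if (k < 1 || k %% 2 == 0) stop("k must be odd and >= 1")
  }
  if (C <= 0) stop("C must be positive")
  label <- switch(method, dadf = "dadf",
                  knn = sprintf("knn_k%d", as.integer(k)),
                  svm_linear = "svm_linear")
  structure(list(method = method, k = as.integer(k), C = C,
                 standardize = standardize, label = label),
            class = "micf_classifier")
}

#' The study's default classifier battery
#' @return Named list of four [classifier_spec()] objects: DADF, knn
#'   with k = 1 and k = 3, and a linear SVM.
#' @export
default_classifiers <- function() {
  specs <- list(classifier_spec("dadf"),
                classifier_spec("knn", k = 1),
                classifier_spec("knn", k = 3),
                classifier_spec("svm_linear"))
  stats::setNames(specs, vapply(specs, `[[`, "", "label"))
}

degenerate_variance_failure <- function(msg) {
  structure(class = c("micf_degenerate_variance", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Diagonal quadratic discriminant (Gaussian naive Bayes) prediction
#'
#' Fits a per-class, per-feature Gaussian with class-specific mean and
#' variance, sums the log densities with the empirical log class priors,
#' and returns the argmax class. Any feature with zero within-class
#' variance raises a degenerate-variance failure (condition class
#' `micf_degenerate_variance`) rather than producing a fabricated
#' prediction. Ties are broken toward the larger-prior class, then
#' toward the first class level.
#'
#' @param train Training matrix (rows = trials).
#' @param labels Factor or character labels (2 classes).
#' @param test Numeric test row.
#' @return Predicted label (character scalar).
#' @export
dadf_train_predict <- function(train, labels, test) {
  train <- as.matrix(train)
  labels <- factor(labels)
  lev <- levels(labels)
  score <- numeric(length(lev))
  prior <- as.numeric(table(labels)[lev]) / length(labels)
  for (ci in seq_along(lev)) {
    X <- train[labels == lev[ci], , drop = FALSE]
    mu <- colMeans(X)
    v <- apply(X, 2, stats::var)
    if (any(v == 0))
      stop(degenerate_variance_failure(sprintf(
        "zero within-class variance in class '%s'", lev[ci])))
    score[ci] <- sum(stats::dnorm(test, mu, sqrt(v), log = TRUE)) +
      log(prior[ci])
  }
  best <- which(score == max(score))
  if (length(best) > 1) best <- best[which.max(prior[best])]
  lev[best]
}

#' k-nearest-neighbour prediction (Euclidean metric)
#'
#' Majority label among the `k` nearest training rows. Distance ties are
#' broken deterministically by the lower training-row index; a vote tie
#' falls back to the label of the single nearest neighbour.
#'
#' @param train Training matrix.
#' @param labels Training labels.
#' @param test Test row.
#' @param k Neighbour count (<= number of training rows).
#' @return Predicted label.
#' @export
knn_predict <- function(train, labels, test, k) {
  train <- as.matrix(train)
  stopifnot(k <= nrow(train))
  d <- sqrt(rowSums(sweep(train, 2, test)^2))
  nn <- order(d)[seq_len(k)]          # order() is stable: lower index wins
  votes <- table(labels[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) as.character(labels[nn[1]]) else top
}

#' Linear soft-margin SVM prediction
#'
#' Trains `e1071::svm` with a linear kernel and cost `C`; features are
#' z-scored with training-fold statistics when `standardize` is set
#' (zero-variance columns are left uncentered-unscaled rather than
#' divided by zero).
#'
#' @param train Training matrix.
#' @param labels Training labels (both classes present).
#' @param test Test row.
#' @param C Cost parameter.
#' @param standardize Z-score using training statistics (default TRUE).
#' @return Predicted label.
#' @export
svm_linear_train_predict <- function(train, labels, test, C = 1,
                                     standardize = TRUE) {
  train <- as.matrix(train)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("both classes must be present in the training set")
  test <- matrix(test, nrow = 1)
  if (standardize) {
    mu <- colMeans(train)
    s <- apply(train, 2, stats::sd)
    s[s == 0] <- 1
    train <- scale(train, center = mu, scale = s)
    test <- scale(test, center = mu, scale = s)
  }
  fit <- e1071::svm(train, labels, kernel = "linear", cost = C,
                    scale = FALSE)
  as.character(stats::predict(fit, test))
}

predict_one <- function(spec, train, labels, test) {
  switch(spec$method,
    dadf = dadf_train_predict(train, labels, test),
    knn = knn_predict(train, labels, test, spec$k),
    svm_linear = svm_linear_train_predict(train, labels, test, spec$C,
                                          spec$standardize))
}

#' Leave-one-out cross-validated classification of one feature matrix
#'
#' Each trial is predicted once by a model trained on all remaining
#' trials; the accuracy is the fraction of correct predictions.
#' Chance-level statistics (proportional chance criterion, z, p, and the
#' improvement-over-chance effect size) are attached from the retained
#' per-condition trial counts. Degenerate feature matrices and
#' classifier failures yield a failed result carrying the reason, never
#' a fabricated accuracy.
#'
#' @param features A `micf_features` matrix.
#' @param spec A [classifier_spec()].
#' @param compat_pdf Passed to [improvement_z()]; if `TRUE`, p-values
#'   reproduce the literal normal-density convention.
#' @return An object of class `micf_clf_result`.
#' @export
loocv <- function(features, spec, compat_pdf = FALSE) {
  stopifnot(inherits(features, "micf_features"),
            inherits(spec, "micf_classifier"))
  base <- list(feature_name = features$feature_name,
               classifier = spec$label,
               subject_id = features$subject_id,
               group_tag = features$group_tag)
  fail <- function(reason)
    structure(c(base, list(failed = TRUE, reason = reason,
                           predicted = NULL, n_correct = NA_integer_,
                           N = length(features$condition),
                           accuracy = NA_real_, cpro = NA_real_,
                           z = NA_real_, p = NA_real_, iocc = NA_real_)),
              class = "micf_clf_result")
  if (isTRUE(features$degenerate))
    return(fail("degenerate feature matrix"))
  y <- features$condition
  if (min(table(y)) < 2) return(fail("fewer than 2 trials per condition"))
  X <- features$values
  N <- nrow(X)
  pred <- character(N)
  for (t in seq_len(N)) {
    res <- tryCatch(
      predict_one(spec, X[-t, , drop = FALSE], y[-t], X[t, ]),
      micf_degenerate_variance = function(e) e,
      error = function(e) e)
    if (inherits(res, "condition")) {
      reason <- if (inherits(res, "micf_degenerate_variance"))
        paste("degenerate variance:", conditionMessage(res))
      else paste("classifier failure:", conditionMessage(res))
      return(fail(reason))
    }
    pred[t] <- res
  }
  n_correct <- sum(pred == y)
  n1 <- sum(y == "imagery"); n2 <- sum(y == "rest")
  st <- chance_stats(n_correct, n1, n2, compat_pdf = compat_pdf)
  structure(c(base, list(failed = FALSE, reason = NA_character_,
                         predicted = pred, n_correct = n_correct, N = N,
                         accuracy = n_correct / N, cpro = st$cpro,
                         z = st$z, p = st$p, iocc = st$iocc)),
            class = "micf_clf_result")
}

#' @export
print.micf_clf_result <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<micf_clf_result> %s / %s: FAILED (%s)\n",
                x$feature_name, x$classifier, x$reason))
  } else {
    cat(sprintf(
      "<micf_clf_result> %s / %s: accuracy %.3f (%d/%d), Cpro %.3f, z %.2f, p %.4f, IOCC %.3f\n",
      x$feature_name, x$classifier, x$accuracy, x$n_correct, x$N,
      x$cpro, x$z, x$p, x$iocc))
  }
  invisible(x)
}

# one result -> one row of the study results table
result_row <- function(x) {
  data.frame(subject = x$subject_id %||% NA_character_,
             group = x$group_tag %||% NA_character_,
             feature = x$feature_name, classifier = x$classifier,
             N = x$N, n_correct = x$n_correct, accuracy = x$accuracy,
             cpro = x$cpro, z = x$z, p = x$p, iocc = x$iocc,
             failed = x$failed, reason = x$reason,
             stringsAsFactors = FALSE)
}
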