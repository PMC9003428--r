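#' Train a classifier
#'
#' The three classifiers of the evaluation protocol:
#' \describe{
#'   \item{`lda_diag`}{Gaussian classes with a shared, pooled *diagonal*
#'     covariance (per-feature variances floored at 1e-9 to tolerate
#'     degenerate features) and empirical class priors.}
#'   \item{`logreg`}{binary logistic regression fitted by IRLS with a weak
#'     L2 penalty (1e-4, intercept unpenalised) purely for numerical
#'     stability on separable data.}
#'   \item{`svm_rbf`}{soft-margin SVM with Gaussian kernel
#'     `exp(-gamma ||u - v||^2)`, `C = 1`,
#'     `gamma = 1 / (P * var(features))` (overall feature variance),
#'     via \pkg{e1071}.}
#' }
#'
#' @param kind one of `"lda_diag"`, `"logreg"`, `"svm_rbf"`.
#' @param features numeric matrix (observations x features) or a
#'   [build_feature_table()] result.
#' @param labels class labels, length = observations; exactly 2 classes
#'   with >= 2 observations each.
#' @return a classifier object with a `predict` method taking a feature
#'   matrix and returning labels.
#' @export
train_classifier <- function(kind = c("lda_diag", "logreg", "svm_rbf"),
                             features, labels) {
  kind <- match.arg(kind)
  X <- if (inherits(features, "feature_table")) features$matrix
       else as.matrix(features)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("one label per observation required")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training data contains a single class")
  if (any(table(labels) < 2L)) stop("each class needs >= 2 observations")

  model <- switch(kind,
    lda_diag = {
      mu <- t(vapply(classes, function(cl)
        colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
      centred <- X - mu[match(labels, classes), , drop = FALSE]
      v <- pmax(colSums(centred^2) / (nrow(X) - length(classes)), 1e-9)
      list(mu = mu, var = v,
           log_prior = log(as.numeric(table(factor(labels, classes))) / nrow(X)))
    },
    logreg = {
      yb <- as.numeric(labels == classes[2])
      Xi <- cbind(1, X)
      beta <- numeric(ncol(Xi))
      pen <- c(0, rep(1e-4, ncol(X)))
      for (it in 1:100) {
        eta <- as.numeric(Xi %*% beta)
        p <- 1 / (1 + exp(-eta))
        wgt <- pmax(p * (1 - p), 1e-10)
        H <- crossprod(Xi, Xi * wgt) + diag(pen, ncol(Xi))
        g <- crossprod(Xi, yb - p) - pen * beta
        step <- solve(H, g)
        beta <- beta + step
        if (max(abs(step)) < 1e-10) break
      }
      list(beta = as.numeric(beta))
    },
    svm_rbf = {
      gamma <- 1 / (ncol(X) * mean((X - mean(X))^2))
      e1071::svm(X, factor(labels, classes), kernel = "radial",
                 cost = 1, gamma = gamma, scale = FALSE)
    })
  structure(list(kind = kind, classes = classes, model = model,
                 p = ncol(X)),
            class = "bci_classifier")
}

#' @export
predict.bci_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$matrix
       else as.matrix(newdata)
  if (ncol(X) != object$p) stop("feature dimension mismatch")
  cls <- object$classes
  m <- object$model
  switch(object$kind,
    lda_diag = {
      scores <- vapply(seq_along(cls), function(k) {
        d <- sweep(X, 2, m$mu[k, ])
        -0.5 * rowSums(sweep(d^2, 2, m$var, "/")) + m$log_prior[k]
      }, numeric(nrow(X)))
      cls[max.col(scores, ties.method = "first")]
    },
    logreg = {
      eta <- as.numeric(cbind(1, X) %*% m$beta)
      ifelse(eta > 0, cls[2], cls[1])
    },
    svm_rbf = as.character(stats::predict(m, X)))
}

#' Deterministic stratified fold assignment
#'
#' Observations of each class are shuffled with a seed-derived RNG stream
#' and dealt round-robin into `k` folds, so every fold holds a near-equal
#' share of each class and the assignment is reproducible.
#'
#' @param labels class label per observation.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.character(labels)
  if (any(table(labels) < k))
    stop("every class needs at least k = ", k,
         " observations; use a smaller k")
  fold <- integer(length(labels))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated accuracy
#'
#' Pooled accuracy over stratified folds: each fold is held out once, the
#' classifier is trained on the remainder, and accuracy is
#' `100 * correct / total` pooled over all held-out predictions.
#'
#' @param kind classifier kind, as in [train_classifier()].
#' @param features observations x features matrix or [build_feature_table()].
#' @param labels class labels (if `features` is a feature table, defaults
#'   to its `obs_labels`).
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return accuracy in percent (0..100).
#' @export
kfold_accuracy <- function(kind, features, labels = NULL, k = 5, seed = 1) {
  X <- if (inherits(features, "feature_table")) features$matrix
       else as.matrix(features)
  if (is.null(labels) && inherits(features, "feature_table"))
    labels <- features$obs_labels
  labels <- as.character(labels)
  fold <- stratified_folds(labels, k, seed)
  correct <- 0L
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- train_classifier(kind, X[!te, , drop = FALSE], labels[!te])
    correct <- correct + sum(predict(fit, X[te, , drop = FALSE]) == labels[te])
  }
  100 * correct / length(labels)
}

#' Aggregate per-subject accuracies into a report
#'
#' @param per_subject numeric matrix or data frame, subjects x classifiers,
#'   of accuracies in percent; no missing cells allowed.
#' @param comparisons optional list of length-2 character vectors naming
#'   classifier pairs to compare with [paired_test()]; the Bonferroni
#'   correction divides `alpha` by the number of comparisons.
#' @param alpha family-wise significance level (default 0.05).
#' @return object of class `classification_report` with `per_subject`,
#'   `means` (unrounded column means), `comparisons` and
#'   `alpha_corrected`.
#' @export
aggregate_report <- function(per_subject, comparisons = NULL, alpha = 0.05) {
  m <- as.matrix(per_subject)
  if (anyNA(m)) stop("missing accuracy cell(s) in the subject grid")
  if (any(m < 0 | m > 100)) stop("accuracies must lie in [0, 100]")
  means <- colMeans(m)
  comp <- NULL
  if (!is.null(comparisons)) {
    nc <- length(comparisons)
    comp <- do.call(rbind, lapply(comparisons, function(pr) {
      tt <- paired_test(m[, pr[1]], m[, pr[2]], n_comparisons = nc,
                        alpha = alpha)
      data.frame(pair = paste(pr, collapse = " vs "),
                 statistic = tt$t, p_value = tt$p,
                 significant = tt$significant)
    }))
  }
  structure(list(per_subject = m, means = means, comparisons = comp,
                 alpha_corrected = if (is.null(comparisons)) alpha
                                   else alpha / length(comparisons)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n  mean accuracy (%):\n")
  print(round(x$means, 2))
  if (!is.null(x$comparisons)) {
    cat(sprintf("  paired comparisons (corrected alpha = %.4g):\n",
                x$alpha_corrected))
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Paired two-tailed t-test with Bonferroni threshold
#'
#' Tests whether two classifiers' per-subject accuracies differ, declaring
#' significance at `alpha / n_comparisons` (e.g. 0.05 / 3 = 0.0167 for the
#' standard three-way comparison).
#'
#' @param acc_a,acc_b equal-length (>= 3) per-subject accuracy vectors.
#' @param n_comparisons number of tests in the family (default 3).
#' @param alpha family-wise level (default 0.05).
#' @return list with `t`, `p`, `significant`, and `alpha_corrected`.
#' @export
paired_test <- function(acc_a, acc_b, n_comparisons = 3, alpha = 0.05) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 3L)
    stop("need equal-length vectors of at least 3 subjects")
  d <- acc_a - acc_b
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences; t statistic undefined")
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  thr <- alpha / n_comparisons
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < thr, alpha_corrected = thr)
}
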