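#' Stratified k-fold assignment
#'
#' Assigns samples to `k` cross-validation folds so that each fold's class
#' proportions are within one sample of the global proportions: each class
#' is dealt out evenly, with remainders sent to the folds that currently
#' hold the fewest samples. Deterministic given `seed`.
#'
#' @param labels A vector of class labels (two classes for this pipeline,
#'   but any number is accepted).
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the shuffle within classes.
#' @return An integer vector in `1:k`, one entry per sample.
#' @examples
#' table(stratified_folds(rep(c("benign", "malignant"), each = 13), seed = 0))
#' @export
stratified_folds <- function(labels, k = 5L, seed = 0L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class must have at least k = ", k, " members", call. = FALSE)
  }
  fold <- integer(length(labels))
  fold_tot <- integer(k)
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      base <- n_c %/% k
      rem <- n_c %% k
      sizes <- rep(base, k)
      if (rem > 0L) {
        # remainders go to the currently smallest folds (ties: lowest index)
        recv <- order(fold_tot, seq_len(k))[seq_len(rem)]
        sizes[recv] <- sizes[recv] + 1L
      }
      fold[idx] <- rep(seq_len(k), times = sizes)
      fold_tot <- fold_tot + sizes
    }
  })
  fold
}

#' Binomial standard error of a classification accuracy
#'
#' The standard error of a binomial proportion evaluated at the (already
#' rounded) printed accuracy: `100 * sqrt(p (1 - p) / n)` with
#' `p = ca_percent / 100`, reported to one decimal. This is the "CA +/- Std"
#' convention used when quoting pooled cross-validated accuracies.
#'
#' @param ca_percent Accuracy in percent, in `[0, 100]`.
#' @param n Number of classified samples.
#' @return The standard error in percentage points, rounded to one decimal.
#' @examples
#' binomial_se(92.3, 26)  # 5.2
#' binomial_se(99.3, 140) # 0.7
#' @export
binomial_se <- function(ca_percent, n) {
  stopifnot(ca_percent >= 0, ca_percent <= 100, n >= 1)
  p <- ca_percent / 100
  round(100 * sqrt(p * (1 - p) / n), 1)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the curve of true-positive rate against
#' false-positive rate over all score thresholds, with tied scores averaged
#' — numerically identical to the Mann-Whitney rank statistic
#' P(score_pos > score_neg) + P(equal)/2.
#'
#' @param scores Real-valued scores for the positive class, one per sample.
#' @param labels Binary labels; the positive class is `"malignant"` if the
#'   labels are characters/factors, otherwise the larger of the two values.
#' @return The AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs at least one sample of each class", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    as.character(labels) == "malignant"
  } else {
    labels == max(labels)
  }
}

#' Cross-validated classification of topological features
#'
#' Runs one cell of the evaluation: fits the requested classifier on each
#' training fold (features standardized by the training fold's mean and
#' standard deviation only), pools the out-of-fold predictions and scores
#' over all samples, and summarises them as pooled accuracy (with binomial
#' SE), AUC and the confusion matrix with malignant as the positive class.
#'
#' The four classifier kinds mirror a standard benchmarking setup:
#' `"nn"` a single-hidden-layer 25-unit ReLU network, `"svm"` a linear
#' soft-margin SVM with box constraint 1, `"knn"` 1-nearest-neighbour with
#' Euclidean distance, `"dt"` a Gini-split decision tree. The 1-NN score is
#' its 0/1 predicted label (a discrete classifier has no graded score).
#'
#' @param features A data frame of numeric feature columns (e.g. `pi`,
#'   `pe`), one row per image.
#' @param labels Class labels, coercible to the two levels
#'   `c("benign", "malignant")`.
#' @param classifier One of `"nn"`, `"svm"`, `"knn"`, `"dt"`.
#' @param folds Optional fold assignment from [stratified_folds()]; built
#'   from `seed` when omitted.
#' @param k Number of folds when `folds` is omitted.
#' @param seed Integer seed for fold assignment and network initialisation.
#' @return An object of class `"topo_cv"`; see [glance.topo_cv()] and
#'   [tidy.topo_cv()].
#' @examples
#' x <- data.frame(pi = c(rnorm(10, 0), rnorm(10, 8)))
#' y <- rep(c("benign", "malignant"), each = 10)
#' glance(run_cv(x, y, classifier = "knn", seed = 1))
#' @export
run_cv <- function(features, labels, classifier = c("nn", "svm", "knn", "dt"),
                   folds = NULL, k = 5L, seed = 0L) {
  classifier <- match.arg(classifier)
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  y <- factor(as.character(labels), levels = c("benign", "malignant"))
  if (anyNA(y)) stop("labels must be 'benign' or 'malignant'", call. = FALSE)
  if (is.null(folds)) folds <- stratified_folds(y, k = k, seed = seed)
  stopifnot(length(folds) == nrow(x), length(y) == nrow(x))
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
  score <- numeric(nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) {
      stop("degenerate fold: training split contains a single class",
           call. = FALSE)
    }
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2L, sd)
    sg[sg == 0] <- 1
    xtr <- scale(x[tr, , drop = FALSE], mu, sg)
    xte <- scale(x[!tr, , drop = FALSE], mu, sg)
    res <- fit_and_score(classifier, xtr, y[tr], xte,
                         seed = seed * 131L + f)
    pred[!tr] <- res$pred
    score[!tr] <- res$score
  }
  tp <- sum(pred == "malignant" & y == "malignant")
  tn <- sum(pred == "benign" & y == "benign")
  fp <- sum(pred == "malignant" & y == "benign")
  fn <- sum(pred == "benign" & y == "malignant")
  ca <- 100 * (tp + tn) / length(y)
  structure(list(
    classifier = classifier,
    n = length(y),
    ca_percent = ca,
    ca_se_percent = binomial_se(round(ca, 1), length(y)),
    auc = roc_auc(score, y),
    confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
    predictions = tibble(truth = y, predicted = pred, score = score,
                         fold = folds)
  ), class = "topo_cv")
}

#' @export
print.topo_cv <- function(x, ...) {
  cat(sprintf(
    "Cross-validated %s: CA %.1f +/- %.1f %%, AUC %.2f (n = %d)\n",
    toupper(x$classifier), x$ca_percent, x$ca_se_percent, x$auc, x$n))
  cm <- x$confusion
  cat(sprintf("  confusion: TP %d  TN %d  FP %d  FN %d\n",
              cm["tp"], cm["tn"], cm["fp"], cm["fn"]))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' `tidy()` returns the pooled confusion matrix in long form (one row per
#' true/predicted class combination); `glance()` returns a one-row summary
#' with accuracy, its binomial SE, AUC and the confusion counts.
#'
#' @param x A `"topo_cv"` object from [run_cv()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.topo_cv <- function(x, ...) {
  cm <- x$confusion
  tibble(
    truth = c("malignant", "benign", "benign", "malignant"),
    predicted = c("malignant", "benign", "malignant", "benign"),
    n = as.integer(cm[c("tp", "tn", "fp", "fn")])
  )
}

#' @rdname tidy.topo_cv
#' @export
glance.topo_cv <- function(x, ...) {
  cm <- x$confusion
  tibble(
    classifier = x$classifier,
    n = x$n,
    ca = x$ca_percent,
    ca_se = x$ca_se_percent,
    auc = x$auc,
    tp = as.integer(cm["tp"]), tn = as.integer(cm["tn"]),
    fp = as.integer(cm["fp"]), fn = as.integer(cm["fn"])
  )
}

#' ROC curve of a cross-validation result
#'
#' @param object A `"topo_cv"` object.
#' @param ... Unused.
#' @return A ggplot of the pooled out-of-fold ROC curve.
#' @export
autoplot.topo_cv <- function(object, ...) {
  pr <- object$predictions
  pos <- pr$truth == "malignant"
  ord <- order(-pr$score)
  tpr <- c(0, cumsum(pos[ord]) / sum(pos))
  fpr <- c(0, cumsum(!pos[ord]) / sum(!pos))
  df <- tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s: AUC %.2f", toupper(object$classifier),
                      object$auc)
    )
}
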