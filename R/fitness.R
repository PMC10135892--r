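#' Wrapper cost weights
#'
#' The wrapper objective is `I = omega * (1 - accuracy) +
#' sigma * (n_selected / n_total)`, minimized over subsets. The default
#' weights 0.99 / 0.01 make classification error dominate while still
#' rewarding smaller subsets.
#'
#' @param omega weight on the error term (default 0.99).
#' @param sigma weight on the feature-fraction term (default 0.01).
#' @return Object of class `fitness_weights`.
#' @export
fitness_weights <- function(omega = 0.99, sigma = 0.01) {
  if (omega < 0 || sigma < 0) stop("weights must be >= 0", call. = FALSE)
  structure(list(omega = omega, sigma = sigma), class = "fitness_weights")
}

#' Classifier configuration for the wrapper
#'
#' The wrapper trains a support vector machine on each candidate subset.
#' Defaults: linear kernel, cost C = 1, per-feature standardization fitted
#' on the training fold only — a fast, conventional choice for
#' high-dimensional deep features.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C regularization parameter (> 0).
#' @param scaling `"standardize"` or `"none"`.
#' @param seed integer seed (the SVM fit itself is deterministic; the seed
#'   is kept for provenance).
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(kernel = c("linear", "rbf"), C = 1,
                              scaling = c("standardize", "none"), seed = 1L) {
  kernel <- match.arg(kernel)
  scaling <- match.arg(scaling)
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  structure(list(kernel = kernel, C = C, scaling = scaling,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Wrapper cost of a subset
#'
#' `I = omega * (1 - accuracy) + sigma * (n_selected / n_total)`. Lower is
#' better; with the default weights `I` lies in `[0, 1]` for accuracy in
#' `[0, 1]`.
#'
#' @param accuracy validation accuracy in `[0, 1]`.
#' @param n_selected number of selected features (>= 1).
#' @param n_total total number of features.
#' @param weights a [fitness_weights()].
#' @return Object of class `fitness_value`: list with `I`, `accuracy`,
#'   `n_selected`, `n_total`.
#' @export
#' @examples
#' fitness(0.946, 651, 1920)$I  # 0.056850625
fitness <- function(accuracy, n_selected, n_total, weights = fitness_weights()) {
  if (is.na(accuracy) || accuracy < 0 || accuracy > 1)
    stop("accuracy must lie in [0, 1]", call. = FALSE)
  if (n_selected < 1 || n_selected > n_total)
    stop("empty-subset error: need 1 <= n_selected <= n_total", call. = FALSE)
  I <- weights$omega * (1 - accuracy) + weights$sigma * (n_selected / n_total)
  structure(list(I = I, accuracy = accuracy,
                 n_selected = as.integer(n_selected),
                 n_total = as.integer(n_total)),
            class = "fitness_value")
}

#' @export
print.fitness_value <- function(x, ...) {
  cat(sprintf("<fitness> I=%.6f  accuracy=%.3f  features=%d/%d\n",
              x$I, x$accuracy, x$n_selected, x$n_total))
  invisible(x)
}

# worst attainable cost: used for empty subsets inside optimizer loops so
# the search can continue instead of erroring
worst_fitness <- function(n_total, weights = fitness_weights()) {
  structure(list(I = weights$omega + weights$sigma, accuracy = 0,
                 n_selected = as.integer(n_total), n_total = as.integer(n_total)),
            class = "fitness_value")
}

# strict "a is better than b" under the search's tie-breaking:
# lower cost, then fewer selected features; remaining ties keep b (earlier)
fitness_better <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$I < b$I) return(TRUE)
  if (a$I > b$I) return(FALSE)
  a$n_selected < b$n_selected
}

# train the configured SVM on x[train,], predict on x[val,]
svm_val_accuracy <- function(x, y, train, val, clf) {
  xtr <- x[train, , drop = FALSE]
  ytr <- droplevels(factor(y[train]))
  if (nlevels(ytr) < 2L)
    stop("single-class training fold; cannot train classifier", call. = FALSE)
  scale_cols <- if (clf$scaling == "standardize")
    apply(xtr, 2L, stats::sd) > 1e-12 else rep(FALSE, ncol(xtr))
  fit <- e1071::svm(x = xtr, y = ytr,
                    kernel = if (clf$kernel == "linear") "linear" else "radial",
                    cost = clf$C, scale = scale_cols)
  pred <- stats::predict(fit, x[val, , drop = FALSE])
  mean(as.character(pred) == as.character(y[val]))
}

#' Evaluate one feature subset with the wrapper
#'
#' Trains the classifier on the training indices of the masked table,
#' measures validation accuracy under the given split, and scores the
#' subset with [fitness()]. For k-fold splits the accuracy is the mean
#' over folds. The same split should be reused across every subset
#' evaluated in one optimizer run so costs are comparable. An all-zero
#' mask returns the worst possible cost (`omega + sigma`) rather than
#' raising, so optimizer loops remain total.
#'
#' @param table a [feature_table()].
#' @param labels factor of class labels aligned with the table rows.
#' @param mask a [subset_mask()] over the table's columns.
#' @param split a [split_spec()] or a materialized split from
#'   [make_split()].
#' @param clf a [classifier_config()].
#' @param weights a [fitness_weights()].
#' @return A `fitness_value`.
#' @export
evaluate_subset <- function(table, labels, mask, split = split_spec(),
                            clf = classifier_config(),
                            weights = fitness_weights()) {
  stopifnot(inherits(table, "feature_table"), inherits(mask, "subset_mask"))
  if (mask$n_total != n_features(table))
    stop("mask length does not match table", call. = FALSE)
  if (mask$n_selected == 0L) return(worst_fitness(mask$n_total, weights))
  if (inherits(split, "split_spec")) split <- make_split(labels, split)
  x <- table$values[, which(mask$bits == 1L), drop = FALSE]
  y <- factor(labels)
  if (!is.null(split$folds)) {
    accs <- vapply(seq_along(split$folds), function(f) {
      val <- split$folds[[f]]
      svm_val_accuracy(x, y, setdiff(seq_len(nrow(x)), val), val, clf)
    }, numeric(1))
    acc <- mean(accs)
  } else {
    acc <- svm_val_accuracy(x, y, split$train, split$validation, clf)
  }
  fitness(acc, mask$n_selected, mask$n_total, weights)
}

#' Memoizing subset evaluator
#'
#' Wraps [evaluate_subset()] for a fixed table/labels/split/classifier so
#' an optimizer can call it once per candidate mask: re-evaluating an
#' identical mask is a cache hit and performs no retraining. The split is
#' materialized once up front and reused for every subset, so all costs in
#' a run are measured on the same validation data.
#'
#' @param table,labels,split,clf,weights as in [evaluate_subset()].
#' @return A function `f(bits)` (0/1 vector or [subset_mask()]) returning
#'   a `fitness_value`, with helper attributes readable via
#'   [evaluator_counts()].
#' @export
cached_evaluator <- function(table, labels, split = split_spec(),
                             clf = classifier_config(),
                             weights = fitness_weights()) {
  split <- if (inherits(split, "split_spec")) make_split(labels, split) else split
  cache <- new.env(parent = emptyenv())
  n_calls <- 0L
  n_trainings <- 0L
  f <- function(bits) {
    if (inherits(bits, "subset_mask")) bits <- bits$bits
    bits <- as.integer(bits)
    n_calls <<- n_calls + 1L
    key <- paste(bits, collapse = "")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    n_trainings <<- n_trainings + 1L
    fv <- evaluate_subset(table, labels, subset_mask_fast(bits), split, clf, weights)
    assign(key, fv, envir = cache)
    fv
  }
  attr(f, "counts") <- function() list(calls = n_calls, trainings = n_trainings)
  class(f) <- c("subset_evaluator", "function")
  f
}

# mask constructor without the 0-feature error (evaluate_subset handles it)
subset_mask_fast <- function(bits) {
  structure(list(bits = bits, n_selected = sum(bits), n_total = length(bits)),
            class = "subset_mask")
}

#' Call/training counters of a cached evaluator
#' @param evaluator a function from [cached_evaluator()].
#' @return list with `calls` (total invocations) and `trainings` (distinct
#'   masks actually trained).
#' @export
evaluator_counts <- function(evaluator) {
  cf <- attr(evaluator, "counts")
  if (is.null(cf)) stop("not a cached evaluator", call. = FALSE)
  cf()
}
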