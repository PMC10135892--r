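#' Class labels for a feature table
#'
#' @param labels vector of class labels, one per sample.
#' @param class_names ordered vector of the distinct classes; defaults to
#'   the sorted unique labels.
#' @return A factor with levels `class_names`.
#' @export
label_vector <- function(labels, class_names = NULL) {
  if (is.null(class_names)) class_names <- sort(unique(as.character(labels)))
  y <- factor(as.character(labels), levels = class_names)
  if (anyNA(y))
    stop("labels contain values outside `class_names`", call. = FALSE)
  y
}

#' Load labels from a two-column CSV
#'
#' @param path CSV with header `sample_id,label`.
#' @return Named factor (names are sample ids).
#' @export
load_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df)))
    stop("labels file must have columns sample_id,label", call. = FALSE)
  y <- label_vector(df$label)
  names(y) <- df$sample_id
  y
}

#' Train/validation split specification
#'
#' Two schemes are supported: a single holdout split (validation fraction
#' 0.2 by default) and k-fold cross-validation (k = 5 by default), both
#' stratified by class by default. For a stratified holdout the validation
#' set receives `round(fraction * class size)` samples of each class
#' (half-up rounding), so 826 samples at fraction 0.2 put 165 in
#' validation.
#'
#' @param scheme `"holdout"` or `"kfold"`.
#' @param fraction holdout validation fraction in (0, 1).
#' @param k number of folds (>= 2).
#' @param stratified stratify by class?
#' @param seed integer seed controlling the random assignment.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(scheme = c("holdout", "kfold"), fraction = 0.2, k = 5L,
                       stratified = TRUE, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "holdout" && (fraction <= 0 || fraction >= 1))
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  if (scheme == "kfold" && k < 2L) stop("`k` must be >= 2", call. = FALSE)
  structure(list(scheme = scheme, fraction = fraction, k = as.integer(k),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_spec")
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Materialize a train/validation split
#'
#' Deterministic given the spec's seed. Holdout returns disjoint,
#' exhaustive `train` and `validation` index sets; k-fold returns `k`
#' disjoint folds covering all indices.
#'
#' @param labels factor of class labels (see [label_vector()]).
#' @param spec a [split_spec()].
#' @return For holdout, `list(train=, validation=)` of integer indices;
#'   for k-fold, `list(folds = list(...))`.
#' @export
make_split <- function(labels, spec) {
  stopifnot(inherits(spec, "split_spec"))
  labels <- as.factor(labels)
  n <- length(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("need >= 2 classes present to split for training", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  if (spec$scheme == "holdout") {
    if (spec$stratified) {
      val <- integer(0)
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        if (length(idx) == 0L) next
        if (length(idx) < 2L)
          stop("class '", cl, "' too small for stratified holdout", call. = FALSE)
        n_val <- round_half_up(spec$fraction * length(idx))
        n_val <- max(1L, min(length(idx) - 1L, as.integer(n_val)))
        val <- c(val, sample(idx, n_val))
      }
    } else {
      n_val <- max(1L, min(n - 1L, as.integer(round_half_up(spec$fraction * n))))
      val <- sample(seq_len(n), n_val)
    }
    val <- sort(val)
    list(train = setdiff(seq_len(n), val), validation = val)
  } else {
    k <- spec$k
    assign_fold <- integer(n)
    if (spec$stratified) {
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        if (length(idx) == 0L) next
        if (length(idx) < k)
          stop("class '", cl, "' has fewer samples than k = ", k, call. = FALSE)
        assign_fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      assign_fold[sample(seq_len(n))] <- rep_len(seq_len(k), n)
    }
    list(folds = lapply(seq_len(k), function(f) which(assign_fold == f)))
  }
}
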