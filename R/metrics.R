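#' Confusion matrix
#'
#' Counts with true classes in rows and predicted classes in columns, over
#' a shared ordered class set.
#'
#' @param y_true,y_pred factors (or vectors) of equal length; predictions
#'   must come from the true label's class set.
#' @param class_names optional ordered class set; defaults to the levels of
#'   `y_true`.
#' @return Object of class `confusion_matrix`: list with integer `counts`
#'   (K x K, dimnames set) and `class_names`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_names = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (is.null(class_names))
    class_names <- if (is.factor(y_true)) levels(y_true) else sort(unique(as.character(y_true)))
  y_true <- factor(as.character(y_true), levels = class_names)
  bad <- !(as.character(y_pred) %in% class_names)
  if (any(bad))
    stop("unknown predicted class: ", paste(unique(as.character(y_pred)[bad]), collapse = ", "),
         call. = FALSE)
  y_pred <- factor(as.character(y_pred), levels = class_names)
  counts <- table(true = y_true, predicted = y_pred)
  counts <- matrix(as.integer(counts), nrow = length(class_names),
                   dimnames = list(true = class_names, predicted = class_names))
  structure(list(counts = counts, class_names = class_names),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#' @param counts square integer matrix (rows = true class).
#' @param class_names ordered class names; default from dimnames or `c1..cK`.
#' @return A [confusion_matrix()] object.
#' @export
confusion_from_counts <- function(counts, class_names = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(class_names)) {
    class_names <- rownames(counts)
    if (is.null(class_names)) class_names <- paste0("c", seq_len(nrow(counts)))
  }
  m <- matrix(as.integer(counts), nrow = nrow(counts),
              dimnames = list(true = class_names, predicted = class_names))
  structure(list(counts = m, class_names = class_names),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Per-class rates from a confusion matrix
#'
#' For each class: true positive rate TPR = TP / (row total), false
#' negative rate FNR = FN / (row total), positive predictive value
#' PPV = TP / (column total), false discovery rate FDR = FP / (column
#' total), all as percentages, plus the overall accuracy
#' 100 * trace / total. Exact complements hold before rounding:
#' TPR + FNR = 100 and PPV + FDR = 100. Display values are rounded
#' half-up to one decimal (so 3 false negatives out of 80 give FNR 3.8);
#' full precision is kept in the `*_exact` columns. A class with an empty
#' row (no true samples) has undefined TPR/FNR; an empty column (never
#' predicted) has undefined PPV/FDR — both surface as `NA` with the
#' `undefined` flag set, never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @param digits display rounding (default 1 decimal).
#' @return A data.frame with one row per class: `class`, `TPR`, `FNR`,
#'   `PPV`, `FDR` (rounded percentages), their `*_exact` counterparts,
#'   and `undefined`; overall accuracy attached as attributes
#'   `accuracy` (rounded) and `accuracy_exact`.
#' @export
class_metrics <- function(cm, digits = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$counts
  tp <- diag(m)
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  tpr <- ifelse(row_tot > 0, 100 * tp / row_tot, NA_real_)
  fnr <- ifelse(row_tot > 0, 100 * (row_tot - tp) / row_tot, NA_real_)
  ppv <- ifelse(col_tot > 0, 100 * tp / col_tot, NA_real_)
  fdr <- ifelse(col_tot > 0, 100 * (col_tot - tp) / col_tot, NA_real_)
  out <- data.frame(
    class = cm$class_names,
    TPR = round_half_up(tpr, digits), FNR = round_half_up(fnr, digits),
    PPV = round_half_up(ppv, digits), FDR = round_half_up(fdr, digits),
    TPR_exact = tpr, FNR_exact = fnr, PPV_exact = ppv, FDR_exact = fdr,
    undefined = row_tot == 0 | col_tot == 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "accuracy_exact") <- overall_accuracy(cm, digits = NULL)
  attr(out, "accuracy") <- round_half_up(attr(out, "accuracy_exact"), digits)
  out
}

#' Overall classification accuracy (percent)
#'
#' @param cm a [confusion_matrix()] with at least one sample.
#' @param digits decimals for half-up display rounding; `NULL` for full
#'   precision.
#' @return Accuracy percentage, `100 * trace / total`.
#' @export
overall_accuracy <- function(cm, digits = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  acc <- 100 * sum(diag(cm$counts)) / total
  if (is.null(digits)) acc else round_half_up(acc, digits)
}

#' Write per-class metrics in the standard report layout
#'
#' Columns: Validation, Class, TPR(%), FNR(%), PPV(%), FDR(%), Accuracy(%)
#' (accuracy printed on the first row of each validation block).
#'
#' @param metrics_list named list of [class_metrics()] results, one per
#'   validation scheme (names become the Validation column).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics_list, path) {
  rows <- lapply(names(metrics_list), function(v) {
    m <- metrics_list[[v]]
    data.frame(Validation = c(v, rep("", nrow(m) - 1L)),
               Class = m$class,
               `TPR(%)` = m$TPR, `FNR(%)` = m$FNR,
               `PPV(%)` = m$PPV, `FDR(%)` = m$FDR,
               `Accuracy(%)` = c(attr(m, "accuracy"), rep(NA, nrow(m) - 1L)),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
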