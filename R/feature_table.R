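#' Construct a feature table
#'
#' A feature table holds a numeric matrix of deep-feature activations
#' (samples in rows, features in columns) together with sample and feature
#' identifiers and the name of the backbone network the features came from.
#' It is the unit that subset masks are applied to and that the selection
#' pipeline concatenates.
#'
#' @param values numeric matrix, `n_samples x n_features`; all entries must
#'   be finite.
#' @param sample_ids character vector of row identifiers; defaults to
#'   existing rownames or `"s1", "s2", ...`.
#' @param feature_ids character vector of unique column identifiers;
#'   defaults to existing colnames or `"<network>:<index>"`.
#' @param network single string tagging the source network (e.g.
#'   `"DenseNet-201"`); purely a label.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `values`, `sample_ids`, `feature_ids`, `network`.
#' @export
#' @examples
#' ft <- feature_table(matrix(rnorm(12), 3, 4), network = "netA")
#' dim(ft)
feature_table <- function(values, sample_ids = NULL, feature_ids = NULL,
                          network = "unknown") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("feature table contains non-finite values (NA/NaN/Inf)", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids))
      feature_ids <- paste0(network, ":", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values))
    stop("length of `sample_ids` does not match number of rows", call. = FALSE)
  if (length(feature_ids) != ncol(values))
    stop("length of `feature_ids` does not match number of columns", call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("`feature_ids` must be unique within a table", call. = FALSE)
  dimnames(values) <- NULL
  structure(
    list(values = values,
         sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids),
         network = as.character(network)[1]),
    class = "feature_table"
  )
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> network=%s  %d samples x %d features\n",
              x$network, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Number of features / samples in a feature table
#' @param table a [feature_table()]
#' @return integer count.
#' @export
n_features <- function(table) ncol(table$values)

#' @rdname n_features
#' @export
n_samples <- function(table) nrow(table$values)

#' Read a feature table from disk
#'
#' Two on-disk forms are supported: `"delimited"` — a UTF-8 CSV whose first
#' row holds the feature identifiers and whose first column holds the sample
#' identifiers — and `"rds"`, R's native serialization of the whole object
#' (bit-exact round trip).
#'
#' @param path file to read.
#' @param format `"delimited"` or `"rds"`; default guesses from the file
#'   extension (`.rds` vs anything else).
#' @param network network tag to attach (delimited format only; the rds
#'   format stores its own).
#' @return A validated [feature_table()].
#' @export
load_feature_table <- function(path, format = c("auto", "delimited", "rds"),
                               network = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "delimited"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "rds") {
    obj <- readRDS(path)
    if (!inherits(obj, "feature_table"))
      stop("rds file does not contain a feature_table: ", path, call. = FALSE)
    if (!is.null(network)) obj$network <- network
    return(feature_table(obj$values, obj$sample_ids, obj$feature_ids, obj$network))
  }

  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L || !nzchar(lines[1]))
    stop("malformed header: first row must list feature identifiers", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header: expected sample-id column plus >=1 feature column",
         call. = FALSE)
  feat_ids <- header[-1]
  nfeat <- length(feat_ids)
  body <- lines[-1]
  body <- body[nzchar(body)]
  samp <- character(length(body))
  vals <- matrix(NA_real_, length(body), nfeat)
  for (i in seq_along(body)) {
    cells <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(cells) != nfeat + 1L)
      stop(sprintf("parse error at data row %d: expected %d values, found %d",
                   i, nfeat, length(cells) - 1L), call. = FALSE)
    samp[i] <- cells[1]
    v <- suppressWarnings(as.numeric(cells[-1]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("parse error at data row %d, column '%s': non-numeric cell '%s'",
                   i, feat_ids[bad], cells[bad + 1L]), call. = FALSE)
    }
    vals[i, ] <- v
  }
  if (any(!is.finite(vals)))
    stop("validation error: non-finite values in feature table", call. = FALSE)
  if (is.null(network)) network <- "unknown"
  feature_table(vals, samp, feat_ids, network)
}

#' Write a feature table to disk
#'
#' @param table a [feature_table()].
#' @param path destination file.
#' @param format `"delimited"` (CSV, values printed at full double
#'   precision) or `"rds"` (bit-exact).
#' @return `path`, invisibly.
#' @export
save_feature_table <- function(table, path, format = c("auto", "delimited", "rds")) {
  stopifnot(inherits(table, "feature_table"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "delimited"
  if (format == "rds") {
    saveRDS(table, path)
    return(invisible(path))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("sample_id", table$feature_ids), collapse = ","), con)
  txt <- apply(table$values, 1L, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = ","))
  writeLines(paste(table$sample_ids, txt, sep = ","), con)
  invisible(path)
}

#' Restrict a feature table to a masked subset of columns
#'
#' Keeps exactly the columns whose mask bit is 1, preserving the original
#' column order and carrying feature identifiers over, so masks remain
#' comparable across runs.
#'
#' @param table a [feature_table()].
#' @param mask a [subset_mask()] with `n_total == n_features(table)` and at
#'   least one selected feature.
#' @return A [feature_table()] with `mask$n_selected` columns.
#' @export
apply_mask <- function(table, mask) {
  stopifnot(inherits(table, "feature_table"), inherits(mask, "subset_mask"))
  if (mask$n_total != n_features(table))
    stop(sprintf("dimension error: mask length %d != table features %d",
                 mask$n_total, n_features(table)), call. = FALSE)
  if (mask$n_selected == 0L)
    stop("empty-subset error: mask selects no features", call. = FALSE)
  keep <- which(mask$bits == 1L)
  feature_table(table$values[, keep, drop = FALSE],
                table$sample_ids, table$feature_ids[keep], table$network)
}

#' Concatenate feature tables column-wise
#'
#' All tables must carry identical sample identifiers in identical order;
#' samples are aligned by identifier equality, never silently reordered.
#' Feature identifiers keep their network prefixes so provenance of every
#' column in the concatenated table is recoverable.
#'
#' @param tables list of [feature_table()] objects.
#' @param network network tag for the result (default: input tags joined
#'   with `"+"`).
#' @return A [feature_table()] whose feature count is the sum of the
#'   inputs' feature counts.
#' @export
concat_tables <- function(tables, network = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  lapply(tables, function(t) stopifnot(inherits(t, "feature_table")))
  ids <- tables[[1]]$sample_ids
  for (t in tables[-1]) {
    if (length(t$sample_ids) != length(ids) || !all(t$sample_ids == ids))
      stop("alignment error: sample_ids differ between tables (no silent reordering)",
           call. = FALSE)
  }
  if (length(tables) == 1L) return(tables[[1]])
  if (is.null(network))
    network <- paste(vapply(tables, `[[`, "", "network"), collapse = "+")
  feature_table(do.call(cbind, lapply(tables, `[[`, "values")),
                ids,
                unlist(lapply(tables, `[[`, "feature_ids")),
                network)
}
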