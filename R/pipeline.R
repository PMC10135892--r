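#' Run every optimizer on one network's feature table
#'
#' Each requested algorithm gets its own seeded run against a shared
#' memoizing evaluator (same split, classifier and weights), so costs are
#' comparable across algorithms. Per-algorithm seeds are derived from the
#' master seed by a fixed counter scheme (`master + 1000 * position of the
#' algorithm in the full algorithm list`), so adding or dropping an
#' algorithm does not perturb the others' random streams.
#'
#' @param table a [feature_table()].
#' @param labels factor of class labels aligned with the table.
#' @param algorithms character vector of algorithm names (default all
#'   eight, see [wbm_algorithms()]).
#' @param split a [split_spec()] used for every subset evaluation.
#' @param clf a [classifier_config()].
#' @param weights a [fitness_weights()].
#' @param iterations,pop_size optimizer budget (defaults 50 and 10).
#' @param seed master seed for this network.
#' @return Object of class `network_result`: list with `network_name`,
#'   `per_optimizer` (named list of `mask`, `accuracy`, `fitness`,
#'   `evaluations`), and `best_algorithm` (maximum accuracy; ties broken
#'   by lower cost, then fewer features).
#' @export
optimize_network <- function(table, labels, algorithms = wbm_algorithms(),
                             split = split_spec(), clf = classifier_config(),
                             weights = fitness_weights(),
                             iterations = 50L, pop_size = 10L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), length(algorithms) >= 1L)
  if (length(labels) != n_samples(table))
    stop("labels not aligned with table", call. = FALSE)
  evaluator <- cached_evaluator(table, labels, split, clf, weights)
  per <- list()
  for (alg in algorithms) {
    alg_seed <- derive_seed(seed, match(alg, wbm_algorithms()))
    cfg <- optimizer_config(alg, iterations = iterations,
                            pop_size = pop_size, seed = alg_seed)
    res <- run_optimizer(cfg, evaluator, n_features(table))
    per[[alg]] <- list(mask = res$best_mask,
                       accuracy = res$best_fitness$accuracy,
                       fitness = res$best_fitness,
                       evaluations = res$history$evaluations_used)
  }
  structure(list(network_name = table$network,
                 per_optimizer = per,
                 best_algorithm = best_algorithm(per)),
            class = "network_result")
}

derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 1000 * counter) %% 2147483647)
}

best_algorithm <- function(per) {
  best <- NULL
  for (alg in names(per)) {
    e <- per[[alg]]
    if (is.null(best)) { best <- alg; next }
    b <- per[[best]]
    if (e$accuracy > b$accuracy ||
        (e$accuracy == b$accuracy && e$fitness$I < b$fitness$I) ||
        (e$accuracy == b$accuracy && e$fitness$I == b$fitness$I &&
         e$mask$n_selected < b$mask$n_selected))
      best <- alg
  }
  best
}

#' @export
print.network_result <- function(x, ...) {
  cat(sprintf("<network_result> %s  best: %s (accuracy %.3f)\n",
              x$network_name, x$best_algorithm,
              x$per_optimizer[[x$best_algorithm]]$accuracy))
  invisible(x)
}

#' Summarize search results as a data frame
#'
#' One row per (network, algorithm) with the best accuracy and subset size
#' found — the layout in which published per-network search grids are
#' reported, and the input format [select_networks()] accepts.
#'
#' @param results list of `network_result` objects.
#' @return data.frame with columns `network`, `algorithm`, `accuracy`,
#'   `n_selected`.
#' @export
results_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(network = r$network_name,
               algorithm = names(r$per_optimizer),
               accuracy = vapply(r$per_optimizer, function(e) e$accuracy, 0),
               n_selected = vapply(r$per_optimizer,
                                   function(e) e$mask$n_selected, 0L),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select networks whose best search accuracy clears a threshold
#'
#' For each network the winning optimizer is the one with maximum accuracy
#' (ties: lower cost, then fewer features). A network survives iff its
#' winner's accuracy *strictly* exceeds the threshold (default 0.94, i.e.
#' "greater than 94%"); survivors keep their input order.
#'
#' @param results either a list of `network_result` objects or a
#'   data.frame with columns `network`, `algorithm`, `accuracy` (and
#'   optionally `n_selected`), one row per network/algorithm pair.
#' @param threshold accuracy cut, strict inequality (default 0.94).
#' @return data.frame of survivors: `network`, `algorithm`, `accuracy`,
#'   `n_selected` (NA when unknown); masks attached as the `"masks"`
#'   attribute when `results` carries them.
#' @export
select_networks <- function(results, threshold = 0.94) {
  if (is.data.frame(results)) {
    df <- results
    if (!all(c("network", "algorithm", "accuracy") %in% names(df)))
      stop("need columns network, algorithm, accuracy", call. = FALSE)
    if (is.null(df$n_selected)) df$n_selected <- NA_integer_
    masks <- NULL
  } else {
    df <- results_table(results)
    masks <- list()
    for (r in results)
      for (alg in names(r$per_optimizer))
        masks[[paste(r$network_name, alg, sep = "|")]] <-
          r$per_optimizer[[alg]]$mask
  }
  networks <- unique(df$network)
  keep <- list()
  for (nw in networks) {
    sub <- df[df$network == nw, , drop = FALSE]
    ord <- order(-sub$accuracy, sub$n_selected)
    win <- sub[ord[1], , drop = FALSE]
    if (win$accuracy > threshold) keep[[nw]] <- win
  }
  if (length(keep) == 0L)
    stop("no network exceeded the selection threshold ", threshold,
         "; consider lowering it", call. = FALSE)
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  if (!is.null(masks)) {
    attr(out, "masks") <- lapply(seq_len(nrow(out)), function(i)
      masks[[paste(out$network[i], out$algorithm[i], sep = "|")]])
  }
  out
}

#' Full wrapper-selection pipeline over a bank of feature tables
#'
#' Runs [optimize_network()] on every table in the bank, applies the
#' accuracy-threshold selection rule, masks and concatenates the surviving
#' tables, trains the final classifier under both a holdout and a k-fold
#' scheme, and reports per-class metrics for each — with full provenance
#' (config and seeds) so the run can be replayed identically.
#'
#' @param feature_bank named list of [feature_table()] objects, all
#'   sample-aligned with `labels`.
#' @param labels factor of class labels.
#' @param algorithms algorithms to run per network.
#' @param threshold selection threshold on best accuracy (strict).
#' @param split search-time [split_spec()] (holdout by default).
#' @param final_k folds for the final cross-validated evaluation.
#' @param clf a [classifier_config()].
#' @param weights a [fitness_weights()].
#' @param iterations,pop_size optimizer budget.
#' @param seed master seed; per-network seeds are derived by a counter
#'   scheme (`seed + 100000 * network index`).
#' @return Object of class `selection_report`: list with `threshold`,
#'   `results` (per-network `network_result`s), `selected` (survivor
#'   table), `masks`, `concatenated_size`, `final_metrics` (named list of
#'   [class_metrics()] per validation scheme), `final_accuracy`, and
#'   `provenance`.
#' @export
run_wbm_pipeline <- function(feature_bank, labels,
                             algorithms = wbm_algorithms(), threshold = 0.94,
                             split = split_spec(), final_k = 5L,
                             clf = classifier_config(),
                             weights = fitness_weights(),
                             iterations = 50L, pop_size = 10L, seed = 1L) {
  stopifnot(is.list(feature_bank), length(feature_bank) >= 1L)
  results <- list()
  for (i in seq_along(feature_bank)) {
    tab <- feature_bank[[i]]
    results[[i]] <- optimize_network(
      tab, labels, algorithms = algorithms, split = split, clf = clf,
      weights = weights, iterations = iterations, pop_size = pop_size,
      seed = derive_seed(seed, 100L * i))
  }
  selected <- select_networks(results, threshold)
  masks <- attr(selected, "masks")

  bank_by_name <- stats::setNames(
    feature_bank, vapply(feature_bank, `[[`, "", "network"))
  masked <- lapply(seq_len(nrow(selected)), function(i)
    apply_mask(bank_by_name[[selected$network[i]]], masks[[i]]))
  concatenated <- concat_tables(masked)

  full_mask <- subset_mask(rep(1L, n_features(concatenated)))
  schemes <- list(
    holdout = split_spec("holdout", fraction = split$fraction,
                         stratified = split$stratified, seed = split$seed),
    kfold = split_spec("kfold", k = final_k,
                       stratified = split$stratified, seed = split$seed))
  final_metrics <- list()
  final_accuracy <- list()
  for (s in names(schemes)) {
    cm <- pipeline_confusion(concatenated, labels, schemes[[s]], clf)
    final_metrics[[s]] <- class_metrics(cm)
    final_accuracy[[s]] <- overall_accuracy(cm, digits = NULL)
  }

  structure(list(
    threshold = threshold,
    results = results,
    selected = selected,
    masks = masks,
    concatenated_size = sum(vapply(masks, function(m) m$n_selected, 0L)),
    per_network_accuracy = stats::setNames(selected$accuracy, selected$network),
    final_metrics = final_metrics,
    final_accuracy = final_accuracy,
    provenance = list(seed = seed, threshold = threshold,
                      algorithms = algorithms, iterations = iterations,
                      pop_size = pop_size, split = split, clf = clf,
                      weights = weights, final_k = final_k,
                      networks = names(bank_by_name))),
    class = "selection_report")
}

# pooled confusion matrix for the final model under one validation scheme
pipeline_confusion <- function(table, labels, spec, clf) {
  y <- factor(labels)
  sp <- make_split(y, spec)
  x <- table$values
  if (!is.null(sp$folds)) {
    yt <- character(0); yp <- character(0)
    for (val in sp$folds) {
      tr <- setdiff(seq_len(nrow(x)), val)
      pred <- svm_predictions(x, y, tr, val, clf)
      yt <- c(yt, as.character(y[val])); yp <- c(yp, pred)
    }
    confusion_matrix(factor(yt, levels = levels(y)), yp, levels(y))
  } else {
    pred <- svm_predictions(x, y, sp$train, sp$validation, clf)
    confusion_matrix(factor(as.character(y[sp$validation]), levels = levels(y)),
                     pred, levels(y))
  }
}

svm_predictions <- function(x, y, train, val, clf) {
  xtr <- x[train, , drop = FALSE]
  ytr <- droplevels(factor(y[train]))
  scale_cols <- if (clf$scaling == "standardize")
    apply(xtr, 2L, stats::sd) > 1e-12 else rep(FALSE, ncol(xtr))
  fit <- e1071::svm(x = xtr, y = ytr,
                    kernel = if (clf$kernel == "linear") "linear" else "radial",
                    cost = clf$C, scale = scale_cols)
  as.character(stats::predict(fit, x[val, , drop = FALSE]))
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> threshold %.2f  survivors: %s\n",
              x$threshold, paste(x$selected$network, collapse = ", ")))
  cat(sprintf("  concatenated features: %d\n", x$concatenated_size))
  for (s in names(x$final_accuracy))
    cat(sprintf("  final accuracy (%s): %.1f%%\n", s, x$final_accuracy[[s]]))
  invisible(x)
}

#' Path to the bundled published search-grid table
#'
#' A CSV of best accuracy and subset size per (backbone network,
#' optimizer) pair from a published brain-MRI deep-feature search grid of
#' 16 networks by 8 optimizers; useful as input to [select_networks()].
#'
#' @return File path of the CSV inside the installed package.
#' @export
published_search_grid <- function() {
  system.file("extdata", "published_search_grid.csv", package = "wbmfs",
              mustWork = TRUE)
}
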