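#' Binary feature-inclusion mask
#'
#' The subset a wrapper search proposes: a 0/1 vector over a table's
#' columns. `n_selected / n_total` is the size fraction penalized by the
#' wrapper cost.
#'
#' @param bits vector coercible to 0/1 integers.
#' @return An object of class `subset_mask` with elements `bits`,
#'   `n_selected`, `n_total`.
#' @export
#' @examples
#' subset_mask(c(1, 0, 1, 1))
subset_mask <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) == 0L) stop("mask must have length >= 1", call. = FALSE)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("mask bits must be 0 or 1", call. = FALSE)
  structure(list(bits = bits,
                 n_selected = sum(bits),
                 n_total = length(bits)),
            class = "subset_mask")
}

#' @export
print.subset_mask <- function(x, ...) {
  cat(sprintf("<subset_mask> %d of %d features selected\n",
              x$n_selected, x$n_total))
  invisible(x)
}

#' Mask from selected column indices
#' @param indices 1-based indices of the selected columns.
#' @param n_total total number of columns.
#' @return A [subset_mask()].
#' @export
mask_from_indices <- function(indices, n_total) {
  stopifnot(all(indices >= 1L), all(indices <= n_total))
  bits <- integer(n_total)
  bits[indices] <- 1L
  subset_mask(bits)
}

#' Serialize / deserialize a mask as JSON
#'
#' The JSON form records the network tag, the total width, and the 0-based
#' indices of the selected columns.
#'
#' @param mask a [subset_mask()].
#' @param path destination / source file.
#' @param network network tag stored alongside the mask.
#' @return `save_mask` returns `path` invisibly; `load_mask` returns a
#'   [subset_mask()] with a `"network"` attribute.
#' @export
save_mask <- function(mask, path, network = "unknown") {
  stopifnot(inherits(mask, "subset_mask"))
  obj <- list(network = network,
              n_total = mask$n_total,
              selected_indices = which(mask$bits == 1L) - 1L)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- mask_from_indices(as.integer(obj$selected_indices) + 1L,
                         as.integer(obj$n_total))
  attr(m, "network") <- obj$network
  m
}
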