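#' Threshold a grayscale image into a binary foreground mask
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold. With `threshold = NULL` an automatic Otsu threshold
#' (maximizing between-class variance of the intensity histogram) is used.
#'
#' @param image numeric matrix of intensities (rows = image rows, origin
#'   top-left).
#' @param threshold scalar threshold, or `NULL` for Otsu.
#' @return Logical matrix of the same shape.
#' @export
binarize <- function(image, threshold = NULL) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  image > threshold
}

#' Otsu threshold of an intensity matrix
#' @param image numeric matrix.
#' @param n_bins histogram resolution (default 256).
#' @return Scalar threshold on the image's own intensity scale.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)  # constant image: everything <= threshold
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  centers[which.max(sigma_b)]
}

check_struct <- function(struct) {
  stopifnot(is.matrix(struct))
  struct <- struct != 0
  if (!any(struct)) stop("structuring element is empty", call. = FALSE)
  if (nrow(struct) %% 2L == 0L || ncol(struct) %% 2L == 0L)
    stop("structuring element must have odd side lengths (origin at center)",
         call. = FALSE)
  struct
}

#' Square structuring element
#' @param size odd side length (default 3).
#' @return Logical `size x size` matrix of `TRUE`.
#' @export
struct_square <- function(size = 3L) {
  if (size %% 2L == 0L) stop("size must be odd", call. = FALSE)
  matrix(TRUE, size, size)
}

# shared translate-and-combine engine on the bounded image grid; pixels
# beyond the border count as foreground for erosion and background for
# dilation, the convention under which erosion/dilation duality holds
# exactly on the window
morph_apply <- function(mask, struct, erode) {
  struct <- check_struct(struct)
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  oi <- (nrow(struct) + 1L) %/% 2L
  oj <- (ncol(struct) + 1L) %/% 2L
  acc <- matrix(erode, H, W)
  for (si in seq_len(nrow(struct))) {
    for (sj in seq_len(ncol(struct))) {
      if (!struct[si, sj]) next
      di <- si - oi; dj <- sj - oj
      shifted <- matrix(erode, H, W)  # border padding
      r_dst <- max(1, 1 - di):min(H, H - di)
      c_dst <- max(1, 1 - dj):min(W, W - dj)
      shifted[r_dst, c_dst] <- mask[r_dst + di, c_dst + dj]
      acc <- if (erode) acc & shifted else acc | shifted
    }
  }
  acc
}

#' Binary erosion
#'
#' A pixel survives iff the structuring element, centered on it, covers no
#' background pixel of the image (positions beyond the border are treated
#' as foreground, the window convention under which erosion and dilation
#' are exact duals). Output foreground is a subset of the input foreground
#' for any element containing its origin.
#'
#' @param mask logical (or 0/1) matrix.
#' @param struct structuring element with odd side lengths; default 3x3
#'   square.
#' @return Logical matrix.
#' @export
morph_erode <- function(mask, struct = struct_square()) {
  morph_apply(mask, struct, erode = TRUE)
}

#' Binary dilation
#'
#' Union of the foreground translated by every offset of the (reflected)
#' structuring element; adds pixels at object borders.
#'
#' @inheritParams morph_erode
#' @return Logical matrix.
#' @export
morph_dilate <- function(mask, struct = struct_square()) {
  # dilation with struct S = union of translates by -s for s in S;
  # reuse the engine with the reflected element
  s <- check_struct(struct)
  refl <- s[rev(seq_len(nrow(s))), rev(seq_len(ncol(s))), drop = FALSE]
  morph_apply(mask, refl, erode = FALSE)
}

#' Morphological opening for speckle removal
#'
#' `iterations` erosions followed by the same number of dilations with the
#' same structuring element. Removes connected speckles smaller than the
#' element while preserving larger structures; anti-extensive and
#' idempotent (for `iterations = 1`).
#'
#' @inheritParams morph_erode
#' @param iterations erosion/dilation repetitions (default 2).
#' @return Logical matrix.
#' @export
denoise_open <- function(mask, struct = struct_square(), iterations = 2L) {
  out <- mask != 0
  for (k in seq_len(iterations)) out <- morph_erode(out, struct)
  for (k in seq_len(iterations)) out <- morph_dilate(out, struct)
  out
}

#' Extreme foreground points of a binary mask
#'
#' Returns the topmost, bottommost, leftmost and rightmost foreground
#' pixels (0-based row/col coordinates, origin top-left); ties are broken
#' toward the smallest orthogonal coordinate.
#'
#' @param mask logical (or 0/1) matrix with at least one foreground pixel.
#' @return Object of class `extreme_points`: list of `top`, `bottom`,
#'   `left`, `right`, each `c(row, col)` 0-based.
#' @export
find_extreme_points <- function(mask) {
  mask <- mask != 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty-foreground error: mask has no foreground pixels", call. = FALSE)
  r <- idx[, 1]; c <- idx[, 2]
  pick <- function(keep) {
    sub <- idx[keep, , drop = FALSE]
    sub <- sub[order(sub[, 1], sub[, 2]), , drop = FALSE]
    as.integer(sub[1, ] - 1L)
  }
  structure(list(
    top    = pick(r == min(r)),
    bottom = pick(r == max(r)),
    left   = pick(c == min(c)),
    right  = pick(c == max(c))),
    class = "extreme_points")
}

#' Crop to the extreme-point bounding box and resize
#'
#' Crops the inclusive box `[top-margin, bottom+margin] x [left-margin,
#' right+margin]` (clamped to the image), then resizes to `out_size` with
#' bilinear interpolation on the corner-aligned grid, so resizing a crop
#' to its own size is the identity.
#'
#' @param image numeric intensity matrix.
#' @param pts an `extreme_points` object from [find_extreme_points()].
#' @param out_size integer `c(H, W)` of the output.
#' @param margin pixels of context added on every side (default 0).
#' @return Numeric `out_size` matrix.
#' @export
crop_and_resize <- function(image, pts, out_size, margin = 0L) {
  stopifnot(inherits(pts, "extreme_points"), length(out_size) == 2L,
            all(out_size >= 1L))
  r0 <- max(0L, pts$top[1] - margin)
  r1 <- min(nrow(image) - 1L, pts$bottom[1] + margin)
  c0 <- max(0L, pts$left[2] - margin)
  c1 <- min(ncol(image) - 1L, pts$right[2] + margin)
  if (r1 < r0 || c1 < c0)
    stop("degenerate crop box after clamping", call. = FALSE)
  crop <- image[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), drop = FALSE]
  resize_bilinear(crop, out_size[1], out_size[2])
}

#' Bilinear resize of an intensity matrix
#'
#' Corner-aligned sampling: output pixel `(i, j)` samples the source at
#' `((i-1) * (H-1)/(Hout-1), (j-1) * (W-1)/(Wout-1))`, interpolated
#' bilinearly. Identity when the sizes match; a single-row/column source
#' is replicated.
#'
#' @param image numeric matrix.
#' @param H,W output dimensions.
#' @return Numeric `H x W` matrix.
#' @export
resize_bilinear <- function(image, H, W) {
  hs <- nrow(image); ws <- ncol(image)
  ri <- if (H == 1L) rep(0, H) else (seq_len(H) - 1) * (hs - 1) / (H - 1)
  ci <- if (W == 1L) rep(0, W) else (seq_len(W) - 1) * (ws - 1) / (W - 1)
  r0 <- pmin(floor(ri), hs - 1); r1 <- pmin(r0 + 1, hs - 1)
  c0 <- pmin(floor(ci), ws - 1); c1 <- pmin(c0 + 1, ws - 1)
  fr <- ri - r0; fc <- ci - c0
  a <- image[r0 + 1, c0 + 1, drop = FALSE]
  b <- image[r1 + 1, c0 + 1, drop = FALSE]
  cc <- image[r0 + 1, c1 + 1, drop = FALSE]
  d <- image[r1 + 1, c1 + 1, drop = FALSE]
  FR <- matrix(fr, H, W)
  FC <- matrix(fc, H, W, byrow = TRUE)
  a * (1 - FR) * (1 - FC) + b * FR * (1 - FC) + cc * (1 - FR) * FC + d * FR * FC
}

#' Crop a brain region out of a grayscale scan
#'
#' The full preprocessing chain: threshold (Otsu unless given), remove
#' speckle noise by morphological opening, locate the extreme points of
#' the remaining foreground, crop their bounding box with a margin, and
#' resize to a backbone's input size.
#'
#' @param image numeric intensity matrix.
#' @param threshold scalar or `NULL` (Otsu).
#' @param struct structuring element (default 3x3 square).
#' @param open_iterations erosion/dilation repetitions (default 2).
#' @param margin crop margin in pixels (default 0).
#' @param out_size output `c(H, W)` (default `c(224, 224)`).
#' @return List with `image` (the cropped, resized matrix), `points`
#'   (the extreme points) and `mask` (the denoised foreground).
#' @export
preprocess_scan <- function(image, threshold = NULL, struct = struct_square(),
                            open_iterations = 2L, margin = 0L,
                            out_size = c(224L, 224L)) {
  mask <- binarize(image, threshold)
  mask <- denoise_open(mask, struct, open_iterations)
  pts <- find_extreme_points(mask)
  list(image = crop_and_resize(image, pts, out_size, margin),
       points = pts, mask = mask)
}

#' Read / write a grayscale image
#'
#' PNG and single-frame TIFF are supported; color inputs are averaged to
#' one channel. Intensities are on `[0, 1]`.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @return `read_gray_image`: numeric intensity matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", path, call. = FALSE)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' @rdname read_gray_image
#' @param image numeric matrix with intensities in `[0, 1]`.
#' @param path destination file.
#' @return `write_gray_image`: `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(image, path)
  } else stop("unsupported image format: ", path, call. = FALSE)
  invisible(path)
}
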