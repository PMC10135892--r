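#' Specification of a synthetic deep-feature bank
#'
#' Emulates the structure of multi-network deep-feature banks extracted
#' from brain-MRI scans: for each "network" a samples-by-features Gaussian
#' matrix in which a small planted subset of informative columns carries
#' class-dependent mean shifts, optional redundant columns are noisy
#' copies of informative ones, and the rest is pure noise.
#'
#' Class mean patterns over the informative columns are fixed
#' deterministically from the class count `K` and the number of
#' informative columns `m`:
#' * if `m >= K - 1`, class 1 is a zero baseline and class `k > 1` is
#'   shifted by `effect_size * noise_sd` on informative column
#'   `k - 1` (cycled if `m > K - 1`), so every informative column is
#'   necessary to separate some pair of classes;
#' * otherwise (needs `2^m >= K`) class `k` uses the binary code of
#'   `k - 1` over the `m` columns, so classes are separable with few
#'   strongly informative columns.
#'
#' The default dimensions are a desk-scale analogue of published
#' deep-feature banks (tables of 1920 or 1280 columns do not enumerate or
#' test well): four classes of 60 samples, two networks of 64 and 48
#' features with 3 informative each.
#'
#' @param n_per_class integer vector (optionally named by class) of
#'   samples per class.
#' @param networks named integer vector of feature dimensions per network.
#' @param n_informative informative columns per network (single value or
#'   named vector); placed at the first columns of each table.
#' @param effect_size class-mean separation in units of `noise_sd`
#'   (default 3).
#' @param redundancy noisy copies per informative column (default 0).
#' @param noise_sd standard deviation of the Gaussian noise (default 1).
#' @param seed integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(glioma = 60, meningioma = 60,
                                           no_tumor = 60, pituitary = 60),
                           networks = c(netA = 64L, netB = 48L),
                           n_informative = 3L, effect_size = 3,
                           redundancy = 0L, noise_sd = 1, seed = 1L) {
  if (length(n_per_class) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (is.null(names(n_per_class)))
    names(n_per_class) <- paste0("class", seq_along(n_per_class))
  if (is.null(names(networks)))
    names(networks) <- paste0("net", seq_along(networks))
  if (length(n_informative) == 1L)
    n_informative <- stats::setNames(rep(n_informative, length(networks)),
                                     names(networks))
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  for (nw in names(networks)) {
    need <- n_informative[[nw]] * (1L + redundancy)
    if (need > networks[[nw]])
      stop("informative + redundant columns exceed dimension of ", nw,
           call. = FALSE)
  }
  structure(list(n_per_class = n_per_class, networks = networks,
                 n_informative = n_informative, effect_size = effect_size,
                 redundancy = as.integer(redundancy), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic class-mean pattern matrix (K x m), in noise-SD units
class_pattern <- function(K, m, effect) {
  P <- matrix(0, K, m)
  if (m >= K - 1) {
    for (k in 2:K) P[k, (k - 2) %% m + 1] <- effect
    if (m > K - 1)
      for (j in K:m) P[(j - 1) %% (K - 1) + 2, j] <- effect
  } else {
    if (2^m < K)
      stop("need 2^n_informative >= number of classes", call. = FALSE)
    for (k in seq_len(K))
      P[k, ] <- effect * as.integer(intToBits(k - 1))[seq_len(m)]
  }
  P
}

#' Generate a synthetic multi-network feature bank
#'
#' Draws the bank described by a [synthetic_spec()]: informative columns
#' get class-dependent Gaussian means separated by
#' `effect_size * noise_sd`, redundant columns are informative columns
#' plus fresh noise, and all remaining columns are pure noise.
#' Deterministic for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `bank` (named list of [feature_table()]), `labels`
#'   (factor), and `informative` (named list of 1-based informative
#'   column indices per network).
#' @export
generate_feature_bank <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  classes <- names(spec$n_per_class)
  y <- factor(rep(classes, times = spec$n_per_class), levels = classes)
  n <- length(y)
  sample_ids <- paste0("s", seq_len(n))
  K <- length(classes)

  bank <- list()
  informative <- list()
  for (nw in names(spec$networks)) {
    D <- spec$networks[[nw]]
    m <- spec$n_informative[[nw]]
    X <- matrix(stats::rnorm(n * D, sd = spec$noise_sd), n, D)
    P <- class_pattern(K, m, spec$effect_size * spec$noise_sd)
    X[, seq_len(m)] <- X[, seq_len(m), drop = FALSE] +
      P[as.integer(y), , drop = FALSE]
    if (spec$redundancy > 0L) {
      col <- m
      for (j in seq_len(m)) {
        for (r in seq_len(spec$redundancy)) {
          col <- col + 1L
          X[, col] <- X[, j] + stats::rnorm(n, sd = spec$noise_sd)
        }
      }
    }
    bank[[nw]] <- feature_table(X, sample_ids,
                                paste0(nw, ":", seq_len(D)), nw)
    informative[[nw]] <- seq_len(m)
  }
  list(bank = bank, labels = y, informative = informative)
}

#' Exhaustive search over all non-empty masks
#'
#' Brute-force ground truth for validating the metaheuristics at small
#' dimensionality: evaluates every one of the `2^D - 1` non-empty masks
#' and returns the minimum-cost one under the same tie-breaking the
#' optimizers use (fewer selected features, then enumeration order).
#'
#' @param evaluator function mask -> `fitness_value`.
#' @param D number of features; hard cap `D <= 20`.
#' @return List with `best_mask`, `best_fitness`, `n_evaluated`
#'   (`= 2^D - 1`).
#' @export
exhaustive_oracle <- function(evaluator, D) {
  if (D > 20L) stop("D exceeds the enumeration cap of 20", call. = FALSE)
  if (D < 1L) stop("D must be >= 1", call. = FALSE)
  best <- NULL; best_bits <- NULL
  for (code in seq_len(2^D - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(D)]
    fv <- evaluator(subset_mask_fast(bits))
    if (fitness_better(fv, best)) {
      best <- fv; best_bits <- bits
    }
  }
  list(best_mask = subset_mask_fast(best_bits), best_fitness = best,
       n_evaluated = 2^D - 1)
}

#' Jaccard index between two masks or index sets
#' @param a,b [subset_mask()]s or integer index vectors.
#' @return `|a intersect b| / |a union b|` (1 when both empty).
#' @export
mask_jaccard <- function(a, b) {
  ia <- if (inherits(a, "subset_mask")) which(a$bits == 1L) else as.integer(a)
  ib <- if (inherits(b, "subset_mask")) which(b$bits == 1L) else as.integer(b)
  u <- length(union(ia, ib))
  if (u == 0L) return(1)
  length(intersect(ia, ib)) / u
}

#' Generate a synthetic brain-like grayscale scan
#'
#' A bright filled ellipse (the "brain") on a dark background, with
#' additive Gaussian noise and a number of isolated single-pixel bright
#' speckles placed outside the ellipse — the situation the extreme-point
#' cropping preprocessor is designed for. The ground-truth bounding box
#' of the ellipse is returned alongside.
#'
#' @param height,width image size (default 64 x 64).
#' @param center ellipse center `c(row, col)`, 0-based; default image
#'   center.
#' @param semiaxes ellipse semi-axes `c(row, col)` in pixels.
#' @param fg,bg foreground/background intensity (defaults 0.9 / 0.05).
#' @param noise_sd additive Gaussian noise SD (default 0).
#' @param speckle_count isolated bright noise pixels (default 0).
#' @param seed integer seed.
#' @return List with `image`, `bbox` (0-based inclusive
#'   `c(top, bottom, left, right)` of the ellipse) and `mask` (true
#'   ellipse support).
#' @export
generate_synthetic_mri <- function(height = 64L, width = 64L, center = NULL,
                                   semiaxes = c(20, 14), fg = 0.9, bg = 0.05,
                                   noise_sd = 0, speckle_count = 0L,
                                   seed = 1L) {
  if (any(semiaxes < 1)) stop("degenerate ellipse", call. = FALSE)
  if (is.null(center)) center <- c((height - 1) / 2, (width - 1) / 2)
  if (center[1] - semiaxes[1] < 0 || center[1] + semiaxes[1] > height - 1 ||
      center[2] - semiaxes[2] < 0 || center[2] + semiaxes[2] > width - 1)
    stop("ellipse extends outside the image", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  r <- matrix(0:(height - 1), height, width)
  cl <- matrix(0:(width - 1), height, width, byrow = TRUE)
  inside <- ((r - center[1]) / semiaxes[1])^2 +
            ((cl - center[2]) / semiaxes[2])^2 <= 1
  img <- matrix(bg, height, width)
  img[inside] <- fg
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(height * width,
                                                     sd = noise_sd),
                                        height, width)
  if (speckle_count > 0L) {
    # keep speckles isolated: off the ellipse (with a halo) and the border
    halo <- morph_dilate(inside, struct_square(5))
    candidates <- which(!halo &
                        r >= 2 & r <= height - 3 & cl >= 2 & cl <= width - 3)
    pick <- sample(candidates, min(speckle_count, length(candidates)))
    img[pick] <- fg
  }
  idx <- which(inside, arr.ind = TRUE)
  bbox <- c(top = min(idx[, 1]) - 1L, bottom = max(idx[, 1]) - 1L,
            left = min(idx[, 2]) - 1L, right = max(idx[, 2]) - 1L)
  list(image = img, bbox = bbox, mask = inside)
}
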