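# brute-force morphology oracles, kept deliberately naive; positions beyond
# the image window count as foreground for erosion (the element "fits"
# there) and as background for dilation, so duality holds on the window
brute_erode <- function(mask, struct) {
  H <- nrow(mask); W <- ncol(mask)
  oi <- (nrow(struct) + 1L) %/% 2L; oj <- (ncol(struct) + 1L) %/% 2L
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ok <- TRUE
    for (si in seq_len(nrow(struct))) for (sj in seq_len(ncol(struct))) {
      if (!struct[si, sj]) next
      r <- i + si - oi; c <- j + sj - oj
      if (r >= 1 && r <= H && c >= 1 && c <= W && !mask[r, c]) ok <- FALSE
    }
    out[i, j] <- ok
  }
  out
}
brute_dilate <- function(mask, struct) {
  H <- nrow(mask); W <- ncol(mask)
  oi <- (nrow(struct) + 1L) %/% 2L; oj <- (ncol(struct) + 1L) %/% 2L
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j]) next
    for (si in seq_len(nrow(struct))) for (sj in seq_len(ncol(struct))) {
      if (!struct[si, sj]) next
      r <- i + si - oi; c <- j + sj - oj
      if (r >= 1 && r <= H && c >= 1 && c <= W) out[r, c] <- TRUE
    }
  }
  out
}

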