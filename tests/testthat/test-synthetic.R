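test_that("feature banks are reproducible and carry the planted structure", {
  sp <- synthetic_spec(seed = 21)
  g1 <- generate_feature_bank(sp)
  g2 <- generate_feature_bank(sp)
  expect_identical(g1$bank$netA$values, g2$bank$netA$values)
  expect_identical(g1$labels, g2$labels)

  expect_identical(n_features(g1$bank$netA), 64L)
  expect_identical(n_features(g1$bank$netB), 48L)
  expect_identical(n_samples(g1$bank$netA), 240L)
  expect_identical(levels(g1$labels),
                   c("glioma", "meningioma", "no_tumor", "pituitary"))
  expect_identical(g1$informative$netA, 1:3)
})

test_that("null banks (zero effect) show only nominal per-column signal", {
  sp <- synthetic_spec(n_per_class = c(a = 40, b = 40),
                       networks = c(net = 50L), n_informative = 3L,
                       effect_size = 0, seed = 5)
  g <- generate_feature_bank(sp)
  x <- g$bank$net$values
  p <- vapply(seq_len(ncol(x)), function(j)
    stats::t.test(x[g$labels == "a", j], x[g$labels == "b", j])$p.value, 0)
  # Bonferroni-corrected rejections should be (almost surely) zero
  expect_identical(sum(p < 0.05 / length(p)), 0L)
})

test_that("a strong planted pair alone supports near-perfect classification", {
  sp <- synthetic_spec(networks = c(net = 20L), n_informative = 2L,
                       effect_size = 5, seed = 9)
  g <- generate_feature_bank(sp)
  fv <- evaluate_subset(g$bank$net, g$labels, mask_from_indices(1:2, 20),
                        split_spec("holdout", seed = 9))
  expect_gt(fv$accuracy, 0.95)
})

test_that("redundant columns are noisy copies of informative ones", {
  sp <- synthetic_spec(networks = c(net = 30L), n_informative = 2L,
                       redundancy = 2L, effect_size = 4, seed = 13)
  g <- generate_feature_bank(sp)
  x <- g$bank$net$values
  # columns 3..6 copy columns 1,1,2,2 plus fresh unit noise
  expect_gt(stats::cor(x[, 1], x[, 3]), 0.5)
  expect_gt(stats::cor(x[, 2], x[, 5]), 0.5)
  expect_lt(abs(stats::cor(x[, 10], x[, 1])), 0.4)
})

test_that("spec validation rejects impossible layouts", {
  expect_error(synthetic_spec(n_per_class = c(a = 10)), "2 classes")
  expect_error(synthetic_spec(networks = c(n = 4L), n_informative = 3L,
                              redundancy = 2L), "exceed")
  expect_error(synthetic_spec(effect_size = -1), "effect_size")
  # fewer informative columns than classes requires a binary code to fit
  expect_error(generate_feature_bank(
    synthetic_spec(n_per_class = c(a = 5, b = 5, c = 5, d = 5, e = 5),
                   networks = c(n = 10L), n_informative = 2L)),
    "2\\^n_informative")
})

test_that("exhaustive enumeration visits every non-empty mask once", {
  ev <- planted_landscape(8)
  orc <- exhaustive_oracle(ev, 8)
  expect_identical(orc$n_evaluated, 255)
  expect_identical(which(orc$best_mask$bits == 1L), 1L)
  expect_equal(orc$best_fitness$I, 0.99 * 0 + 0.01 * (1 / 8))

  orc1 <- exhaustive_oracle(ev, 1)
  expect_identical(orc1$best_mask$bits, 1L)
  expect_identical(orc1$n_evaluated, 1)

  # monotone landscape: tie-break picks the lowest-index singleton
  mono <- function(m) {
    bits <- if (inherits(m, "subset_mask")) m$bits else m
    structure(list(I = 0.1 * sum(bits), accuracy = 0.5,
                   n_selected = sum(bits), n_total = 3L),
              class = "fitness_value")
  }
  orc3 <- exhaustive_oracle(mono, 3)
  expect_identical(orc3$best_mask$bits, c(1L, 0L, 0L))

  expect_error(exhaustive_oracle(ev, 21), "cap")
})

test_that("the oracle lower-bounds every mask it enumerated", {
  ev <- additive_landscape(6, planted = c(2, 5))
  orc <- exhaustive_oracle(ev, 6)
  for (code in seq_len(2^6 - 1)) {
    bits <- as.integer(intToBits(code))[1:6]
    expect_lte(orc$best_fitness$I, ev(bits)$I)
  }
  expect_identical(which(orc$best_mask$bits == 1L), c(2L, 5L))
})

test_that("mask Jaccard behaves as a set similarity", {
  expect_equal(mask_jaccard(mask_from_indices(1:3, 8), 1:3), 1)
  expect_equal(mask_jaccard(mask_from_indices(1:2, 8), 1:4), 0.5)
  expect_equal(mask_jaccard(integer(0), integer(0)), 1)
  expect_equal(mask_jaccard(mask_from_indices(5, 8), 1:4), 0)
})

test_that("synthetic scans come with exact ground truth in the clean case", {
  g <- generate_synthetic_mri(48, 40, semiaxes = c(15, 10))
  expect_identical(dim(g$image), c(48L, 40L))
  pts <- find_extreme_points(binarize(g$image, 0.5))
  expect_identical(c(pts$top[1], pts$bottom[1], pts$left[2], pts$right[2]),
                   unname(g$bbox))

  # isolated speckles are removed by opening; recovery stays exact
  gs <- generate_synthetic_mri(48, 40, semiaxes = c(15, 10),
                               speckle_count = 5, seed = 2)
  raw <- binarize(gs$image, 0.5)
  expect_gt(sum(raw), sum(gs$mask))           # speckles present pre-opening
  cleaned <- denoise_open(raw, struct_square(3), iterations = 1)
  pts <- find_extreme_points(cleaned)
  expect_identical(c(pts$top[1], pts$bottom[1], pts$left[2], pts$right[2]),
                   unname(gs$bbox))

  g2 <- generate_synthetic_mri(48, 40, semiaxes = c(15, 10),
                               noise_sd = 0.05, seed = 3)
  expect_identical(g2$image, generate_synthetic_mri(48, 40,
    semiaxes = c(15, 10), noise_sd = 0.05, seed = 3)$image)
  expect_error(generate_synthetic_mri(semiaxes = c(0, 5)), "degenerate")
  expect_error(generate_synthetic_mri(20, 20, semiaxes = c(15, 15)), "outside")
})
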