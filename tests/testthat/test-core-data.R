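test_that("feature tables round-trip through both on-disk formats", {
  ft <- random_table(5, 7)
  csv <- withr::local_tempfile(fileext = ".csv")
  rds <- withr::local_tempfile(fileext = ".rds")

  save_feature_table(ft, csv)
  back <- load_feature_table(csv, network = "netX")
  expect_equal(back$values, ft$values)
  expect_identical(back$sample_ids, ft$sample_ids)
  expect_identical(back$feature_ids, ft$feature_ids)

  save_feature_table(ft, rds)
  expect_identical(load_feature_table(rds), ft)
})

test_that("malformed delimited input is rejected with a located error", {
  ft <- random_table(4, 7)
  f <- withr::local_tempfile(fileext = ".csv")
  save_feature_table(ft, f)
  lines <- readLines(f)
  # drop the last value of data row 3
  lines[4] <- sub(",[^,]*$", "", lines[4])
  writeLines(lines, f)
  expect_error(load_feature_table(f), "row 3")

  writeLines(c("", "x"), f)
  expect_error(load_feature_table(f), "header")

  save_feature_table(ft, f)
  lines <- readLines(f)
  lines[2] <- sub(",[^,]*$", ",abc", lines[2])
  writeLines(lines, f)
  expect_error(load_feature_table(f), "non-numeric")
})

test_that("construction validates finiteness and identifier shape", {
  m <- matrix(1:6, 2, 3)
  expect_error(feature_table(matrix(c(1, NA, 3, 4), 2, 2)), "non-finite")
  expect_error(feature_table(m, feature_ids = c("a", "a", "b")), "unique")
  expect_error(feature_table(m, sample_ids = "only_one"), "rows")
  ft <- feature_table(m + 0, network = "EfficientNet-b0")
  expect_identical(ft$feature_ids, paste0("EfficientNet-b0:", 1:3))
})

test_that("a table can carry a published backbone dimensionality", {
  ft <- feature_table(matrix(0, 4, 1280), network = "EfficientNet-b0")
  expect_identical(n_features(ft), 1280L)
})

test_that("apply_mask selects exactly the flagged columns in order", {
  ft <- random_table(6, 10)
  expect_equal(apply_mask(ft, subset_mask(rep(1, 10))), ft)

  m <- mask_from_indices(c(1, 3), 3)
  ft3 <- random_table(4, 3)
  out <- apply_mask(ft3, m)
  expect_identical(out$feature_ids, ft3$feature_ids[c(1, 3)])
  expect_equal(out$values, ft3$values[, c(1, 3)])

  set.seed(9)
  bits <- integer(10); bits[sample(10, 4)] <- 1L
  out <- apply_mask(ft, subset_mask(bits))
  expect_identical(n_features(out), 4L)
  expect_equal(colSums(out$values), colSums(ft$values)[bits == 1])

  expect_error(apply_mask(ft, subset_mask(rep(1, 9))), "dimension")
  expect_error(apply_mask(ft, subset_mask(rep(0, 10))), "empty-subset")
})

test_that("masking composes over nested index sets", {
  ft <- random_table(5, 12, seed = 11)
  outer <- mask_from_indices(c(2, 4, 5, 7, 9, 12), 12)
  inner <- mask_from_indices(c(1, 3, 6), 6)  # within the masked table
  composed <- mask_from_indices(which(outer$bits == 1)[c(1, 3, 6)], 12)
  expect_equal(apply_mask(apply_mask(ft, outer), inner),
               apply_mask(ft, composed))
})

test_that("concatenation preserves provenance and demands aligned samples", {
  a <- random_table(5, 4, network = "netA", seed = 1)
  b <- feature_table(matrix(rnorm(15), 5, 3), sample_ids = a$sample_ids,
                     network = "netB")
  expect_equal(concat_tables(list(a)), a)

  ab <- concat_tables(list(a, b))
  expect_identical(n_features(ab), 7L)
  expect_identical(ab$feature_ids, c(a$feature_ids, b$feature_ids))
  expect_equal(ab$values, cbind(a$values, b$values))

  # splitting a table by any column partition and re-concatenating is lossless
  left <- apply_mask(ab, mask_from_indices(1:4, 7))
  right <- apply_mask(ab, mask_from_indices(5:7, 7))
  expect_equal(concat_tables(list(left, right), network = ab$network), ab)

  perm <- feature_table(b$values, rev(b$sample_ids), network = "netB")
  expect_error(concat_tables(list(a, perm)), "alignment")
})

test_that("masked tables of published sizes concatenate to the printed total", {
  ids <- paste0("s", 1:3)
  dn <- feature_table(matrix(0, 3, 1920), sample_ids = ids, network = "DenseNet-201")
  ef <- feature_table(matrix(0, 3, 1280), sample_ids = ids, network = "EfficientNet-b0")
  m_dn <- mask_from_indices(seq_len(651), 1920)
  m_ef <- mask_from_indices(seq_len(641), 1280)
  out <- concat_tables(list(apply_mask(dn, m_dn), apply_mask(ef, m_ef)))
  expect_identical(n_features(out), 1292L)
})

test_that("masks serialize to JSON and back", {
  m <- mask_from_indices(c(2, 5, 6), 8)
  f <- withr::local_tempfile(fileext = ".json")
  save_mask(m, f, network = "netA")
  back <- load_mask(f)
  expect_equal(back$bits, m$bits)
  expect_identical(attr(back, "network"), "netA")
})

test_that("stratified holdout reproduces published per-class counts", {
  y <- label_vector(rep(c("glioma", "meningioma", "no_tumor", "pituitary"),
                        times = c(826, 822, 395, 827)))
  sp <- make_split(y, split_spec("holdout", fraction = 0.2, seed = 5))
  expect_identical(sum(y[sp$validation] == "glioma"), 165L)
  # partition property
  expect_identical(sort(c(sp$train, sp$validation)), seq_along(y))
  expect_length(intersect(sp$train, sp$validation), 0)
})

test_that("splits are deterministic in the seed and k-fold partitions cover", {
  y <- label_vector(rep(c("a", "b"), 50))
  s1 <- make_split(y, split_spec("holdout", seed = 7))
  s2 <- make_split(y, split_spec("holdout", seed = 7))
  expect_identical(s1, s2)
  s3 <- make_split(y, split_spec("holdout", seed = 8))
  expect_false(identical(s1, s3))

  kf <- make_split(y, split_spec("kfold", k = 5, seed = 1, stratified = FALSE))
  expect_length(kf$folds, 5)
  expect_identical(sort(unlist(kf$folds)), seq_along(y))
  expect_true(all(lengths(kf$folds) == 20))

  # stratified proportions within one sample of the target per class
  y2 <- label_vector(rep(c("a", "b", "c"), times = c(31, 47, 22)))
  sp <- make_split(y2, split_spec("holdout", fraction = 0.2, seed = 2))
  for (cl in levels(y2)) {
    n_val <- sum(y2[sp$validation] == cl)
    expect_lte(abs(n_val - 0.2 * sum(y2 == cl)), 1)
  }
  expect_error(make_split(label_vector(rep(c("a", "b"), c(3, 50))),
                          split_spec("kfold", k = 5)), "fewer samples")
})

test_that("labels load from the two-column CSV contract", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,label", "s1,tumor", "s2,healthy", "s3,tumor"), f)
  y <- load_labels(f)
  expect_identical(as.character(y), c("tumor", "healthy", "tumor"))
  expect_identical(names(y), c("s1", "s2", "s3"))
})
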