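test_that("imbalance ratio matches the published class counts and boundaries", {
  expect_equal(imbalance_ratio(896, 3200), 0.28)
  expect_equal(imbalance_ratio(64, 3200), 0.02)
  expect_equal(imbalance_ratio(50, 50), 1.0)
  expect_equal(imbalance_ratio(0, 10), 0.0)
  expect_error(imbalance_ratio(5, 0), "majority_count")
  expect_error(imbalance_ratio(10, 5), "argument order")
  # monotone nondecreasing in the minority count
  r <- vapply(0:100, imbalance_ratio, numeric(1), majority_count = 100)
  expect_true(all(diff(r) >= 0))
})

test_that("class distribution counts and ratios are consistent", {
  x <- tiny_image_set(c(6, 4, 2))
  cd <- class_distribution(x)
  expect_equal(unname(cd$counts), c(6L, 4L, 2L))
  expect_equal(sum(cd$counts), length(x))
  expect_equal(unname(cd$ratios), c(1, 4 / 6, 2 / 6))
  expect_equal(max(cd$ratios), 1)

  one <- tiny_image_set(c(5))
  expect_equal(unname(class_distribution(one)$ratios), 1)
  two <- tiny_image_set(c(3, 3))
  expect_equal(unname(class_distribution(two)$ratios), c(1, 1))
  expect_error(class_distribution(subset_images(x, integer(0))), "empty")
})

test_that("subsampling preserves imbalance ratios via per-class floors", {
  x <- tiny_image_set(c(40, 12, 4), size = 4L)
  s <- subsample_preserving_ratio(x, 0.25, seed = 5)
  expect_equal(unname(class_distribution(s)$counts), c(10L, 3L, 1L))
  # determinism and full-fraction identity
  s2 <- subsample_preserving_ratio(x, 0.25, seed = 5)
  expect_identical(s$images, s2$images)
  full <- subsample_preserving_ratio(x, 1.0, seed = 1)
  expect_equal(unname(class_distribution(full)$counts),
               unname(class_distribution(x)$counts))
  expect_error(subsample_preserving_ratio(x, 0.1, seed = 1), "class")
})

test_that("stratified split is an exact disjoint partition", {
  x <- tiny_image_set(c(20, 10, 5), size = 4L)
  sp <- stratified_split(x, 0.8, seed = 3)
  expect_equal(unname(class_distribution(sp$train)$counts),
               round(0.8 * c(20, 10, 5)))
  expect_equal(length(sp$train) + length(sp$test), length(x))
  # union reproduces the original class counts exactly
  merged <- bind_images(sp$train, sp$test)
  expect_equal(class_distribution(merged)$counts, class_distribution(x)$counts)
  # same seed, same partition
  sp2 <- stratified_split(x, 0.8, seed = 3)
  expect_identical(sp$train$images, sp2$train$images)
  expect_error(stratified_split(tiny_image_set(c(4, 1)), 0.8, seed = 1),
               "fewer than 2")
})

test_that("client partition is stratified, disjoint and balanced", {
  x <- tiny_image_set(c(20, 11, 5), size = 4L)
  sh <- partition_clients(x, 2, seed = 9)
  sizes <- vapply(sh, length, integer(1))
  expect_equal(sum(sizes), length(x))
  expect_lte(max(sizes) - min(sizes), 1L)
  merged <- do.call(bind_images, sh)
  expect_equal(class_distribution(merged)$counts, class_distribution(x)$counts)
  # per-class proportions within one sample of the global split
  global <- class_distribution(x)$counts
  for (s in sh) {
    cnt <- class_distribution(s)$counts
    expect_true(all(abs(cnt - global / 2) <= 1))
  }
  expect_identical(partition_clients(x, 1, seed = 1)[[1]]$images, x$images)
  expect_error(partition_clients(tiny_image_set(c(2)), 5, seed = 1), "clients")
})

test_that("image directory round trip preserves data and manifest", {
  x <- tiny_image_set(c(3, 2), size = 8L)
  dir <- withr::local_tempdir()
  write_image_dir(x, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), length(x))
  expect_setequal(names(man), c("path", "label", "provenance"))
  y <- read_image_dir(dir, class_names = x$class_names)
  expect_equal(length(y), length(x))
  expect_equal(class_distribution(y)$counts, class_distribution(x)$counts)
  # PNG quantizes to 8 bits
  expect_lt(max(abs(y$images[[1]] - x$images[[1]])), 1 / 255)
})
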