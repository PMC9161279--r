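test_that("save/load round trip preserves the mask exactly and the image to 8-bit", {
  sm <- generate_sample(rosette_spec(image_size = 32, n_leaves = 3, seed = 4))
  d <- file.path(tempdir(), "leafseg-roundtrip")
  dir.create(d, showWarnings = FALSE)
  ip <- file.path(d, "im.png"); mp <- file.path(d, "mk.png")
  png::writePNG(sm$image / 255, ip)
  png::writePNG(sm$mask + 0.0, mp)
  got <- load_sample(list(image = ip, mask = mp, count = sm$count))
  expect_identical(got$mask, sm$mask)
  expect_lt(max(abs(got$image - sm$image / 255)), 1 / 255)
  expect_equal(got$count, sm$count)
})

test_that("records without a mask load cleanly; shape mismatches error", {
  sm <- generate_sample(rosette_spec(image_size = 32, n_leaves = 3, seed = 4))
  d <- file.path(tempdir(), "leafseg-io2")
  dir.create(d, showWarnings = FALSE)
  ip <- file.path(d, "im.png")
  png::writePNG(sm$image / 255, ip)
  got <- load_sample(list(image = ip, mask = NA, count = NA))
  expect_null(got$mask)
  expect_true(is.na(got$count))
  expect_error(load_sample(list(image = file.path(d, "nope.png"))), "not found")
  # mask of wrong shape
  mp <- file.path(d, "bad.png")
  png::writePNG(matrix(1, 16, 16), mp)
  expect_error(load_sample(list(image = ip, mask = mp)), "shape")
})

test_that("resize_pair downsamples 500px imagery to the 480px training size", {
  img <- array(stats::runif(500 * 500 * 3), c(500, 500, 3))
  msk <- random_binary_mask(500, 500)
  out <- resize_pair(img, msk, 480)
  expect_equal(dim(out$image), c(480, 480, 3))
  expect_equal(dim(out$mask), c(480, 480))
  expect_true(all(out$mask %in% c(0L, 1L)))
})

test_that("resize_pair is the identity at the native size and keeps full masks full", {
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  msk <- matrix(1L, 64, 64)
  out <- resize_pair(img, msk, 64)
  expect_identical(out$mask, msk)
  expect_equal(out$image, img)
  out2 <- resize_pair(img, msk, 40)
  expect_true(all(out2$mask == 1L))
  expect_error(resize_pair(img, msk, 4), ">= 8")
})

test_that("geometric augmentations transform image and mask identically", {
  sm <- generate_sample(rosette_spec(image_size = 32, n_leaves = 4, seed = 8))
  img <- sm$image / 255
  for (s in 1:25) {
    cfg <- aug_config(gamma_range = NULL, brightness_range = NULL,
                      contrast_range = NULL, hsv_shift = NULL, p = 1)
    out <- apply_augmentation(img, sm$mask, cfg, seed = 500 + s)
    expect_identical(out$mask, oracle_replay_geometric(sm$mask, out$log))
    expect_true(all(out$mask %in% c(0L, 1L)))
  }
})

test_that("photometric augmentations leave the mask bitwise unchanged", {
  sm <- generate_sample(rosette_spec(image_size = 32, n_leaves = 4, seed = 9))
  img <- sm$image / 255
  cfg <- aug_config(rotate90 = FALSE, flips = character(0), scale_range = NULL, p = 1)
  for (s in 1:25) {
    out <- apply_augmentation(img, sm$mask, cfg, seed = 900 + s)
    expect_identical(out$mask, sm$mask)
    expect_true(length(out$log) > 0)
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("four quarter-turns compose to the identity", {
  sm <- generate_sample(rosette_spec(image_size = 32, n_leaves = 3, seed = 2))
  img <- sm$image / 255
  r <- leafseg:::rot90_img
  expect_equal(r(r(r(r(img, 1), 1), 1), 1), img)
  expect_identical(r(sm$mask, 4), sm$mask)
})

test_that("split_dataset partitions records at the requested ratio", {
  m <- data.frame(image = sprintf("i%03d.png", 1:100),
                  mask = sprintf("m%03d.png", 1:100),
                  count = rep(3L, 100), split = "", stringsAsFactors = FALSE)
  s <- split_dataset(m, 0.8, seed = 1)
  expect_equal(sum(s$split == "train"), 80)
  expect_equal(sum(s$split == "val"), 20)
  expect_true(all(s$split %in% c("train", "val")))
  # rounding with tiny datasets
  s5 <- split_dataset(m[1:5, ], 0.8, seed = 1)
  expect_equal(sum(s5$split == "train"), 4)
  expect_equal(sum(s5$split == "val"), 1)
  # determinism
  expect_identical(split_dataset(m, 0.8, seed = 42), split_dataset(m, 0.8, seed = 42))
  expect_error(split_dataset(m[1, , drop = FALSE], 0.8), "at least 2")
  expect_error(split_dataset(m, 1.2), "ratio")
})

test_that("manifests round trip through CSV", {
  m <- data.frame(image = c("a.png", "b.png"), mask = c("am.png", ""),
                  count = c(3L, 5L), split = c("train", "val"),
                  stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".csv")
  write_manifest(m, p)
  got <- read_manifest(p)
  expect_equal(got$image, m$image)
  expect_equal(got$count, m$count)
  expect_equal(got$split, m$split)
})
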