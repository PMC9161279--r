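test_that("generated samples honour the count and mask invariants", {
  sm <- generate_sample(rosette_spec(n_leaves = 5, seed = 7))
  expect_equal(sm$count, 5)
  expect_length(sm$leaf_polygons, 5)
  # mask is the union of the per-leaf supports
  union <- matrix(0L, 64, 64)
  for (p in sm$leaf_polygons) union <- pmax(union, rasterise_polygon(p, 64))
  expect_identical(sm$mask, union)
  expect_true(all(sm$mask %in% c(0L, 1L)))
  expect_true(all(dim(sm$image) == c(64, 64, 3)))
  expect_true(all(sm$image >= 0 & sm$image <= 255))
  # leaves can merge by overlap but never split: components <= count
  for (s in 1:5) {
    smi <- generate_sample(rosette_spec(n_leaves = 6, seed = s))
    comps <- max(leafseg:::label_components(smi$mask))
    expect_lte(comps, smi$count)
  }
})

test_that("a single-leaf mask matches a point-in-polygon oracle", {
  sm <- generate_sample(rosette_spec(n_leaves = 1, background_mode = "plain",
                                     illumination_jitter = c(1, 1), seed = 13))
  oracle <- oracle_rasterise(sm$leaf_polygons[[1]], 64)
  expect_identical(sm$mask, oracle)
  expect_gt(sum(sm$mask), 0)
})

test_that("identical spec and seed reproduce samples and datasets exactly", {
  spec <- rosette_spec(n_leaves = 4, background_mode = "soil_with_pot", seed = 99)
  expect_identical(generate_sample(spec), generate_sample(spec))

  d1 <- file.path(tempdir(), "leafseg-det1")
  d2 <- file.path(tempdir(), "leafseg-det2")
  sampler <- rosette_sampler(n_leaves_range = c(2L, 6L))
  m1 <- generate_dataset(4, sampler, seed = 5, out_dir = d1)
  m2 <- generate_dataset(4, sampler, seed = 5, out_dir = d2)
  expect_identical(m1$count, m2$count)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$image[i], "raw", 1e6), readBin(m2$image[i], "raw", 1e6))
    expect_identical(readBin(m1$mask[i], "raw", 1e6), readBin(m2$mask[i], "raw", 1e6))
  }
})

test_that("invalid specs are rejected naming the offending field", {
  expect_error(rosette_spec(n_leaves = 0), "n_leaves")
  expect_error(rosette_spec(image_size = 16), "image_size")
  expect_error(rosette_spec(leaf_length_range = c(0.5, 0.2)), "leaf_length_range")
  expect_error(rosette_spec(leaf_length_range = c(0, 0.5)), "leaf_length_range")
  expect_error(rosette_spec(illumination_jitter = c(1.2, 0.8)), "illumination_jitter")
  expect_error(rosette_spec(center_jitter = -1), "center_jitter")
})

test_that("foreground fraction increases with the leaf length range", {
  frac <- function(range) {
    mean(vapply(1:50, function(s) {
      mean(generate_sample(rosette_spec(n_leaves = 5, leaf_length_range = range,
                                        seed = 1000 + s))$mask)
    }, numeric(1)))
  }
  f_small <- frac(c(0.2, 0.3))
  f_mid <- frac(c(0.4, 0.5))
  f_large <- frac(c(0.6, 0.8))
  expect_lt(f_small, f_mid)
  expect_lt(f_mid, f_large)
})

test_that("dataset generation writes a consistent manifest", {
  d <- file.path(tempdir(), "leafseg-manifest")
  m <- generate_dataset(10, rosette_sampler(n_leaves_range = c(4L, 4L)),
                        seed = 3, out_dir = d)
  expect_equal(nrow(m), 10)
  expect_true(all(m$count == 4))
  expect_true(all(file.exists(m$image)))
  expect_true(all(file.exists(m$mask)))
  # masks reload as strictly binary
  s <- load_sample(m[1, ])
  expect_true(all(s$mask %in% c(0L, 1L)))
  expect_equal(s$count, 4L)
})
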