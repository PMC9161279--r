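test_that("a residual unit with a zero branch is the identity on non-negative input", {
  x <- array(stats::runif(4 * 4 * 3), c(4, 4, 3))
  zero_branch <- function(x) x * 0
  expect_identical(residual_unit(x, zero_branch), x)
  # stacking zero-branch units stays the identity
  y <- x
  for (i in 1:5) y <- residual_unit(y, zero_branch)
  expect_identical(y, x)
  # and the general case matches relu(x + F(x)) computed by hand
  set.seed(12)
  branch <- function(x) 0.3 * x - 0.2
  got <- residual_unit(x, branch)
  expect_equal(got, pmax(x + branch(x), 0), tolerance = 1e-12)
  expect_error(residual_unit(x, function(x) x[1:2]), "shape")
})

test_that("a network with all residual branches zeroed reduces to stem plus head", {
  cfg <- count_config(input_mode = "rgb", n_blocks = 2, widths = c(8, 8),
                      stage_strides = c(1L, 1L), input_size = 16)
  model <- init_countnet(cfg, seed = 5)
  # zero every block parameter; shortcuts are pure identity (no projections)
  for (nm in names(model$params)) {
    if (grepl("^s[0-9]+_b", nm)) model$params[[nm]] <- model$params[[nm]] * 0
  }
  expect_false(any(grepl("_pw$", names(model$params))))
  x <- array(stats::runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  ag <- asNamespace("leafseg")
  pn <- ag$wrap_params(model$params)
  out <- ag$count_forward_nodes(pn, ag$tg_leaf(x), cfg)
  # stem + gap + head computed directly
  stem <- ag$op_relu(ag$op_conv2d(ag$tg_leaf(x), pn$stem_w, pn$stem_b, 1L, 1L))
  direct <- ag$op_dense(ag$op_gap(stem), pn$head_w, pn$head_b)
  expect_equal(out$value, direct$value, tolerance = 1e-12)
})

test_that("assemble_inputs implements the four input schemes", {
  sm <- lapply(1:5, function(i) {
    s <- generate_sample(rosette_spec(image_size = 32, n_leaves = i, seed = i))
    list(image = s$image / 255, mask = s$mask, count = s$count)
  })
  rgb <- assemble_inputs(sm, "rgb")
  expect_length(rgb, 5)
  expect_equal(dim(rgb[[1]]$x)[3], 3)

  rgbm <- assemble_inputs(sm, "rgb_mask_channel")
  expect_length(rgbm, 5)
  expect_equal(dim(rgbm[[1]]$x)[3], 4)
  expect_equal(rgbm[[3]]$x[, , 4], sm[[3]]$mask + 0)

  mix <- assemble_inputs(sm, "mixture")
  expect_length(mix, 10)
  expect_equal(mix[[1]]$count, mix[[2]]$count)
  expect_equal(mix[[2]]$x[, , 1], sm[[1]]$mask + 0)   # replicated mask item
  expect_equal(mix[[2]]$x[, , 2], mix[[2]]$x[, , 3])

  x2 <- assemble_inputs(sm, "rgb_x2")
  expect_length(x2, 10)
  expect_identical(x2[[1]]$x, x2[[2]]$x)

  nomask <- lapply(sm, function(s) list(image = s$image, mask = NULL, count = s$count))
  expect_error(assemble_inputs(nomask, "rgb_mask_channel"), "requires a mask")
  expect_length(assemble_inputs(nomask, "rgb"), 5)
})

test_that("count_loss equals the loop oracle and is quadratic in the error", {
  expect_equal(count_loss(c(4, 4), c(5, 3)), 1.0)
  expect_equal(count_loss(c(5, 3, 7), c(5, 3, 7)), 0)
  set.seed(20)
  for (i in 1:10) {
    n <- sample(1:20, 1)
    p <- stats::runif(n, 0, 10); g <- stats::runif(n, 0, 10)
    expect_equal(count_loss(p, g), sum((p - g)^2) / n, tolerance = 1e-12)
    expect_equal(count_loss(g + 3 * (p - g), g), 9 * count_loss(p, g),
                 tolerance = 1e-9)
  }
  expect_error(count_loss(numeric(0), numeric(0)), "empty")
  expect_error(count_loss(1:3, 1:2), "mismatch")
})

test_that("count predictions round half away from zero and floor at zero", {
  rc <- leafseg:::round_count
  expect_equal(rc(4.4), 4L)
  expect_equal(rc(4.5), 5L)
  expect_equal(rc(3.5), 4L)
  expect_equal(rc(-0.3), 0L)
  expect_equal(rc(-2.7), 0L)
  expect_equal(rc(0.49), 0L)
})

test_that("predict_count enforces the mask requirement and reports both forms", {
  cfg <- count_config(input_mode = "rgb_mask_channel", n_blocks = 1,
                      widths = c(8), stage_strides = 2L, input_size = 16)
  model <- init_countnet(cfg, seed = 3)
  s <- generate_sample(rosette_spec(image_size = 32, n_leaves = 3, seed = 6))
  expect_error(predict_count(model, s$image / 255), "requires a mask")
  p <- predict_count(model, s$image / 255, mask = s$mask)
  expect_s3_class(p, "count_prediction")
  expect_true(is.numeric(p$raw))
  expect_true(p$rounded >= 0)
  expect_equal(p$rounded, leafseg:::round_count(p$raw))
})

test_that("zero-epoch counter training returns an initialised model", {
  m <- fixture_dataset(6, "cnt-zero", image_size = 32, seed = 66)
  cfg <- count_config(input_mode = "rgb", n_blocks = 1, widths = c(8),
                      stage_strides = 2L, input_size = 32)
  model <- train_counter(m, cfg, train_config(epochs = 0, seed = 1))
  expect_s3_class(model, "countnet_model")
  expect_equal(nrow(model$history), 0)
})
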