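test_that("the nested skip graph has the triangular structure", {
  for (L in 2:5) {
    widths <- 2^(3:(2 + L))
    g <- build_node_graph(seg_config(n_levels = L, base_widths = widths))
    expect_length(g, L * (L + 1) / 2)
    for (nd in g) {
      expected <- if (nd$j == 0) 1L else nd$j + 1L
      expect_equal(nd$in_degree, expected)
    }
  }
  # the two-level graph is exactly {(0,0), (1,0), (0,1)}
  g2 <- build_node_graph(seg_config(n_levels = 2, base_widths = c(8, 16)))
  expect_setequal(names(g2), c("0,0", "1,0", "0,1"))
  # the top decoder node of a five-level graph merges five feature streams
  g5 <- build_node_graph(seg_config())
  expect_equal(g5[["0,4"]]$in_degree, 5)
  expect_setequal(g5[["0,4"]]$inputs,
                  c("same(0,0)", "same(0,1)", "same(0,2)", "same(0,3)", "up(1,3)"))
})

test_that("config invariants are enforced", {
  expect_error(seg_config(n_levels = 1, base_widths = 8), "n_levels")
  expect_error(seg_config(n_levels = 3, base_widths = c(8, 16)), "one entry per level")
  expect_error(seg_config(n_levels = 3, base_widths = c(16, 8, 32)), "increasing")
  expect_error(seg_config(output_threshold = 1.5), "output_threshold")
})

test_that("forward pass produces calibrated probability maps of the input size", {
  cfg <- seg_config(n_levels = 3, base_widths = c(4, 8, 16))
  model <- init_segnet(cfg, seed = 1)
  x <- array(stats::runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  p <- seg_forward(model, x)
  expect_equal(dim(p), c(16, 16, 2))
  expect_true(all(p >= 0 & p <= 1))
  # indivisible spatial sizes are rejected, naming the requirement
  bad <- array(stats::runif(15 * 15 * 3), c(15, 15, 3))
  expect_error(seg_forward(model, bad), "divisible by 4")
  # evaluation is deterministic
  expect_identical(p, seg_forward(model, x))
})

test_that("transposed-convolution upsampling is drop-in for bilinear", {
  cfg <- seg_config(n_levels = 2, base_widths = c(4, 8),
                    upsample_mode = "transposed_conv")
  model <- init_segnet(cfg, seed = 2)
  x <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  p <- seg_forward(model, x)
  expect_equal(dim(p), c(8, 8, 1))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("dice coefficient matches hand-computed overlaps", {
  gt <- matrix(0, 4, 4); gt[1, 1:4] <- 1              # 4 foreground pixels
  expect_equal(dice_coefficient(gt, gt), 1, tolerance = 1e-5)
  pred <- matrix(0, 4, 4); pred[1, 1:2] <- 1; pred[2, 1:2] <- 1  # overlap 2
  expect_equal(dice_coefficient(pred, gt), 2 * 2 / (4 + 4), tolerance = 1e-5)
  disj <- matrix(0, 4, 4); disj[3, 1:4] <- 1
  expect_lt(dice_coefficient(disj, gt), 1e-5)
})

test_that("combined loss decomposes into its BCE and Dice terms", {
  set.seed(31)
  pred <- array(stats::runif(6 * 6 * 3, 0.05, 0.95), c(6, 6, 3))
  gt <- array(as.numeric(stats::runif(6 * 6 * 3) < 0.4), c(6, 6, 3))
  # dice weight 0: equals the loop BCE oracle
  expect_equal(combined_loss(pred, gt, weights = c(bce = 1, dice = 0)),
               oracle_bce(pred, gt), tolerance = 1e-6)
  # bce weight 0: equals 1 - mean per-image dice
  d <- mean(vapply(1:3, function(b) 1 - dice_coefficient(pred[, , b], gt[, , b]),
                   numeric(1)))
  expect_equal(combined_loss(pred, gt, weights = c(bce = 0, dice = 1)), d,
               tolerance = 1e-6)
  # perfect prediction drives the loss to zero
  eps <- 1e-6
  near <- pmin(pmax(gt, eps), 1 - eps)
  expect_lt(combined_loss(near, gt), 1e-4)
  # a prediction better in both terms has lower loss
  worse <- pmin(pmax(0.5 + 0.2 * (0.5 - gt), eps), 1 - eps)
  expect_lt(combined_loss(near, gt), combined_loss(worse, gt))
  expect_error(combined_loss(pred * 3, gt), "probabilities")
})

test_that("the literal per-pixel loss form is negative at a perfect prediction", {
  gt <- array(1, c(4, 4, 1))
  pred <- array(1 - 1e-6, c(4, 4, 1))
  l <- combined_loss(pred, gt, form = "as_printed")
  expect_lt(l, 0)   # -(0.5*log(1) + 2*1/(1+1)) = -1 per pixel
  expect_equal(l, -1, tolerance = 1e-3)
})

test_that("boundary weight map matches the exhaustive-distance oracle", {
  # two 2x2 squares in an 8x8 mask (two components)
  m <- matrix(0L, 8, 8)
  m[2:3, 2:3] <- 1L
  m[6:7, 6:7] <- 1L
  got <- boundary_weight_map(m, w0 = 10, sigma = 0.5)
  expect_equal(got, oracle_weight_map(m, 10, 0.5), tolerance = 1e-12)
  # boundary pixels (d1 = d2 = 0 for a single component) get wc + w0
  single <- matrix(0L, 8, 8); single[3:6, 3:6] <- 1L
  wm <- boundary_weight_map(single, w0 = 10, sigma = 0.5)
  wc_fg <- 0.5 / mean(single == 1)
  expect_equal(wm[3, 3], wc_fg + 10, tolerance = 1e-12)
  # interior background far from the boundary decays to wc
  wc_bg <- 0.5 / mean(single == 0)
  expect_equal(wm[8, 8], wc_bg, tolerance = 1e-6)
  # random small masks against the oracle
  set.seed(77)
  for (i in 1:5) {
    r <- random_binary_mask(6, 6, 0.3)
    expect_equal(boundary_weight_map(r, 10, 0.5), oracle_weight_map(r, 10, 0.5),
                 tolerance = 1e-12)
  }
  # all-background mask: class-weight-only map
  z <- matrix(0L, 5, 5)
  expect_equal(boundary_weight_map(z), matrix(0.5, 5, 5))
})

test_that("zero-epoch training returns an initialised model without error", {
  m <- fixture_dataset(6, "seg-zero", image_size = 32, seed = 55)
  cfg <- seg_config(n_levels = 3, base_widths = c(4, 8, 16))
  model <- train_segmentation(m, cfg, train_config(epochs = 0, seed = 1,
                                                   input_size = 32))
  expect_s3_class(model, "segnet_model")
  expect_equal(nrow(model$history), 0)
  # and its predictions plug straight into the metrics
  s <- load_sample(m[1, ])
  pr <- predict_mask(model, s$image)
  expect_equal(dim(pr$binary_mask), dim(s$mask))
  expect_identical(pr$binary_mask,
                   matrix(as.integer(pr$prob_map >= pr$threshold_used), 32, 32))
  sc <- seg_scores(pr$binary_mask, s$mask)
  expect_true(sc$iou >= 0 && sc$iou <= 1)
})
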