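test_that("segmentation scores match hand-counted pixel examples", {
  gt <- matrix(0L, 3, 3); gt[1, 1] <- 1L; gt[1, 2] <- 1L
  pred <- matrix(0L, 3, 3); pred[1, 2] <- 1L; pred[2, 2] <- 1L
  sc <- seg_scores(pred, gt)
  expect_equal(sc$tp, 1); expect_equal(sc$fp, 1); expect_equal(sc$fn, 1)
  expect_equal(sc$iou, 1 / 3)
  expect_equal(sc$precision, 50)
  expect_equal(sc$recall, 50)

  # all-foreground prediction over a half-foreground 2x2 ground truth
  gt2 <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  pred2 <- matrix(1L, 2, 2)
  sc2 <- seg_scores(pred2, gt2)
  expect_equal(sc2$recall, 100)
  expect_equal(sc2$precision, 50)
  expect_equal(sc2$iou, 0.5)

  # perfect prediction
  sc3 <- seg_scores(gt, gt)
  expect_equal(sc3$iou, 1)
  expect_equal(sc3$precision, 100)
  expect_equal(sc3$recall, 100)
})

test_that("the Dice-style denominator option implements the printed variant", {
  gt <- matrix(0L, 3, 3); gt[1, ] <- 1L       # 3 px
  pred <- gt
  expect_equal(seg_scores(pred, gt, dice_style = TRUE)$iou, 3 / 6)
  expect_equal(seg_scores(pred, gt)$iou, 1)
})

test_that("degenerate and invalid mask pairs are handled explicitly", {
  z <- matrix(0L, 4, 4)
  expect_message(sc <- seg_scores(z, z), "degenerate")
  expect_equal(sc$iou, 1)
  expect_equal(sc$precision, 100)
  expect_equal(sc$recall, 100)
  expect_error(seg_scores(matrix(0.5, 2, 2), z[1:2, 1:2]), "binary")
  expect_error(seg_scores(z, z[1:2, ]), "same shape")
})

test_that("IoU is symmetric and precision/recall swap under argument exchange", {
  set.seed(40)
  for (i in 1:20) {
    a <- random_binary_mask(8, 8); b <- random_binary_mask(8, 8)
    if (sum(a) == 0 || sum(b) == 0) next
    sa <- seg_scores(a, b); sb <- seg_scores(b, a)
    expect_equal(sa$iou, sb$iou)
    expect_equal(sa$precision, sb$recall)
    expect_equal(sa$recall, sb$precision)
  }
})

test_that("count scores match the worked example and keep the sign convention", {
  cs <- count_scores(c(5, 3, 7), c(4, 4, 7))
  expect_equal(cs$dic, 0)
  expect_equal(cs$adic, 2 / 3)
  expect_equal(cs$mse, 2 / 3)

  expect_equal(count_scores(c(4), c(4))$mse, 0)
  # under-prediction is positive DiC (gt - pred ordering)
  one <- count_scores(c(7), c(5))
  expect_equal(one$dic, 2); expect_equal(one$adic, 2); expect_equal(one$mse, 4)
  over <- count_scores(c(5), c(7))
  expect_equal(over$dic, -2)

  # structural inequalities hold on random vectors
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:20, 1)
    gt <- sample(0:10, n, replace = TRUE); pr <- sample(0:10, n, replace = TRUE)
    cs <- count_scores(gt, pr)
    expect_gte(cs$adic, abs(cs$dic))
    expect_gte(cs$mse, cs$dic^2)
  }
  expect_error(count_scores(1:3, 1:2), "equal length")
  expect_error(count_scores(numeric(0), numeric(0)), "empty")
})

test_that("evaluate_split reports per-image rows and self-consistent aggregates", {
  m <- fixture_dataset(8, "metrics-eval", image_size = 32, seed = 70)
  seg <- train_segmentation(m, seg_config(n_levels = 3, base_widths = c(4, 8, 16)),
                            train_config(epochs = 0, seed = 1, input_size = 32))
  cnt <- train_counter(m, count_config(input_mode = "rgb_mask_channel",
                                       n_blocks = 1, widths = 8,
                                       stage_strides = 2L, input_size = 32),
                       train_config(epochs = 0, seed = 1))
  out <- file.path(tempdir(), "leafseg-report")
  rep <- evaluate_split(m, "val", seg_model = seg, count_model = cnt,
                        out_dir = out)
  expect_equal(nrow(rep$per_image), sum(m$split == "val"))
  expect_equal(rep$count$adic,
               mean(abs(rep$per_image$count_gt - rep$per_image$count_pred)))
  expect_equal(rep$seg$iou, mean(rep$per_image$iou))
  expect_true(file.exists(file.path(out, "per_image.csv")))
  expect_true(file.exists(file.path(out, "summary.txt")))
  # micro aggregation pools pixels instead of averaging images
  rep2 <- evaluate_split(m, "val", seg_model = seg, aggregate = "micro")
  expect_true(rep2$seg$iou >= 0 && rep2$seg$iou <= 1)
  expect_error(evaluate_split(m, "val"), "nothing to evaluate")
  expect_error(evaluate_split(m, "test", seg_model = seg), "no records")
})
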