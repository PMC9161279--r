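# Evaluation metrics: pixel-level segmentation scores (IoU, precision,
# recall) and count regression scores (DiC, ADiC, MSE).

#' Segmentation scores for one mask pair
#'
#' Computes TP/FP/FN pixel counts and from them IoU (fraction), precision and
#' recall (percent).  The default IoU is the standard
#' intersection-over-union `|P_gt ∩ P_pred| / |P_gt ∪ P_pred|`;
#' `dice_style = TRUE` instead divides the intersection by `|P_gt| + |P_pred|`
#' (a Dice-style denominator) for comparison.  When both masks are empty the
#' pair is degenerate-perfect: IoU 1, precision and recall 100 (a message is
#' emitted so the convention is visible in logs).  A ratio that is undefined
#' on a non-empty pair (empty prediction or empty ground truth) scores 0.
#'
#' @param pred,gt Binary 0/1 matrices of equal shape.
#' @param dice_style Use `|gt| + |pred|` as the denominator of the overlap
#'   score instead of the union.
#' @return A `seg_scores` list: `iou`, `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
seg_scores <- function(pred, gt, dice_style = FALSE) {
  if (!all(dim(pred) == dim(gt)))
    stop("`pred` and `gt` must have the same shape", call. = FALSE)
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("masks must be binary 0/1", call. = FALSE)
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  if (tp + fp + fn == 0) {
    message("seg_scores: both masks empty; reporting degenerate-perfect scores")
    out <- list(iou = 1, precision = 100, recall = 100, tp = 0L, fp = 0L, fn = 0L)
    class(out) <- "seg_scores"
    return(out)
  }
  denom <- if (dice_style) (tp + fn) + (tp + fp) else tp + fp + fn
  out <- list(iou = tp / denom,
              precision = if (tp + fp > 0) 100 * tp / (tp + fp) else 0,
              recall = if (tp + fn > 0) 100 * tp / (tp + fn) else 0,
              tp = tp, fp = fp, fn = fn)
  class(out) <- "seg_scores"
  out
}

#' Count regression scores
#'
#' Difference in Count `DiC = mean(gt - pred)` (under-prediction is
#' positive), Absolute Difference in Count `ADiC = mean(|gt - pred|)` and
#' `MSE = mean((gt - pred)^2)`, with standard deviations of the per-image
#' differences reported alongside.
#'
#' @param gt,pred Equal-length numeric vectors of leaf counts.
#' @return A `count_scores` list: `dic`, `adic`, `mse`, `dic_sd`, `adic_sd`,
#'   `per_image_errors` (the vector `gt - pred`).
#' @export
count_scores <- function(gt, pred) {
  if (length(gt) != length(pred))
    stop("`gt` and `pred` must have equal length", call. = FALSE)
  if (length(gt) == 0) stop("empty count vectors", call. = FALSE)
  e <- gt - pred
  out <- list(dic = mean(e), adic = mean(abs(e)), mse = mean(e^2),
              dic_sd = stats::sd(e), adic_sd = stats::sd(abs(e)),
              per_image_errors = e)
  class(out) <- "count_scores"
  out
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf("IoU %.4f | Precision %.2f%% | Recall %.2f%% (TP %d, FP %d, FN %d)\n",
              x$iou, x$precision, x$recall, x$tp, x$fp, x$fn))
  invisible(x)
}

#' @export
print.count_scores <- function(x, ...) {
  cat(sprintf("DiC %.3f (%.3f) | ADiC %.3f (%.3f) | MSE %.3f  [n = %d]\n",
              x$dic, x$dic_sd, x$adic, x$adic_sd, x$mse,
              length(x$per_image_errors)))
  invisible(x)
}

#' Evaluate trained models over a manifest split
#'
#' Runs the segmentation and/or counting model over every record of the
#' requested split and aggregates per-image scores.  Segmentation scores are
#' macro-averaged (unweighted mean of per-image scores) by default;
#' `aggregate = "micro"` pools TP/FP/FN pixel counts over the split instead.
#'
#' @param manifest Manifest data frame with filled `split` column.
#' @param split Which split to evaluate (`"val"`, `"train"`, `"test"`).
#' @param seg_model Optional trained segmentation model.
#' @param count_model Optional trained counting model.
#' @param mode Counting input mode (see [count_config()]); masks for
#'   mask-using modes come from `seg_model` predictions when one is given,
#'   otherwise from the ground-truth masks.
#' @param aggregate `"macro"` or `"micro"` segmentation aggregation.
#' @param out_dir Optional directory for `per_image.csv` and `summary.txt`.
#' @return An `eval_report` list with `per_image` (data frame), `seg`
#'   (aggregate seg scores or `NULL`) and `count` ([count_scores] or `NULL`).
#' @export
evaluate_split <- function(manifest, split = "val", seg_model = NULL,
                           count_model = NULL, mode = NULL,
                           aggregate = c("macro", "micro"), out_dir = NULL) {
  aggregate <- match.arg(aggregate)
  recs <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(recs) == 0) stop("no records in split '", split, "'", call. = FALSE)
  if (is.null(seg_model) && is.null(count_model))
    stop("nothing to evaluate: supply `seg_model` and/or `count_model`", call. = FALSE)
  if (!is.null(count_model) && is.null(mode)) mode <- count_model$config$input_mode

  rows <- vector("list", nrow(recs))
  tp <- fp <- fn <- 0
  gt_counts <- pred_counts <- numeric(0)
  for (i in seq_len(nrow(recs))) {
    sm <- load_sample(recs[i, ])
    row <- list(image = recs$image[i])
    pred_mask <- NULL
    if (!is.null(seg_model)) {
      sp <- predict_mask(seg_model, sm$image)
      pred_mask <- sp$binary_mask
      sc <- seg_scores(pred_mask, sm$mask)
      tp <- tp + sc$tp; fp <- fp + sc$fp; fn <- fn + sc$fn
      row$iou <- sc$iou; row$precision <- sc$precision; row$recall <- sc$recall
    }
    if (!is.null(count_model)) {
      use_mask <- if (!is.null(pred_mask)) pred_mask else sm$mask
      cp <- predict_count(count_model, sm$image, mask = use_mask, mode = mode)
      gt_counts <- c(gt_counts, sm$count)
      pred_counts <- c(pred_counts, cp$rounded)
      row$count_gt <- sm$count; row$count_pred <- cp$rounded; row$count_raw <- cp$raw
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  per_image <- do.call(rbind, rows)

  seg <- NULL
  if (!is.null(seg_model)) {
    seg <- if (aggregate == "macro") {
      list(iou = mean(per_image$iou), precision = mean(per_image$precision),
           recall = mean(per_image$recall))
    } else {
      list(iou = tp / (tp + fp + fn), precision = 100 * tp / (tp + fp),
           recall = 100 * tp / (tp + fn))
    }
  }
  cnt <- if (!is.null(count_model)) count_scores(gt_counts, pred_counts) else NULL

  report <- structure(list(per_image = per_image, seg = seg, count = cnt,
                           split = split, n = nrow(per_image),
                           aggregate = aggregate),
                      class = "eval_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_image, file.path(out_dir, "per_image.csv"), row.names = FALSE)
    writeLines(utils::capture.output(print(report)), file.path(out_dir, "summary.txt"))
  }
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over split '%s' (%d images, %s aggregation)\n",
              x$split, x$n, x$aggregate))
  if (!is.null(x$seg))
    cat(sprintf("  segmentation: IoU %.4f | Precision %.2f%% | Recall %.2f%%\n",
                x$seg$iou, x$seg$precision, x$seg$recall))
  if (!is.null(x$count))
    cat(sprintf("  counting:     DiC %.3f | ADiC %.3f | MSE %.3f\n",
                x$count$dic, x$count$adic, x$count$mse))
  invisible(x)
}
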