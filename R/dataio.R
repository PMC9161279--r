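# Reading/writing samples and manifests, the resize/normalise pipeline, the
# paired image-mask augmentation scheme, and train/validation splitting.
#
# Conventions: images are (H, W, 3) double arrays in [0, 1]; masks are
# (H, W) integer matrices in {0, 1}; row-major top-left origin, 1-based
# indexing.  Geometric augmentations are applied identically to image and
# mask; photometric ones touch the image only, so the annotation stays
# consistent with the pixels.

#' Write / read a dataset manifest
#'
#' The manifest is a CSV with header `image,mask,count,split`; `mask` may be
#' empty for unlabelled records and `split` is one of `""`, `"train"`,
#' `"val"`, `"test"`.
#'
#' @param manifest Data frame with those columns.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(image = "character", mask = "character",
                                      count = "integer", split = "character"))
  m
}

#' Load one sample record
#'
#' @param record One manifest row (list or single-row data frame) with at
#'   least `image`; optionally `mask` and `count`.
#' @return List with `image` (`H x W x 3` double, scaled to `[0, 1]`),
#'   `mask` (0/1 integer matrix or `NULL`), `count` (integer or `NA`).
#' @export
load_sample <- function(record) {
  if (!file.exists(record$image))
    stop("image file not found: ", record$image, call. = FALSE)
  img <- png::readPNG(record$image)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  mask <- NULL
  if (!is.null(record$mask) && !is.na(record$mask) && nzchar(record$mask)) {
    if (!file.exists(record$mask))
      stop("mask file not found: ", record$mask, call. = FALSE)
    m <- png::readPNG(record$mask)
    if (length(dim(m)) == 3) m <- m[, , 1]
    if (!all(dim(m) == dim(img)[1:2]))
      stop("mask shape does not match image shape", call. = FALSE)
    mask <- matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
  }
  count <- if (!is.null(record$count)) as.integer(record$count) else NA_integer_
  list(image = img, mask = mask, count = count)
}

#' Resize an image/mask pair
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbour sampling and re-binarisation, so the annotation stays
#' crisp at any scale.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param mask 0/1 matrix or `NULL`.
#' @param target Output side length in pixels (>= 8).
#' @return List `image`, `mask`, both `target x target`.
#' @export
resize_pair <- function(image, mask, target) {
  if (target < 8) stop("`target` must be >= 8", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h != target || w != target)
    image <- nn_resize_bilinear(image, target, target)
  image <- pmin(pmax(image, 0), 1)
  if (!is.null(mask)) {
    if (nrow(mask) != target || ncol(mask) != target) {
      ri <- pmin(pmax(round((seq_len(target) - 0.5) * nrow(mask) / target + 0.5), 1), nrow(mask))
      ci <- pmin(pmax(round((seq_len(target) - 0.5) * ncol(mask) / target + 0.5), 1), ncol(mask))
      mask <- matrix(as.integer(mask[ri, ci] >= 1L), target, target)
    }
  }
  list(image = image, mask = mask)
}

#' Augmentation configuration
#'
#' Mirrors the training-time augmentation scheme: 90-degree rotations, flips,
#' random rescaling, gamma, brightness, contrast and HSV shifts, plus final
#' normalisation.  Geometric steps transform image and mask identically;
#' colour steps leave the mask untouched.
#'
#' @param rotate90 Enable random 0/90/180/270-degree rotation.
#' @param flips Subset of `c("h", "v", "hv")` to draw from (plus "none").
#' @param scale_range Random rescale factor range (resize then centre
#'   crop/pad back to the input size).
#' @param gamma_range,brightness_range,contrast_range Photometric ranges;
#'   set to `NULL` to disable a step.
#' @param hsv_shift Per-channel additive shifts `c(h, s, v)` giving the
#'   maximum absolute shift of hue (fraction of the hue circle), saturation
#'   and value; `NULL` disables.
#' @param normalize Keep images clipped to `[0, 1]` after photometric steps.
#' @param p Per-step application probability.
#' @return An object of class `aug_config`.
#' @export
aug_config <- function(rotate90 = TRUE, flips = c("h", "v", "hv"),
                       scale_range = c(0.8, 1.2), gamma_range = c(0.7, 1.5),
                       brightness_range = c(0.8, 1.2),
                       contrast_range = c(0.8, 1.2),
                       hsv_shift = c(0.02, 0.1, 0.1),
                       normalize = TRUE, p = 0.5) {
  chk <- function(r, nm) {
    if (!is.null(r) && (length(r) != 2 || r[1] > r[2]))
      stop("range `", nm, "` must be ordered c(lo, hi)", call. = FALSE)
  }
  chk(scale_range, "scale_range"); chk(gamma_range, "gamma_range")
  chk(brightness_range, "brightness_range"); chk(contrast_range, "contrast_range")
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  structure(list(rotate90 = rotate90, flips = flips, scale_range = scale_range,
                 gamma_range = gamma_range, brightness_range = brightness_range,
                 contrast_range = contrast_range, hsv_shift = hsv_shift,
                 normalize = normalize, p = p),
            class = "aug_config")
}

# Rotate by k*90 degrees counter-clockwise (transpose, then reverse rows).
rot90_img <- function(x, k) {
  k <- k %% 4
  for (i in seq_len(k)) {
    if (length(dim(x)) == 2) {
      x <- t(x)
      x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
    } else {
      x <- aperm(x, c(2, 1, 3))
      x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
    }
  }
  x
}

flip_img <- function(x, mode) {
  d2 <- length(dim(x)) == 2
  if (mode %in% c("h", "hv")) {  # horizontal flip: reverse columns
    x <- if (d2) x[, rev(seq_len(ncol(x))), drop = FALSE]
    else x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  }
  if (mode %in% c("v", "hv")) {  # vertical flip: reverse rows
    x <- if (d2) x[rev(seq_len(nrow(x))), , drop = FALSE]
    else x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  }
  x
}

# Rescale by `s` and crop/pad back to the original size; image edges are
# replicated by the crop/pad, mask padding is background.
rescale_keep_size <- function(image, mask, s) {
  h <- dim(image)[1]; w <- dim(image)[2]
  nh <- max(8L, round(h * s)); nw <- max(8L, round(w * s))
  img2 <- nn_resize_bilinear(image, nh, nw)
  msk2 <- NULL
  if (!is.null(mask)) {
    ri <- pmin(pmax(round((seq_len(nh) - 0.5) * h / nh + 0.5), 1), h)
    ci <- pmin(pmax(round((seq_len(nw) - 0.5) * w / nw + 0.5), 1), w)
    msk2 <- mask[ri, ci, drop = FALSE]
  }
  if (nh >= h) {
    top <- floor((nh - h) / 2); left <- floor((nw - w) / 2)
    img <- img2[top + seq_len(h), left + seq_len(w), , drop = FALSE]
    msk <- if (is.null(msk2)) NULL else msk2[top + seq_len(h), left + seq_len(w), drop = FALSE]
  } else {
    top <- floor((h - nh) / 2); left <- floor((w - nw) / 2)
    ri <- pmin(pmax(seq_len(h) - top, 1), nh)   # replicate edges
    ci <- pmin(pmax(seq_len(w) - left, 1), nw)
    img <- img2[ri, ci, , drop = FALSE]
    msk <- NULL
    if (!is.null(msk2)) {
      msk <- matrix(0L, h, w)
      msk[top + seq_len(nh), left + seq_len(nw)] <- msk2
    }
  }
  list(image = img, mask = msk)
}

rgb_to_hsv_arr <- function(img) {
  d <- dim(img)
  m <- grDevices::rgb2hsv(t(matrix(img, d[1] * d[2], 3)), maxColorValue = 1)
  array(t(m), c(d[1], d[2], 3))
}

hsv_to_rgb_arr <- function(hsv) {
  h <- hsv[, , 1] %% 1; s <- pmin(pmax(hsv[, , 2], 0), 1); v <- pmin(pmax(hsv[, , 3], 0), 1)
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dim(hsv))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Apply one random augmentation draw to an image/mask pair
#'
#' Each enabled step fires independently with probability `p`.  Geometric
#' steps (rotation, flip, rescale) transform image and mask identically;
#' photometric steps (gamma, brightness, contrast, HSV) modify the image
#' only.  The returned `log` records every applied step and its drawn
#' parameters.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param mask 0/1 matrix or `NULL`.
#' @param config An [aug_config()].
#' @param seed Optional seed for this draw; `NULL` uses the current RNG
#'   stream.
#' @return List `image`, `mask`, `log`.
#' @export
apply_augmentation <- function(image, mask, config, seed = NULL) {
  if (!is.null(mask) && !all(dim(mask) == dim(image)[1:2]))
    stop("image and mask shapes disagree", call. = FALSE)
  run <- function() {
    log <- list()
    fire <- function() stats::runif(1) < config$p
    if (isTRUE(config$rotate90) && fire()) {
      k <- sample(0:3, 1)
      image <<- rot90_img(image, k)
      if (!is.null(mask)) mask <<- rot90_img(mask, k)
      log$rotate90 <- k
    }
    if (length(config$flips) && fire()) {
      mode <- sample(config$flips, 1)
      image <<- flip_img(image, mode)
      if (!is.null(mask)) mask <<- flip_img(mask, mode)
      log$flip <- mode
    }
    if (!is.null(config$scale_range) && fire()) {
      s <- stats::runif(1, config$scale_range[1], config$scale_range[2])
      out <- rescale_keep_size(image, mask, s)
      image <<- out$image; if (!is.null(mask)) mask <<- out$mask
      log$scale <- s
    }
    if (!is.null(config$gamma_range) && fire()) {
      g <- stats::runif(1, config$gamma_range[1], config$gamma_range[2])
      image <<- pmin(pmax(image, 0), 1)^g
      log$gamma <- g
    }
    if (!is.null(config$brightness_range) && fire()) {
      f <- stats::runif(1, config$brightness_range[1], config$brightness_range[2])
      image <<- image * f
      log$brightness <- f
    }
    if (!is.null(config$contrast_range) && fire()) {
      f <- stats::runif(1, config$contrast_range[1], config$contrast_range[2])
      mu <- mean(image)
      image <<- mu + (image - mu) * f
      log$contrast <- f
    }
    if (!is.null(config$hsv_shift) && fire()) {
      sh <- stats::runif(3, -config$hsv_shift, config$hsv_shift)
      hsv <- rgb_to_hsv_arr(pmin(pmax(image, 0), 1))
      hsv[, , 1] <- hsv[, , 1] + sh[1]
      hsv[, , 2] <- hsv[, , 2] + sh[2]
      hsv[, , 3] <- hsv[, , 3] + sh[3]
      image <<- hsv_to_rgb_arr(hsv)
      log$hsv <- sh
    }
    if (isTRUE(config$normalize)) image <<- pmin(pmax(image, 0), 1)
    log
  }
  log <- if (is.null(seed)) run() else with_rng(seed, run())
  if (!is.null(mask)) mask <- matrix(as.integer(mask >= 1L), nrow(mask), ncol(mask))
  list(image = image, mask = mask, log = log)
}

#' Split a manifest into train and validation sets
#'
#' Shuffles records with the given seed and tags the first `ratio` fraction
#' as `"train"` and the remainder as `"val"`; the result is a partition.
#'
#' @param manifest Manifest data frame.
#' @param ratio Train fraction in (0, 1); default 0.8 for the conventional
#'   80/20 split.
#' @param seed Shuffle seed.
#' @return The manifest with the `split` column filled.
#' @export
split_dataset <- function(manifest, ratio = 0.8, seed = 1L) {
  n <- nrow(manifest)
  if (n < 2) stop("need at least 2 records to split", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  ord <- with_rng(seed, sample.int(n))
  n_train <- max(1L, min(n - 1L, round(n * ratio)))
  manifest$split[ord[seq_len(n_train)]] <- "train"
  manifest$split[ord[(n_train + 1):n]] <- "val"
  manifest
}
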