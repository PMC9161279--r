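# Counting stream: a residual regression network that maps an input
# assembled from the RGB image (and optionally the segmented binary mask) to
# a single real-valued leaf count.
#
# Architecture: a stem convolution, then residual units grouped into stages
# (one width per stage, spatial downsampling at each stage entry), global
# average pooling and a single-output fully connected head.

#' Counting network configuration
#'
#' @param input_mode How training items are assembled from a sample:
#'   `"rgb"` (image only), `"rgb_mask_channel"` (4-channel image + binary
#'   mask), `"mixture"` (two 3-channel items per sample: the RGB image and
#'   the mask replicated to three channels, both with the same count label)
#'   or `"rgb_x2"` (the RGB item duplicated, a sample-doubling control).
#' @param n_blocks Total number of residual units (>= 1), distributed evenly
#'   over the stages; paper-scale backbones use 16.
#' @param stem_kernel Stem convolution size (3 for the desk profile, 7 for
#'   a paper-scale backbone).
#' @param widths Channel count per stage.
#' @param stage_strides Spatial stride applied by the first unit of each
#'   stage (default 2 per stage).
#' @param input_size Square input resolution the network is trained at
#'   (desk default 64; paper-scale backbones use 224-480).
#' @return An object of class `count_config`.
#' @export
count_config <- function(input_mode = c("rgb_mask_channel", "rgb", "mixture", "rgb_x2"),
                         n_blocks = 4L, stem_kernel = 3L,
                         widths = c(16, 32, 64, 128),
                         stage_strides = NULL, input_size = 64L) {
  input_mode <- match.arg(input_mode)
  if (n_blocks < 1) stop("`n_blocks` must be >= 1", call. = FALSE)
  if (stem_kernel %% 2 != 1) stop("`stem_kernel` must be odd", call. = FALSE)
  if (is.null(stage_strides)) stage_strides <- rep(2L, length(widths))
  if (length(stage_strides) != length(widths))
    stop("`stage_strides` must match `widths`", call. = FALSE)
  structure(list(input_mode = input_mode, n_blocks = as.integer(n_blocks),
                 stem_kernel = as.integer(stem_kernel),
                 widths = as.integer(widths),
                 stage_strides = as.integer(stage_strides),
                 input_size = as.integer(input_size)),
            class = "count_config")
}

#' In-channel count implied by an input mode
#' @param mode One of the [count_config()] input modes.
#' @return 4 for `"rgb_mask_channel"`, otherwise 3.
#' @export
mode_channels <- function(mode) if (mode == "rgb_mask_channel") 4L else 3L

# Distribute n_blocks over n_stages as evenly as possible (later stages get
# the remainder, mirroring common residual backbones that deepen late).
blocks_per_stage <- function(n_blocks, n_stages) {
  base <- n_blocks %/% n_stages
  extra <- n_blocks %% n_stages
  counts <- rep(base, n_stages)
  if (extra > 0) counts[seq(n_stages - extra + 1, n_stages)] <- base + 1
  if (n_blocks < n_stages) {
    counts <- rep(0L, n_stages)
    counts[seq_len(n_blocks)] <- 1L
  }
  counts
}

init_count_params <- function(config, seed) {
  with_rng(seed, {
    k <- config$stem_kernel
    cin <- mode_channels(config$input_mode)
    w <- config$widths
    p <- list(stem_w = init_conv_w(k, k, cin, w[1]), stem_b = numeric(w[1]))
    bps <- blocks_per_stage(config$n_blocks, length(w))
    prev <- w[1]
    for (s in seq_along(w)) {
      for (b in seq_len(bps[s])) {
        key <- sprintf("s%d_b%d", s, b)
        cin_b <- if (b == 1) prev else w[s]
        st <- if (b == 1) config$stage_strides[s] else 1L
        p[[paste0(key, "_w1")]] <- init_conv_w(3, 3, cin_b, w[s])
        p[[paste0(key, "_b1")]] <- numeric(w[s])
        p[[paste0(key, "_w2")]] <- init_conv_w(3, 3, w[s], w[s])
        p[[paste0(key, "_b2")]] <- numeric(w[s])
        if (cin_b != w[s] || st != 1) {
          p[[paste0(key, "_pw")]] <- init_conv_w(1, 1, cin_b, w[s])
          p[[paste0(key, "_pb")]] <- numeric(w[s])
        }
      }
      if (bps[s] > 0) prev <- w[s]
    }
    p$head_w <- init_dense_w(prev, 1)
    p$head_b <- numeric(1)
    p
  })
}

count_forward_nodes <- function(pn, xnode, config) {
  k <- config$stem_kernel
  h <- op_relu(op_conv2d(xnode, pn$stem_w, pn$stem_b, 1L, (k - 1L) %/% 2L))
  w <- config$widths
  bps <- blocks_per_stage(config$n_blocks, length(w))
  for (s in seq_along(w)) {
    for (b in seq_len(bps[s])) {
      key <- sprintf("s%d_b%d", s, b)
      st <- if (b == 1) config$stage_strides[s] else 1L
      f <- op_relu(op_conv2d(h, pn[[paste0(key, "_w1")]], pn[[paste0(key, "_b1")]], st, 1L))
      f <- op_conv2d(f, pn[[paste0(key, "_w2")]], pn[[paste0(key, "_b2")]], 1L, 1L)
      sc <- if (!is.null(pn[[paste0(key, "_pw")]])) {
        op_conv2d(h, pn[[paste0(key, "_pw")]], pn[[paste0(key, "_pb")]], st, 0L)
      } else h
      h <- op_relu(op_add(sc, f))
    }
  }
  op_dense(op_gap(h), pn$head_w, pn$head_b)   # (N, 1)
}

#' One residual unit
#'
#' `x_{l+1} = ReLU(h(x_l) + F(x_l))` with `h` the identity mapping; when the
#' branch output is zero and the input is elementwise non-negative the unit
#' is exactly the identity, which is what makes deep stacks trainable.
#'
#' @param x Input array.
#' @param branch Function computing the residual branch `F(x)`; its output
#'   must have the shape of `x`.
#' @return Array of the same shape as `x`.
#' @export
residual_unit <- function(x, branch) {
  fx <- branch(x)
  if (!identical(dim(fx), dim(x)) && length(fx) != length(x))
    stop("residual branch output shape does not match input", call. = FALSE)
  pmax(x + fx, 0)
}

#' Assemble counting-network inputs from labelled samples
#'
#' @param samples List of samples, each a list with `image` (`(H, W, 3)` in
#'   `[0, 1]`), `mask` (0/1 matrix, required for mask-using modes) and
#'   `count`.
#' @param mode Input mode (see [count_config()]).
#' @return List of items, each `list(x = array, count = )`: one 3-channel
#'   item per sample for `"rgb"`; one 4-channel item for
#'   `"rgb_mask_channel"`; two items (RGB and 3x-replicated mask) for
#'   `"mixture"`; two identical RGB items for `"rgb_x2"`.
#' @export
assemble_inputs <- function(samples, mode = "rgb_mask_channel") {
  items <- list()
  for (s in samples) {
    if (mode != "rgb" && mode != "rgb_x2" && is.null(s$mask))
      stop("input mode '", mode, "' requires a mask for every sample", call. = FALSE)
    d <- dim(s$image)
    if (mode == "rgb") {
      items[[length(items) + 1]] <- list(x = s$image, count = s$count)
    } else if (mode == "rgb_mask_channel") {
      x <- array(0, c(d[1], d[2], 4))
      x[, , 1:3] <- s$image
      x[, , 4] <- s$mask
      items[[length(items) + 1]] <- list(x = x, count = s$count)
    } else if (mode == "mixture") {
      m3 <- array(rep(as.numeric(s$mask), 3), c(d[1], d[2], 3))
      items[[length(items) + 1]] <- list(x = s$image, count = s$count)
      items[[length(items) + 1]] <- list(x = m3, count = s$count)
    } else if (mode == "rgb_x2") {
      items[[length(items) + 1]] <- list(x = s$image, count = s$count)
      items[[length(items) + 1]] <- list(x = s$image, count = s$count)
    } else stop("unknown input mode: ", mode, call. = FALSE)
  }
  items
}

#' Mean-squared-error counting loss
#'
#' `(1/m) * sum((pred - gt)^2)` on raw (unrounded) predictions.
#'
#' @param pred,gt Equal-length numeric vectors.
#' @return Scalar loss.
#' @export
count_loss <- function(pred, gt) {
  if (length(pred) == 0) stop("empty batch", call. = FALSE)
  if (length(pred) != length(gt)) stop("length mismatch", call. = FALSE)
  mean((pred - gt)^2)
}

#' Initialise a counting model
#' @param config A [count_config()].
#' @param seed Weight-initialisation seed.
#' @return A `countnet_model` (untrained).
#' @export
init_countnet <- function(config = count_config(), seed = 1L) {
  structure(list(config = config, params = init_count_params(config, seed),
                 seed = seed,
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      val_adic = numeric())),
            class = "countnet_model")
}

# Adapt a 3-channel stem to 4 channels by initialising the extra channel's
# filters to the mean of the RGB filters; used when externally supplied
# (3-channel) initial weights are loaded into a 4-channel model.
adapt_stem_weights <- function(stem_w) {
  d <- dim(stem_w)
  out <- array(0, c(d[1], d[2], 4, d[4]))
  out[, , 1:3, ] <- stem_w
  out[, , 4, ] <- apply(stem_w, c(1, 2, 4), mean)
  out
}

#' Train the counting stream
#'
#' Optimises the MSE objective with Adam over items assembled per the
#' config's input mode (masks come from the ground truth during training);
#' logs per-epoch loss and validation ADiC and returns the
#' best-validation-ADiC weights.
#'
#' @param manifest Manifest with `train` and `val` splits, counts, and mask
#'   paths when the mode needs them.
#' @param config A [count_config()].
#' @param train_config A [train_config()]; `init_params` may carry externally
#'   supplied starting weights (a 3-channel stem is widened via the mean-RGB
#'   rule when the mode needs 4 channels).
#' @return A trained `countnet_model`.
#' @export
train_counter <- function(manifest, config = count_config(), train_config = NULL) {
  tc <- if (is.null(train_config)) leafseg::train_config() else train_config
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  va <- manifest[manifest$split == "val", , drop = FALSE]
  if (nrow(tr) == 0 || nrow(va) == 0)
    stop("manifest needs non-empty 'train' and 'val' splits", call. = FALSE)
  if (any(is.na(tr$count)) || any(is.na(va$count)))
    stop("every record needs a `count` for counter training", call. = FALSE)
  size <- config$input_size

  load_all <- function(recs) {
    lapply(seq_len(nrow(recs)), function(i) {
      sm <- load_sample(recs[i, ])
      rp <- resize_pair(sm$image, sm$mask, size)
      list(image = rp$image, mask = rp$mask, count = sm$count)
    })
  }
  tr_s <- load_all(tr); va_s <- load_all(va)
  items <- assemble_inputs(tr_s, config$input_mode)

  model <- init_countnet(config, seed = tc$seed)
  if (!is.null(tc$init_params)) {
    ip <- tc$init_params
    if (dim(ip$stem_w)[3] == 3 && mode_channels(config$input_mode) == 4)
      ip$stem_w <- adapt_stem_weights(ip$stem_w)
    model$params[names(ip)] <- ip
  }
  if (tc$epochs == 0) return(model)

  params <- model$params
  state <- adam_init(params)
  lr <- tc$lr
  cin <- mode_channels(config$input_mode)
  best <- list(adic = Inf, params = params)
  hist <- vector("list", tc$epochs)
  wait <- 0L

  cin_val <- mode_channels(config$input_mode)
  va_x <- array(0, c(size, size, cin_val, length(va_s)))
  for (k in seq_along(va_s)) {
    va_x[, , 1:3, k] <- va_s[[k]]$image
    if (cin_val == 4) va_x[, , 4, k] <- va_s[[k]]$mask
  }
  va_counts <- vapply(va_s, function(s) s$count, numeric(1))
  val_adic <- function(params) {
    preds <- numeric(length(va_s))
    for (bi in seq(1, length(va_s), by = 16)) {
      ids <- bi:min(bi + 15, length(va_s))
      pn <- wrap_params(params)
      raw <- as.numeric(count_forward_nodes(pn, tg_leaf(va_x[, , , ids, drop = FALSE]),
                                            config)$value)
      preds[ids] <- vapply(raw, round_count, integer(1))
    }
    mean(abs(va_counts - preds))
  }

  with_rng(tc$seed + 2L, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(length(items))
      ep_loss <- 0; nb <- 0
      for (bi in seq(1, length(ord), by = tc$batch_size)) {
        ids <- ord[bi:min(bi + tc$batch_size - 1, length(ord))]
        B <- length(ids)
        x <- array(0, c(size, size, cin, B))
        y <- numeric(B)
        for (k in seq_len(B)) {
          it <- items[[ids[k]]]
          xi <- it$x
          if (!is.null(tc$augment)) {
            if (cin == 4) {
              a <- apply_augmentation(xi[, , 1:3, drop = FALSE],
                                      matrix(as.integer(xi[, , 4] >= 0.5), size, size),
                                      tc$augment)
              xi[, , 1:3] <- a$image; xi[, , 4] <- a$mask
            } else {
              a <- apply_augmentation(xi, NULL, tc$augment)
              xi <- a$image
            }
          }
          x[, , , k] <- xi
          y[k] <- it$count
        }
        pn <- wrap_params(params)
        out <- count_forward_nodes(pn, tg_leaf(x), config)
        pred <- as.numeric(out$value)
        loss <- count_loss(pred, y)
        seed_grad <- matrix(2 * (pred - y) / B, B, 1)
        grads <- run_backward(pn, out, seed_grad)
        upd <- adam_step(params, grads, state, lr = lr, weight_decay = tc$weight_decay)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      va_m <- val_adic(params)
      hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / nb, val_adic = va_m)
      if (va_m < best$adic) {
        best <- list(adic = va_m, params = params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (isTRUE(tc$reduce_on_plateau) && wait >= tc$patience) {
          lr <- lr * tc$lr_factor
          wait <- 0L
        }
      }
      if (isTRUE(tc$verbose))
        message(sprintf("epoch %3d | mse %.4f | val ADiC %.3f", epoch, ep_loss / nb, va_m))
    }
  })
  model$params <- best$params
  model$best_adic <- best$adic
  model$history <- do.call(rbind, hist)
  model
}

# Round half away from zero, floored at 0 (counts cannot be negative).
round_count <- function(x) max(0L, as.integer(sign(x) * floor(abs(x) + 0.5)))

#' Predict a leaf count for one image
#'
#' For `"mixture"` and `"rgb_x2"` modes inference uses the RGB
#' representation only; `"rgb_mask_channel"` requires a mask (ground truth
#' or a segmentation-stream prediction).
#'
#' @param model Trained `countnet_model`.
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param mask Optional 0/1 matrix.
#' @param mode Input mode; defaults to the model's.
#' @return A `count_prediction`: `raw` (real) and `rounded` (integer >= 0,
#'   half away from zero).
#' @export
predict_count <- function(model, image, mask = NULL, mode = NULL) {
  if (is.null(mode)) mode <- model$config$input_mode
  size <- model$config$input_size
  rp <- resize_pair(image, mask, size)
  cin <- mode_channels(mode)
  if (cin == 4) {
    if (is.null(mask))
      stop("input mode 'rgb_mask_channel' requires a mask", call. = FALSE)
    x <- array(0, c(size, size, 4, 1))
    x[, , 1:3, 1] <- rp$image
    x[, , 4, 1] <- rp$mask
  } else {
    x <- array(rp$image, c(size, size, 3, 1))
  }
  pn <- wrap_params(model$params)
  raw <- as.numeric(count_forward_nodes(pn, tg_leaf(x), model$config)$value)
  structure(list(raw = raw, rounded = round_count(raw)),
            class = "count_prediction")
}

#' @export
print.count_prediction <- function(x, ...) {
  cat(sprintf("leaf count: raw %.3f, rounded %d\n", x$raw, x$rounded))
  invisible(x)
}
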