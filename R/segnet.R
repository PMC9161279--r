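# Segmentation stream: an encoder-decoder with nested dense skip pathways.
#
# The computation graph is triangular: node (i, j) lives at resolution level
# i (spatial size / 2^i) and skip depth j.  Backbone column j = 0 is the
# encoder; node (i, 0) receives only the 2x2-max-pooled output of (i-1, 0).
# A node (i, j > 0) receives the j same-level outputs x^{i,0..j-1} plus the
# upsampled output of (i+1, j-1), concatenated along channels.  Every node
# applies two 3x3 convolutions, each followed by a ReLU.  The head is a 1x1
# convolution with logistic activation on x^{0, L-1}, giving a per-pixel
# foreground probability.

#' Segmentation network configuration
#'
#' @param n_levels Number of resolution levels (default 5, i.e. L1-L5).
#' @param base_widths Channel count per level, strictly increasing; the
#'   default (8, 16, 32, 64, 128) is the desk-scale profile, use
#'   (32, 64, 128, 256, 512) for a paper-scale instantiation.
#' @param upsample_mode `"bilinear"` (bilinear interpolation followed by a
#'   1x1 convolution) or `"transposed_conv"` (learned 2x2 stride-2
#'   deconvolution).
#' @param deep_supervision When `TRUE` the (shared) head is applied to every
#'   top-level node x^{0,1..L-1} and the probabilities are averaged.
#' @param output_threshold Binarisation threshold in (0, 1).
#' @param loss_weights Named vector `c(bce = , dice = )` weighting the two
#'   loss terms; the default (1/2, 1) mirrors the coefficients of the
#'   published combined objective.
#' @param use_boundary_weight_map Weight the BCE term by
#'   [boundary_weight_map()] of the ground truth.
#' @param w0,sigma Boundary weight-map amplitude and spread (pixels).
#' @param loss_form `"standard"` (BCE + 1 - soft Dice) or `"as_printed"`
#'   (the literal per-pixel formula; diagnostic only, not a usable training
#'   objective for background pixels).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(n_levels = 5L, base_widths = c(8, 16, 32, 64, 128),
                       upsample_mode = c("bilinear", "transposed_conv"),
                       deep_supervision = FALSE, output_threshold = 0.5,
                       loss_weights = c(bce = 0.5, dice = 1),
                       use_boundary_weight_map = FALSE, w0 = 10, sigma = 0.5,
                       loss_form = c("standard", "as_printed")) {
  upsample_mode <- match.arg(upsample_mode)
  loss_form <- match.arg(loss_form)
  if (n_levels < 2) stop("`n_levels` must be >= 2", call. = FALSE)
  if (length(base_widths) != n_levels)
    stop("`base_widths` must have one entry per level", call. = FALSE)
  if (any(diff(base_widths) <= 0))
    stop("`base_widths` must be strictly increasing", call. = FALSE)
  if (output_threshold <= 0 || output_threshold >= 1)
    stop("`output_threshold` must be in (0, 1)", call. = FALSE)
  structure(list(n_levels = as.integer(n_levels),
                 base_widths = as.integer(base_widths),
                 upsample_mode = upsample_mode,
                 deep_supervision = deep_supervision,
                 output_threshold = output_threshold,
                 loss_weights = loss_weights,
                 use_boundary_weight_map = use_boundary_weight_map,
                 w0 = w0, sigma = sigma, loss_form = loss_form),
            class = "seg_config")
}

#' Build the nested-skip node graph
#'
#' Enumerates the triangular index set of nodes `(i, j)` with
#' `i + j <= n_levels - 1` and records each node's inputs: the pooled encoder
#' input for `j = 0`, and the `j` same-level predecessors plus one upsampled
#' lower-level node for `j > 0` (in-degree `j + 1`).
#'
#' @param config A [seg_config()].
#' @return A `seg_graph`: list of nodes keyed `"i,j"`, each with `i`, `j`,
#'   `inputs` (character vector of source descriptions), `in_degree`, and
#'   `out_channels`.
#' @export
build_node_graph <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  L <- config$n_levels
  nodes <- list()
  for (j in 0:(L - 1)) {
    for (i in 0:(L - 1 - j)) {
      key <- sprintf("%d,%d", i, j)
      inputs <- if (j == 0) {
        if (i == 0) "image" else sprintf("pool(%d,0)", i - 1)
      } else {
        c(sprintf("same(%d,%d)", i, 0:(j - 1)), sprintf("up(%d,%d)", i + 1, j - 1))
      }
      nodes[[key]] <- list(i = i, j = j, inputs = inputs,
                           in_degree = length(inputs),
                           out_channels = config$base_widths[i + 1])
    }
  }
  structure(nodes, class = "seg_graph")
}

# Parameter set for the graph: per node two 3x3 convs; per upsampled edge a
# 1x1 channel-reduction conv (bilinear mode) or a learned 2x2 transposed
# conv; one shared 1x1 head.
init_seg_params <- function(config, seed) {
  with_rng(seed, {
    L <- config$n_levels
    w <- config$base_widths
    p <- list()
    for (j in 0:(L - 1)) {
      for (i in 0:(L - 1 - j)) {
        cin <- if (j == 0) { if (i == 0) 3L else w[i] } else (j + 1L) * w[i + 1]
        key <- sprintf("n%d_%d", i, j)
        p[[paste0(key, "_w1")]] <- init_conv_w(3, 3, cin, w[i + 1])
        p[[paste0(key, "_b1")]] <- numeric(w[i + 1])
        p[[paste0(key, "_w2")]] <- init_conv_w(3, 3, w[i + 1], w[i + 1])
        p[[paste0(key, "_b2")]] <- numeric(w[i + 1])
        if (j > 0) {
          ukey <- sprintf("u%d_%d", i, j)
          if (config$upsample_mode == "bilinear") {
            p[[paste0(ukey, "_w")]] <- init_conv_w(1, 1, w[i + 2], w[i + 1])
          } else {
            p[[paste0(ukey, "_w")]] <- init_conv_w(2, 2, w[i + 2], w[i + 1])
          }
          p[[paste0(ukey, "_b")]] <- numeric(w[i + 1])
        }
      }
    }
    p$head_w <- init_conv_w(1, 1, w[1], 1)
    p$head_b <- numeric(1)
    p
  })
}

# Learned 2x2 stride-2 transposed convolution as a tape op.
op_transposed_conv2 <- function(x, w, b) {
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Cout <- dim(w$value)[4]
  xm <- matrix(aperm(x$value, c(1, 2, 4, 3)), ncol = C)  # (H*W*N) x C
  y <- array(0, c(2 * H, 2 * W, Cout, N))
  for (di in 0:1) for (dj in 0:1) {
    Wm <- matrix(w$value[di + 1, dj + 1, , ], C, Cout)
    blk <- xm %*% Wm                                     # (H*W*N) x Cout
    blk <- aperm(array(blk, c(H, W, N, Cout)), c(1, 2, 4, 3))
    y[seq(1 + di, 2 * H, by = 2), seq(1 + dj, 2 * W, by = 2), , ] <- blk
  }
  y <- sweep(y, 3, b$value, "+")
  tg_node(y, list(x, w, b), function(g) {
    gx <- array(0, d)
    gw <- array(0, dim(w$value))
    for (di in 0:1) for (dj in 0:1) {
      gblk <- g[seq(1 + di, 2 * H, by = 2), seq(1 + dj, 2 * W, by = 2), , , drop = FALSE]
      gm <- matrix(aperm(gblk, c(1, 2, 4, 3)), ncol = Cout)
      Wm <- matrix(w$value[di + 1, dj + 1, , ], C, Cout)
      gx <- gx + aperm(array(gm %*% t(Wm), c(H, W, N, C)), c(1, 2, 4, 3))
      gw[di + 1, dj + 1, , ] <- t(xm) %*% gm
    }
    gb <- apply(g, 3, sum)
    list(gx, gw, gb)
  })
}

# Forward pass over the node graph; returns the logit and probability nodes.
seg_forward_nodes <- function(pn, xnode, config) {
  L <- config$n_levels
  X <- list()
  for (i in 0:(L - 1)) {
    inp <- if (i == 0) xnode else op_maxpool2(X[[sprintf("%d,%d", i - 1, 0)]])
    key <- sprintf("n%d_%d", i, 0)
    h <- op_relu(op_conv2d(inp, pn[[paste0(key, "_w1")]], pn[[paste0(key, "_b1")]], 1L, 1L))
    h <- op_relu(op_conv2d(h, pn[[paste0(key, "_w2")]], pn[[paste0(key, "_b2")]], 1L, 1L))
    X[[sprintf("%d,%d", i, 0)]] <- h
  }
  for (j in 1:(L - 1)) {
    for (i in 0:(L - 1 - j)) {
      ukey <- sprintf("u%d_%d", i, j)
      below <- X[[sprintf("%d,%d", i + 1, j - 1)]]
      up <- if (config$upsample_mode == "bilinear") {
        op_conv2d(op_upsample2(below), pn[[paste0(ukey, "_w")]],
                  pn[[paste0(ukey, "_b")]], 1L, 0L)
      } else {
        op_transposed_conv2(below, pn[[paste0(ukey, "_w")]], pn[[paste0(ukey, "_b")]])
      }
      same <- lapply(0:(j - 1), function(k) X[[sprintf("%d,%d", i, k)]])
      inp <- op_concat(c(same, list(up)))
      key <- sprintf("n%d_%d", i, j)
      h <- op_relu(op_conv2d(inp, pn[[paste0(key, "_w1")]], pn[[paste0(key, "_b1")]], 1L, 1L))
      h <- op_relu(op_conv2d(h, pn[[paste0(key, "_w2")]], pn[[paste0(key, "_b2")]], 1L, 1L))
      X[[sprintf("%d,%d", i, j)]] <- h
    }
  }
  heads <- if (isTRUE(config$deep_supervision)) 1:(L - 1) else L - 1
  logits <- lapply(heads, function(j)
    op_conv2d(X[[sprintf("0,%d", j)]], pn$head_w, pn$head_b, 1L, 0L))
  if (length(logits) == 1) {
    lg <- logits[[1]]
  } else {
    lg <- logits[[1]]
    for (k in 2:length(logits)) lg <- op_add(lg, logits[[k]])
    lg <- tg_node(lg$value / length(logits), list(lg),
                  function(g) list(g / length(logits)))
  }
  list(logits = lg, prob = op_sigmoid(lg))
}

#' Initialise a segmentation model
#'
#' @param config A [seg_config()].
#' @param seed Weight-initialisation seed.
#' @return A `segnet_model` (untrained).
#' @export
init_segnet <- function(config = seg_config(), seed = 1L) {
  structure(list(config = config, graph = build_node_graph(config),
                 params = init_seg_params(config, seed), seed = seed,
                 input_size = NA_integer_,
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      val_iou = numeric())),
            class = "segnet_model")
}

#' Forward pass of the segmentation network
#'
#' @param model A `segnet_model`.
#' @param images `(H, W, 3)` array or `(H, W, 3, N)` batch in `[0, 1]`; `H`
#'   and `W` must be divisible by `2^(n_levels - 1)`.
#' @return `(H, W, N)` array of foreground probabilities.
#' @export
seg_forward <- function(model, images) {
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1)
  d <- dim(images)
  div <- 2^(model$config$n_levels - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf("input spatial size %dx%d must be divisible by %d (2^(n_levels-1))",
                 d[1], d[2], div), call. = FALSE)
  pn <- wrap_params(model$params)
  out <- seg_forward_nodes(pn, tg_leaf(images), model$config)
  pr <- out$prob$value
  array(pr, c(d[1], d[2], d[4]))
}

#' Dice coefficient between a soft prediction and a binary mask
#'
#' `(2 * sum(pred * gt) + eps) / (sum(pred) + sum(gt) + eps)`; `eps` makes
#' the empty-vs-empty case equal 1.
#'
#' @param pred Soft (or binary) prediction array.
#' @param gt Binary mask of the same shape.
#' @param eps Stabiliser.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, gt, eps = 1e-6) {
  if (!all(dim(pred) == dim(gt)) && length(pred) != length(gt))
    stop("`pred` and `gt` must have the same shape", call. = FALSE)
  (2 * sum(pred * gt) + eps) / (sum(pred) + sum(gt) + eps)
}

#' Combined BCE + Dice segmentation loss
#'
#' Default (`form = "standard"`): per image,
#' `bce_weight * BCE(pred, gt) + dice_weight * (1 - Dice(pred, gt))`,
#' averaged over the batch; the BCE term is pixel-weighted when a
#' `weight_map` is given.  `form = "as_printed"` evaluates the literal
#' per-pixel expression
#' `-(1/N) * sum_b mean(0.5 * gt * log(pred) + 2 * gt * pred / (gt + pred))`,
#' kept for comparison: it has no background term (every summand vanishes
#' where `gt = 0`) and is negative at the optimum, so it is not used for
#' training.
#'
#' @param pred Probability array `(H, W)` or `(H, W, N)` / `(H, W, 1, N)`,
#'   values in `[0, 1]`.
#' @param gt Binary array of matching shape.
#' @param weights Named vector `c(bce = , dice = )`.
#' @param weight_map Optional per-pixel BCE weights, same spatial shape.
#' @param form `"standard"` or `"as_printed"`.
#' @param eps Probability clamp.
#' @return Scalar loss.
#' @export
combined_loss <- function(pred, gt, weights = c(bce = 0.5, dice = 1),
                          weight_map = NULL, form = c("standard", "as_printed"),
                          eps = 1e-7) {
  form <- match.arg(form)
  if (length(pred) != length(gt))
    stop("`pred` and `gt` must have the same shape", call. = FALSE)
  if (min(pred) < -1e-6 || max(pred) > 1 + 1e-6)
    stop("`pred` must contain probabilities in [0, 1]", call. = FALSE)
  pm <- per_image_list(pred); gm <- per_image_list(gt)
  wm <- if (!is.null(weight_map)) per_image_list(weight_map) else NULL
  n <- length(pm)
  total <- 0
  for (b in seq_len(n)) {
    p <- pmin(pmax(pm[[b]], eps), 1 - eps)
    g <- gm[[b]]
    if (form == "standard") {
      l <- -(g * log(p) + (1 - g) * log(1 - p))
      if (!is.null(wm)) l <- l * wm[[b]]
      total <- total + weights[["bce"]] * mean(l) +
        weights[["dice"]] * (1 - dice_coefficient(p, g))
    } else {
      total <- total - mean(0.5 * g * log(p) + 2 * g * p / (g + p + eps))
    }
  }
  total / n
}

# Split a (H,W) / (H,W,N) / (H,W,1,N) array into a list of per-image matrices.
per_image_list <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) return(list(as.matrix(x)))
  if (length(d) == 4) x <- array(x, c(d[1], d[2], d[4]))
  d <- dim(x)
  lapply(seq_len(d[3]), function(b) x[, , b])
}

#' Boundary-emphasising loss weight map
#'
#' `w(x) = wc(x) + w0 * exp(-(d1(x) + d2(x))^2 / (2 * sigma^2))`, where
#' `wc` is the inverse-frequency class weight (`0.5 / freq(class)`, so a
#' balanced mask gives 1 for both classes), `d1` is the Euclidean distance
#' from the pixel to the nearest foreground-component boundary and `d2` the
#' distance to the second-nearest component's boundary.  With a single
#' component `d2 = d1` (the convention of separating touching objects is
#' vacuous), and an all-background mask returns the `wc`-only map.
#' Boundary pixels are foreground pixels with a 4-neighbour that is
#' background or outside the image.
#'
#' @param mask Binary 0/1 matrix.
#' @param w0 Amplitude of the boundary term (default 10).
#' @param sigma Spread in pixels (default 0.5).
#' @return Numeric matrix of per-pixel weights.
#' @export
boundary_weight_map <- function(mask, w0 = 10, sigma = 0.5) {
  if (!all(mask %in% c(0, 1))) stop("`mask` must be binary 0/1", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  freq_fg <- mean(mask == 1); freq_bg <- 1 - freq_fg
  wc <- matrix(0, h, w)
  if (freq_bg > 0) wc[mask == 0] <- 0.5 / freq_bg
  if (freq_fg > 0) wc[mask == 1] <- 0.5 / freq_fg
  comps <- label_components(mask)
  ncomp <- max(comps)
  if (ncomp == 0) return(wc)
  # boundary pixel coordinates per component
  is_boundary <- function(r, c) {
    mask[r, c] == 1 &&
      (r == 1 || c == 1 || r == h || c == w ||
       mask[r - 1, c] == 0 || mask[r + 1, c] == 0 ||
       mask[r, c - 1] == 0 || mask[r, c + 1] == 0)
  }
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  dmin <- matrix(Inf, h * w, ncomp)
  for (k in seq_len(ncomp)) {
    sel <- which(comps == k)
    bsel <- sel[vapply(sel, function(ix) {
      r <- ((ix - 1) %% h) + 1; c <- ((ix - 1) %/% h) + 1
      is_boundary(r, c)
    }, logical(1))]
    br <- ((bsel - 1) %% h) + 1; bc <- ((bsel - 1) %/% h) + 1
    # distance from every pixel to this component's nearest boundary pixel
    d2m <- outer(as.vector(rows), br, function(a, b) (a - b)^2) +
      outer(as.vector(cols), bc, function(a, b) (a - b)^2)
    dmin[, k] <- sqrt(apply(d2m, 1, min))
  }
  d1 <- apply(dmin, 1, min)
  d2 <- if (ncomp >= 2) apply(dmin, 1, function(v) sort(v)[2]) else d1
  wc + matrix(w0 * exp(-(d1 + d2)^2 / (2 * sigma^2)), h, w)
}

# 8-connected component labelling of a binary matrix (flood fill).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask == 1 & lab == 0)) {
    if (lab[start] != 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      ix <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- ((ix - 1) %% h) + 1; c <- ((ix - 1) %/% h) + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || cc < 1 || rr > h || cc > w) next
        jx <- rr + (cc - 1) * h
        if (mask[jx] == 1 && lab[jx] == 0) { lab[jx] <- cur; queue <- c(queue, jx) }
      }
    }
  }
  lab
}

# Gradient of the standard combined loss with respect to the logits, for one
# batch: probabilities p (H,W,1,N), ground truth g, optional weight maps.
combined_loss_grad_logits <- function(p, g, weights, wmaps = NULL, eps = 1e-7) {
  d <- dim(p); N <- d[4]; npix <- d[1] * d[2]
  gr <- array(0, d)
  for (b in seq_len(N)) {
    pb <- pmin(pmax(p[, , 1, b], eps), 1 - eps)
    gb <- g[, , 1, b]
    gbce <- (pb - gb) / npix
    if (!is.null(wmaps)) gbce <- gbce * wmaps[[b]]
    sp <- sum(pb); sg <- sum(gb); spg <- sum(pb * gb)
    den <- sp + sg + 1e-6
    ddice_dp <- (2 * gb * den - (2 * spg + 1e-6)) / den^2
    gdice <- -ddice_dp * pb * (1 - pb)
    gr[, , 1, b] <- (weights[["bce"]] * gbce + weights[["dice"]] * gdice) / N
  }
  gr
}

#' Train the segmentation stream
#'
#' Adam optimisation of the combined BCE + Dice objective with on-the-fly
#' paired augmentation; per-epoch training loss and validation IoU are
#' logged and the best-validation-IoU weights are returned.
#'
#' @param manifest Manifest with `train` and `val` splits and mask paths.
#' @param config A [seg_config()].
#' @param train_config A [train_config()]; `input_size` (default 64) must be
#'   divisible by `2^(n_levels - 1)`.
#' @return A trained `segnet_model` with `history` filled.
#' @export
train_segmentation <- function(manifest, config = seg_config(),
                               train_config = NULL) {
  tc <- if (is.null(train_config)) leafseg::train_config() else train_config
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  va <- manifest[manifest$split == "val", , drop = FALSE]
  if (nrow(tr) == 0 || nrow(va) == 0)
    stop("manifest needs non-empty 'train' and 'val' splits", call. = FALSE)
  size <- if (is.null(tc$input_size)) 64L else as.integer(tc$input_size)
  div <- 2^(config$n_levels - 1)
  if (size %% div != 0)
    stop(sprintf("input size %d must be divisible by %d", size, div), call. = FALSE)

  load_all <- function(recs) {
    lapply(seq_len(nrow(recs)), function(i) {
      sm <- load_sample(recs[i, ])
      rp <- resize_pair(sm$image, sm$mask, size)
      list(image = rp$image, mask = rp$mask)
    })
  }
  tr_s <- load_all(tr); va_s <- load_all(va)

  model <- init_segnet(config, seed = tc$seed)
  model$input_size <- size
  if (tc$epochs == 0) return(model)

  params <- model$params
  state <- adam_init(params)
  lr <- tc$lr
  best <- list(iou = -Inf, params = params)
  hist <- vector("list", tc$epochs)
  wait <- 0L

  wmap_cache <- NULL
  if (isTRUE(config$use_boundary_weight_map))
    wmap_cache <- lapply(tr_s, function(s) boundary_weight_map(s$mask, config$w0, config$sigma))

  va_x <- array(0, c(size, size, 3, length(va_s)))
  for (k in seq_along(va_s)) va_x[, , , k] <- va_s[[k]]$image
  val_iou <- function(params) {
    m2 <- model; m2$params <- params
    ious <- numeric(length(va_s))
    for (bi in seq(1, length(va_s), by = 8)) {
      ids <- bi:min(bi + 7, length(va_s))
      pr <- seg_forward(m2, va_x[, , , ids, drop = FALSE])
      for (k in seq_along(ids)) {
        bin <- matrix(as.integer(pr[, , k] >= config$output_threshold), size, size)
        ious[ids[k]] <- seg_scores(bin, va_s[[ids[k]]]$mask)$iou
      }
    }
    mean(ious)
  }

  with_rng(tc$seed + 1L, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(length(tr_s))
      ep_loss <- 0; nb <- 0
      for (bi in seq(1, length(ord), by = tc$batch_size)) {
        ids <- ord[bi:min(bi + tc$batch_size - 1, length(ord))]
        B <- length(ids)
        x <- array(0, c(size, size, 3, B))
        g <- array(0, c(size, size, 1, B))
        wmaps <- if (!is.null(wmap_cache)) vector("list", B) else NULL
        for (k in seq_len(B)) {
          s <- tr_s[[ids[k]]]
          if (!is.null(tc$augment)) {
            a <- apply_augmentation(s$image, s$mask, tc$augment)
            s <- list(image = a$image, mask = a$mask)
            if (!is.null(wmaps))
              wmaps[[k]] <- boundary_weight_map(s$mask, config$w0, config$sigma)
          } else if (!is.null(wmaps)) wmaps[[k]] <- wmap_cache[[ids[k]]]
          x[, , , k] <- s$image
          g[, , 1, k] <- s$mask
        }
        pn <- wrap_params(params)
        out <- seg_forward_nodes(pn, tg_leaf(x), config)
        p <- out$prob$value
        loss <- combined_loss(p, g, config$loss_weights,
                              weight_map = if (!is.null(wmaps)) array(unlist(wmaps), dim(g)) else NULL)
        seed_grad <- combined_loss_grad_logits(p, g, config$loss_weights, wmaps)
        grads <- run_backward(pn, out$logits, seed_grad)
        upd <- adam_step(params, grads, state, lr = lr, weight_decay = tc$weight_decay)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      vi <- val_iou(params)
      hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / nb, val_iou = vi)
      if (vi > best$iou) {
        best <- list(iou = vi, params = params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (isTRUE(tc$reduce_on_plateau) && wait >= tc$patience) {
          lr <- lr * tc$lr_factor
          wait <- 0L
        }
      }
      if (isTRUE(tc$verbose))
        message(sprintf("epoch %3d | loss %.4f | val IoU %.4f", epoch, ep_loss / nb, vi))
    }
  })
  model$params <- best$params
  model$best_iou <- best$iou
  model$history <- do.call(rbind, hist)
  model
}

#' Predict a binary plant mask for one image
#'
#' The image is resized to the model's training resolution if needed, the
#' probability map is computed, resized back to the original resolution, and
#' thresholded.
#'
#' @param model Trained `segnet_model`.
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param threshold Binarisation threshold; defaults to the model config's.
#' @return A `seg_prediction`: `prob_map`, `binary_mask`, `threshold_used`.
#' @export
predict_mask <- function(model, image, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$config$output_threshold
  d <- dim(image)
  size <- model$input_size
  work <- image
  if (!is.na(size) && (d[1] != size || d[2] != size))
    work <- resize_pair(image, NULL, size)$image
  pr <- seg_forward(model, work)[, , 1]
  if (!all(dim(pr) == d[1:2])) {
    pr <- nn_resize_bilinear(array(pr, c(dim(pr), 1)), d[1], d[2])[, , 1]
  }
  structure(list(prob_map = pr,
                 binary_mask = matrix(as.integer(pr >= threshold), d[1], d[2]),
                 threshold_used = threshold),
            class = "seg_prediction")
}
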