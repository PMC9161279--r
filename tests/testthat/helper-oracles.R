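# Independent brute-force oracles used to verify the package kernels.
# These deliberately re-derive every quantity with naive loops or a
# different algorithm than the implementation under test.

# Even-odd point-in-polygon test (ray cast to the right), one pixel at a time.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < xi + (py - yi) * (xj - xi) / (yj - yi)) inside <- !inside
    j <- i
  }
  inside
}

oracle_rasterise <- function(poly, size) {
  m <- matrix(0L, size, size)
  for (r in seq_len(size))
    for (c in seq_len(size))
      if (oracle_point_in_polygon(c, r, poly)) m[r, c] <- 1L
  m
}

# Pixel-by-pixel segmentation scores.
oracle_seg_scores <- function(pred, gt) {
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1L
      if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1L
      if (pred[i, j] == 0 && gt[i, j] == 1) fn <- fn + 1L
    }
  # documented convention: an undefined ratio (no positive predictions, or
  # no positive ground truth, while the pair is not empty-empty) scores 0
  list(iou = tp / (tp + fp + fn),
       precision = if (tp + fp > 0) 100 * tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) 100 * tp / (tp + fn) else 0,
       tp = tp, fp = fp, fn = fn)
}

# Item-by-item count scores.
oracle_count_scores <- function(gt, pred) {
  m <- length(gt)
  dic <- adic <- mse <- 0
  for (i in seq_len(m)) {
    e <- gt[i] - pred[i]
    dic <- dic + e; adic <- adic + abs(e); mse <- mse + e^2
  }
  list(dic = dic / m, adic = adic / m, mse = mse / m)
}

# Per-pixel binary cross-entropy averaged per image then over the batch.
oracle_bce <- function(pred, gt, eps = 1e-7) {
  total <- 0
  d <- dim(pred)
  nb <- if (length(d) == 3) d[3] else 1
  for (b in seq_len(nb)) {
    p <- if (length(d) == 3) pred[, , b] else pred
    g <- if (length(d) == 3) gt[, , b] else gt
    s <- 0
    for (i in seq_along(p)) {
      pi <- min(max(p[i], eps), 1 - eps)
      s <- s - (g[i] * log(pi) + (1 - g[i]) * log(1 - pi))
    }
    total <- total + s / length(p)
  }
  total / nb
}

# Exhaustive boundary weight map: label components by repeated flood fill,
# list every boundary pixel, and take per-pixel minima over exact Euclidean
# distances.  Conventions match the documented ones: 8-connected components,
# boundary = foreground pixel with a 4-neighbour that is background or
# outside, d2 = d1 for a single component.
oracle_weight_map <- function(mask, w0 = 10, sigma = 0.5) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w); ncomp <- 0L
  for (sr in seq_len(h)) for (sc in seq_len(w)) {
    if (mask[sr, sc] == 1 && lab[sr, sc] == 0) {
      ncomp <- ncomp + 1L
      stack <- list(c(sr, sc)); lab[sr, sc] <- ncomp
      while (length(stack)) {
        rc <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- rc[1] + dr; c2 <- rc[2] + dc
          if (r2 >= 1 && c2 >= 1 && r2 <= h && c2 <= w &&
              mask[r2, c2] == 1 && lab[r2, c2] == 0) {
            lab[r2, c2] <- ncomp
            stack[[length(stack) + 1]] <- c(r2, c2)
          }
        }
      }
    }
  }
  freq_fg <- mean(mask == 1)
  wc <- matrix(0, h, w)
  if (freq_fg < 1) wc[mask == 0] <- 0.5 / (1 - freq_fg)
  if (freq_fg > 0) wc[mask == 1] <- 0.5 / freq_fg
  if (ncomp == 0) return(wc)
  bnd <- vector("list", ncomp)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] == 1) {
      nb_bg <- r == 1 || c == 1 || r == h || c == w ||
        mask[r - 1, c] == 0 || mask[r + 1, c] == 0 ||
        mask[r, c - 1] == 0 || mask[r, c + 1] == 0
      if (nb_bg) bnd[[lab[r, c]]] <- rbind(bnd[[lab[r, c]]], c(r, c))
    }
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    dk <- numeric(ncomp)
    for (k in seq_len(ncomp)) {
      best <- Inf
      for (t in seq_len(nrow(bnd[[k]])))
        best <- min(best, sqrt((r - bnd[[k]][t, 1])^2 + (c - bnd[[k]][t, 2])^2))
      dk[k] <- best
    }
    dk <- sort(dk)
    d1 <- dk[1]
    d2 <- if (ncomp >= 2) dk[2] else d1
    out[r, c] <- wc[r, c] + w0 * exp(-(d1 + d2)^2 / (2 * sigma^2))
  }
  out
}

# Geometric augmentation oracle, re-implemented from the documented
# conventions (CCW rotation = transpose + reverse rows; "h" flip reverses
# columns; rescale = nearest-neighbour resize + centre crop / zero pad).
oracle_rot90_mask <- function(m, k) {
  for (i in seq_len(k %% 4)) {
    m <- t(m)
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  m
}

oracle_flip_mask <- function(m, mode) {
  if (mode %in% c("h", "hv")) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (mode %in% c("v", "hv")) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

oracle_scale_mask <- function(m, s) {
  h <- nrow(m); w <- ncol(m)
  nh <- max(8L, round(h * s)); nw <- max(8L, round(w * s))
  ri <- pmin(pmax(round((seq_len(nh) - 0.5) * h / nh + 0.5), 1), h)
  ci <- pmin(pmax(round((seq_len(nw) - 0.5) * w / nw + 0.5), 1), w)
  m2 <- m[ri, ci, drop = FALSE]
  if (nh >= h) {
    top <- floor((nh - h) / 2); left <- floor((nw - w) / 2)
    m2[top + seq_len(h), left + seq_len(w), drop = FALSE]
  } else {
    top <- floor((h - nh) / 2); left <- floor((w - nw) / 2)
    out <- matrix(0L, h, w)
    out[top + seq_len(nh), left + seq_len(nw)] <- m2
    out
  }
}

# Replay the geometric part of an augmentation log on a mask.
oracle_replay_geometric <- function(mask, log) {
  if (!is.null(log$rotate90)) mask <- oracle_rot90_mask(mask, log$rotate90)
  if (!is.null(log$flip)) mask <- oracle_flip_mask(mask, log$flip)
  if (!is.null(log$scale)) mask <- oracle_scale_mask(mask, log$scale)
  mask
}
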