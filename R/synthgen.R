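# Synthetic top-down rosette imagery with exact ground truth.
#
# Each sample is a roughly centred rosette of overlapping teardrop leaves
# radiating from the plant centre, composited over a plain, soil, or
# soil-plus-pot background.  The binary mask and the leaf count are known by
# construction, so the generator provides fully labelled data for both the
# segmentation and the counting stream at any desk scale.

# Run `expr` under a private RNG stream, restoring the caller's state after.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Specification of one synthetic rosette image
#'
#' Describes the geometry, appearance and randomness of a single rendered
#' rosette.  Identical specs (including `seed`) always render bit-identical
#' samples.
#'
#' @param image_size Pixels per side of the square image (>= 32).
#' @param n_leaves Number of leaves to render (>= 1).
#' @param leaf_length_range Leaf length as a fraction of the half-image,
#'   `c(min, max)` with `0 < min <= max <= 1`.
#' @param leaf_aspect_range Leaf width/length ratio range.
#' @param angle_mode `"phyllotactic"` places successive leaves at multiples of
#'   `phyllotactic_angle` (the golden angle typical for rosettes) plus up to
#'   +/- 10 degrees of noise; `"uniform"` draws angles independently, which
#'   produces worst-case leaf overlap.
#' @param phyllotactic_angle Divergence angle in degrees (default 137.5).
#' @param center_jitter Maximum plant-centre offset from the image centre, in
#'   pixels.
#' @param background_mode One of `"plain"`, `"soil"`, `"soil_with_pot"`.
#' @param illumination_jitter Multiplicative brightness range applied to the
#'   final image, e.g. `c(0.9, 1.1)`; use `c(1, 1)` to disable.
#' @param seed RNG seed; all randomness in the sample flows from it.
#' @return An object of class `rosette_spec`.
#' @export
rosette_spec <- function(image_size = 64L, n_leaves = 5L,
                         leaf_length_range = c(0.3, 0.6),
                         leaf_aspect_range = c(0.25, 0.5),
                         angle_mode = c("phyllotactic", "uniform"),
                         phyllotactic_angle = 137.5,
                         center_jitter = 2,
                         background_mode = c("soil", "plain", "soil_with_pot"),
                         illumination_jitter = c(0.9, 1.1),
                         seed = 1L) {
  angle_mode <- match.arg(angle_mode)
  background_mode <- match.arg(background_mode)
  spec <- structure(
    list(image_size = as.integer(image_size), n_leaves = as.integer(n_leaves),
         leaf_length_range = as.numeric(leaf_length_range),
         leaf_aspect_range = as.numeric(leaf_aspect_range),
         angle_mode = angle_mode, phyllotactic_angle = phyllotactic_angle,
         center_jitter = center_jitter, background_mode = background_mode,
         illumination_jitter = as.numeric(illumination_jitter),
         seed = as.integer(seed)),
    class = "rosette_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  if (!is.finite(spec$image_size) || spec$image_size < 32)
    stop("invalid `image_size`: must be >= 32", call. = FALSE)
  if (!is.finite(spec$n_leaves) || spec$n_leaves < 1)
    stop("invalid `n_leaves`: must be >= 1", call. = FALSE)
  r <- spec$leaf_length_range
  if (length(r) != 2 || r[1] <= 0 || r[1] > r[2] || r[2] > 1)
    stop("invalid `leaf_length_range`: need 0 < min <= max <= 1", call. = FALSE)
  a <- spec$leaf_aspect_range
  if (length(a) != 2 || a[1] <= 0 || a[1] > a[2])
    stop("invalid `leaf_aspect_range`: need 0 < min <= max", call. = FALSE)
  i <- spec$illumination_jitter
  if (length(i) != 2 || i[1] <= 0 || i[1] > i[2])
    stop("invalid `illumination_jitter`: need 0 < min <= max", call. = FALSE)
  if (spec$center_jitter < 0)
    stop("invalid `center_jitter`: must be >= 0", call. = FALSE)
  invisible(spec)
}

# Teardrop leaf outline in image coordinates (columns = x, y), pixel centres
# at integer coordinates.  Widest ~60% of the way out, pointed at the tip.
leaf_polygon <- function(cx, cy, angle_deg, length_px, aspect, n_pts = 28) {
  u <- seq(0.001, 1, length.out = n_pts)
  prof <- (u^0.9 * (1 - u)^0.55)
  prof <- prof / max(prof)
  hw <- aspect * length_px / 2
  a <- u * length_px
  b <- prof * hw
  th <- angle_deg * pi / 180
  rot <- function(ax, bx) cbind(cx + ax * cos(th) - bx * sin(th),
                                cy + ax * sin(th) + bx * cos(th))
  poly <- rbind(rot(a, b), rot(rev(a), -rev(b)))
  colnames(poly) <- c("x", "y")
  poly
}

#' Rasterise a closed polygon onto a square pixel grid
#'
#' Even-odd scanline fill; a pixel is foreground when its centre (integer
#' coordinates, origin top-left, 1-based) lies inside the polygon.
#'
#' @param poly Two-column matrix of vertices `(x, y)`.
#' @param size Pixels per side.
#' @return Integer matrix `size x size` of 0/1 (rows = y, columns = x).
#' @export
rasterise_polygon <- function(poly, size) {
  m <- matrix(0L, size, size)
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (row in seq_len(size)) {
    crosses <- (y > row) != (y2 > row)
    if (!any(crosses)) next
    xs <- x[crosses] + (row - y[crosses]) * (x2[crosses] - x[crosses]) /
      (y2[crosses] - y[crosses])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- ceiling(xs[k]); hi <- floor(xs[k + 1])
      lo <- max(1L, lo); hi <- min(size, hi)
      if (lo <= hi) m[row, lo:hi] <- 1L
    }
  }
  m
}

# Low-frequency random field in [-1, 1], drawn on a coarse grid and
# bilinearly upsampled; gives the soil its patchy texture.
low_freq_field <- function(size, cells = 6) {
  g <- array(stats::runif(cells * cells, -1, 1), c(cells, cells, 1))
  f <- nn_resize_bilinear(g, size, size)
  f[, , 1]
}

render_background <- function(spec) {
  s <- spec$image_size
  img <- array(0, c(s, s, 3))
  if (spec$background_mode == "plain") {
    img[, , 1] <- 0.5; img[, , 2] <- 0.5; img[, , 3] <- 0.5
    return(img)
  }
  base <- c(0.40, 0.28, 0.18)                      # moist potting soil
  field <- low_freq_field(s)
  speck <- matrix(stats::rnorm(s * s, sd = 0.035), s, s)
  moss <- pmax(low_freq_field(s, cells = 5) - 0.55, 0)  # sparse green patches
  for (c in 1:3) {
    img[, , c] <- base[c] * (1 + 0.25 * field) + speck
  }
  img[, , 2] <- img[, , 2] + 0.5 * moss
  if (spec$background_mode == "soil_with_pot") {
    ctr <- (s + 1) / 2
    d <- sqrt(outer((seq_len(s) - ctr)^2, (seq_len(s) - ctr)^2, "+"))
    rim <- d >= 0.82 * s / 2 & d <= 0.98 * s / 2
    outside <- d > 0.98 * s / 2
    pot <- c(0.45, 0.22, 0.12)                     # terracotta rim
    for (c in 1:3) {
      ch <- img[, , c]
      ch[rim] <- pot[c] * (1 + 0.15 * field[rim])
      ch[outside] <- 0.22 + 0.05 * field[outside]  # bench surface
      img[, , c] <- ch
    }
  }
  img
}

#' Render one synthetic rosette sample
#'
#' Draws `n_leaves` teardrop leaves radiating from a jittered centre, each
#' with its own length, width, green shade, midrib darkening and brightness
#' gradient, composites them over the requested background, and returns the
#' 8-bit image together with the exact union mask and leaf count.  Leaves may
#' overlap, so occlusion arises naturally; the count is the number of leaves
#' drawn, not the number of visible connected components.
#'
#' @param spec A [rosette_spec()].
#' @return An object of class `synthetic_sample`: list with `image`
#'   (`H x W x 3` integer array, 0..255), `mask` (`H x W` 0/1 integer matrix),
#'   `count`, `leaf_polygons` (list of vertex matrices) and `spec_used`.
#' @export
generate_sample <- function(spec) {
  validate_spec(spec)
  with_rng(spec$seed, {
    s <- spec$image_size
    img <- render_background(spec)
    ctr <- (s + 1) / 2
    cx <- ctr + stats::runif(1, -1, 1) * spec$center_jitter
    cy <- ctr + stats::runif(1, -1, 1) * spec$center_jitter
    n <- spec$n_leaves
    angles <- if (spec$angle_mode == "phyllotactic") {
      stats::runif(1, 0, 360) + (seq_len(n) - 1) * spec$phyllotactic_angle +
        stats::runif(n, -10, 10)
    } else {
      stats::runif(n, 0, 360)
    }
    lens <- stats::runif(n, spec$leaf_length_range[1], spec$leaf_length_range[2]) * s / 2
    aspects <- stats::runif(n, spec$leaf_aspect_range[1], spec$leaf_aspect_range[2])
    shade <- stats::runif(n)                       # per-leaf green shade
    polys <- vector("list", n)
    mask <- matrix(0L, s, s)
    xs <- matrix(rep(seq_len(s), each = s), s, s)  # column index of each pixel
    ys <- matrix(rep(seq_len(s), s), s, s)         # row index
    for (k in seq_len(n)) {
      poly <- leaf_polygon(cx, cy, angles[k], lens[k], aspects[k])
      polys[[k]] <- poly
      mk <- rasterise_polygon(poly, s) == 1L
      mask[mk] <- 1L
      if (!any(mk)) next
      th <- angles[k] * pi / 180
      dx <- xs[mk] - cx; dy <- ys[mk] - cy
      a <- dx * cos(th) + dy * sin(th)             # along-axis coordinate
      b <- -dx * sin(th) + dy * cos(th)            # across-axis
      u <- pmin(pmax(a / lens[k], 0), 1)
      col <- c(0.10 + 0.10 * shade[k], 0.32 + 0.30 * shade[k],
               0.06 + 0.10 * shade[k])
      bright <- 0.8 + 0.45 * u                     # tips catch more light
      vein <- ifelse(abs(b) < 0.035 * lens[k], 0.78, 1)  # darker midrib
      noise <- 1 + stats::rnorm(sum(mk), sd = 0.02)
      for (c in 1:3) {
        ch <- img[, , c]
        ch[mk] <- col[c] * bright * vein * noise
        img[, , c] <- ch
      }
    }
    gain <- stats::runif(1, spec$illumination_jitter[1], spec$illumination_jitter[2])
    img <- pmin(pmax(img * gain, 0), 1)
    structure(list(image = array(as.integer(round(img * 255)), dim(img)),
                   mask = mask, count = n, leaf_polygons = polys,
                   spec_used = spec),
              class = "synthetic_sample")
  })
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> %dx%d, %d leaves, %.1f%% foreground, background '%s'\n",
              nrow(x$mask), ncol(x$mask), x$count, 100 * mean(x$mask),
              x$spec_used$background_mode))
  invisible(x)
}

#' Sampler over rosette specs for dataset generation
#'
#' Defines the distribution that [generate_dataset()] draws each sample's
#' spec from: the leaf count is uniform on `n_leaves_range`; all remaining
#' fields are held at the given values.
#'
#' @param image_size,background_mode,leaf_length_range,leaf_aspect_range,angle_mode,center_jitter,illumination_jitter
#'   Passed through to [rosette_spec()].
#' @param n_leaves_range Integer `c(min, max)` leaf-count range (default
#'   1..12, covering young through mature rosettes).
#' @return A function `(index, seed) -> rosette_spec`.
#' @export
rosette_sampler <- function(image_size = 64L, n_leaves_range = c(1L, 12L),
                            background_mode = "soil",
                            leaf_length_range = c(0.3, 0.6),
                            leaf_aspect_range = c(0.25, 0.5),
                            angle_mode = "phyllotactic",
                            center_jitter = 2,
                            illumination_jitter = c(0.9, 1.1)) {
  force(image_size); force(n_leaves_range); force(background_mode)
  function(i, seed) {
    counts <- n_leaves_range[1]:n_leaves_range[2]
    n <- with_rng(seed, counts[sample.int(length(counts), 1)])
    rosette_spec(image_size = image_size, n_leaves = n,
                 leaf_length_range = leaf_length_range,
                 leaf_aspect_range = leaf_aspect_range,
                 angle_mode = angle_mode, center_jitter = center_jitter,
                 background_mode = background_mode,
                 illumination_jitter = illumination_jitter,
                 seed = seed + 1L)
  }
}

#' Generate a dataset of synthetic rosettes on disk
#'
#' Writes `n_samples` image/mask PNG pairs plus a CSV manifest
#' (`image,mask,count,split`).  Per-sample seeds are derived from `seed`, so
#' the whole dataset is reproducible byte-for-byte.
#'
#' @param n_samples Number of samples (>= 1).
#' @param spec_sampler A function `(index, seed) -> rosette_spec`, e.g. from
#'   [rosette_sampler()].
#' @param seed Master RNG seed.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data frame (invisibly also written to
#'   `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(n_samples, spec_sampler = rosette_sampler(),
                             seed = 1L, out_dir) {
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sample_seed <- as.integer((as.numeric(seed) * 10000 + i * 7) %% 2147483629)
    sm <- generate_sample(spec_sampler(i, sample_seed))
    img_path <- file.path(out_dir, sprintf("img_%04d.png", i))
    mask_path <- file.path(out_dir, sprintf("mask_%04d.png", i))
    png::writePNG(sm$image / 255, img_path)
    png::writePNG(sm$mask + 0.0, mask_path)
    rows[[i]] <- data.frame(image = img_path, mask = mask_path,
                            count = sm$count, split = "", stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
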