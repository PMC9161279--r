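# Minimal reverse-mode automatic differentiation over dense R arrays.
#
# The graph is built define-by-run: every op returns a `tg_node` environment
# holding the forward value, references to its parent nodes and a closure that
# maps the node's output gradient to per-parent gradients.  `tg_backward()`
# walks the nodes in reverse creation order (a valid topological order for a
# define-by-run tape) and accumulates gradients.  Feature arrays use the
# (H, W, C, N) layout shared with the C++ kernels.

.tg <- new.env(parent = emptyenv())
.tg$id <- 0L

tg_node <- function(value, parents = list(), backward = NULL) {
  .tg$id <- .tg$id + 1L
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$id <- .tg$id
  class(e) <- "tg_node"
  e
}

tg_leaf <- function(value) tg_node(value)

tg_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

#' @keywords internal
tg_backward <- function(node, seed) {
  # Collect reachable nodes, process in decreasing creation id.
  seen <- new.env(parent = emptyenv())
  stack <- list(node)
  nodes <- list()
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(cur$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- cur
    for (p in cur$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  tg_accum(node, seed)
  for (n in nodes[ord]) {
    if (is.null(n$backward) || is.null(n$grad)) next
    gs <- n$backward(n$grad)
    for (k in seq_along(gs)) {
      if (!is.null(gs[[k]])) tg_accum(n$parents[[k]], gs[[k]])
    }
  }
  invisible(NULL)
}

# ---- ops -------------------------------------------------------------------

op_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  y <- nn_conv2d_fwd(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  tg_node(y, list(x, w, b), function(g) {
    bw <- nn_conv2d_bwd(x$value, w$value, g, as.integer(stride), as.integer(pad))
    list(bw$gx, bw$gw, bw$gb)
  })
}

op_relu <- function(x) {
  m <- x$value > 0
  tg_node(x$value * m, list(x), function(g) list(g * m))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  tg_node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_maxpool2 <- function(x) {
  fw <- nn_maxpool2_fwd(x$value)
  dimx <- dim(x$value)
  tg_node(fw$y, list(x), function(g) list(nn_maxpool2_bwd(g, fw$idx, dimx)))
}

op_upsample2 <- function(x) {
  dimx <- dim(x$value)
  tg_node(nn_upsample2_fwd(x$value), list(x),
          function(g) list(nn_upsample2_bwd(g, dimx)))
}

op_add <- function(a, b) {
  tg_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

# Concatenate along the channel axis (dim 3).
op_concat <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  chans <- vapply(vals, function(v) dim(v)[3], numeric(1))
  d <- dim(vals[[1]])
  out <- array(0, c(d[1], d[2], sum(chans), d[4]))
  at <- 0L
  for (v in vals) {
    cc <- dim(v)[3]
    out[, , at + seq_len(cc), ] <- v
    at <- at + cc
  }
  tg_node(out, nodes, function(g) {
    at <- 0L
    lapply(chans, function(cc) {
      gi <- g[, , at + seq_len(cc), , drop = FALSE]
      at <<- at + cc
      gi
    })
  })
}

# Global average pooling: (H, W, C, N) -> (N, C) matrix.
op_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  y <- t(apply(x$value, c(3, 4), mean))  # N x C
  dim(y) <- c(d[4], d[3])
  tg_node(y, list(x), function(g) {
    gx <- array(0, d)
    for (n in seq_len(d[4]))
      for (c in seq_len(d[3]))
        gx[, , c, n] <- g[n, c] / hw
    list(gx)
  })
}

# Dense layer on (N, F) matrices: y = x %*% W + b.
op_dense <- function(x, w, b) {
  y <- x$value %*% w$value
  y <- sweep(y, 2, b$value, "+")
  tg_node(y, list(x, w, b), function(g) {
    list(g %*% t(w$value), t(x$value) %*% g, colSums(g))
  })
}

# ---- parameters and optimiser ---------------------------------------------

# He-normal initialisation for a conv weight of dims (kh, kw, Cin, Cout).
init_conv_w <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

init_dense_w <- function(fin, fout) {
  matrix(stats::rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout)
}

# Wrap a flat named list of parameter arrays as leaf nodes.
wrap_params <- function(params) lapply(params, tg_leaf)

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step with classic L2 regularisation folded into the gradient.
adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) g <- params[[k]] * 0
    if (weight_decay > 0) g <- g + weight_decay * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Evaluate a scalar-loss closure and return gradients for all wrapped params.
# `forward` receives the list of param nodes and must return a node plus a
# seed gradient (dL/d node value).
run_backward <- function(pnodes, out_node, seed_grad) {
  tg_backward(out_node, seed_grad)
  lapply(pnodes, function(p) p$grad)
}
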