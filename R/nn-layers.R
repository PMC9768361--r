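# Differentiable ops (autograd nodes over the C++ kernels) and layer
# constructors for the segmentation network. All activations are arrays
# with dim (H, W, C, N).

op_conv <- function(x, w, b, stride = 1L, pad = 0L, training = TRUE) {
  y <- conv2d_fwd(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  if (!training) return(ag_node(y))
  ag_node(y, parents = list(x, w, b), backward = function(g) {
    gr <- conv2d_bwd(x$value, w$value, g, as.integer(stride), as.integer(pad))
    list(gr$dx, gr$dw, gr$db)
  })
}

op_bn <- function(x, layer, training = TRUE, momentum = 0.1, eps = 1e-5) {
  res <- bn_fwd(x$value, layer$gamma$value, layer$beta$value,
                layer$running_mean, layer$running_var, training, eps)
  if (!training) return(ag_node(res$y))
  layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * res$mean
  layer$running_var <- (1 - momentum) * layer$running_var + momentum * res$var
  ag_node(res$y, parents = list(x, layer$gamma, layer$beta), backward = function(g) {
    gr <- bn_bwd(x$value, g, layer$gamma$value, res$mean, res$invstd)
    list(gr$dx, gr$dgamma, gr$dbeta)
  })
}

op_relu <- function(x, training = TRUE) {
  y <- relu_fwd(x$value)
  if (!training) return(ag_node(y))
  ag_node(y, parents = list(x), backward = function(g) list(relu_bwd(y, g)))
}

op_add <- function(a, b, training = TRUE) {
  y <- a$value + b$value
  if (!training) return(ag_node(y))
  ag_node(y, parents = list(a, b), backward = function(g) list(g, g))
}

op_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L, training = TRUE) {
  res <- maxpool_fwd(x$value, as.integer(k), as.integer(stride), as.integer(pad))
  if (!training) return(ag_node(res$y))
  in_dim <- dim(x$value)
  ag_node(res$y, parents = list(x), backward = function(g) {
    list(maxpool_bwd(g, res$idx, as.integer(in_dim)))
  })
}

op_upsample2 <- function(x, training = TRUE) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]
  y <- x$value[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , , drop = FALSE]
  if (!training) return(ag_node(y))
  ag_node(y, parents = list(x), backward = function(g) {
    o1 <- seq(1L, 2L * H, by = 2L); o2 <- o1 + 1L
    e1 <- seq(1L, 2L * W, by = 2L); e2 <- e1 + 1L
    list(g[o1, e1, , , drop = FALSE] + g[o2, e1, , , drop = FALSE] +
         g[o1, e2, , , drop = FALSE] + g[o2, e2, , , drop = FALSE])
  })
}

op_concat <- function(a, b, training = TRUE) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  if (!training) return(ag_node(y))
  ag_node(y, parents = list(a, b), backward = function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# Global average pool: (H, W, C, N) -> C x N matrix.
op_gap <- function(x, training = TRUE) {
  d <- dim(x$value)
  xm <- x$value
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  s <- .colMeans(xm, d[1] * d[2], d[3] * d[4])
  dim(s) <- c(d[3], d[4])
  if (!training) return(ag_node(s))
  ag_node(s, parents = list(x), backward = function(g) {
    dx <- rep(as.numeric(g) / (d[1] * d[2]), each = d[1] * d[2])
    dim(dx) <- d
    list(dx)
  })
}

op_dense <- function(s, w, b, training = TRUE) {
  y <- w$value %*% s$value + b$value  # bias recycled down columns
  if (!training) return(ag_node(y))
  ag_node(y, parents = list(s, w, b), backward = function(g) {
    list(crossprod(w$value, g), g %*% t(s$value), rowSums(g))
  })
}

op_sigmoid <- function(x, training = TRUE) {
  y <- 1 / (1 + exp(-x$value))
  if (!training) return(ag_node(y))
  ag_node(y, parents = list(x), backward = function(g) list(g * y * (1 - y)))
}

# Per-channel scaling of (H, W, C, N) by gates (C x N).
op_scale_channels <- function(x, gates, training = TRUE) {
  d <- dim(x$value)
  gv <- rep(as.numeric(gates$value), each = d[1] * d[2])
  y <- x$value * gv
  if (!training) return(ag_node(y))
  ag_node(y, parents = list(x, gates), backward = function(g) {
    m <- g * x$value
    dim(m) <- c(d[1] * d[2], d[3] * d[4])
    dg <- .colSums(m, d[1] * d[2], d[3] * d[4])
    dim(dg) <- c(d[3], d[4])
    list(g * gv, dg)
  })
}

# Channel-wise softmax over dim 3 of (H, W, K, N).
op_softmax <- function(x, training = TRUE) {
  d <- dim(x$value)
  K <- d[3]
  v <- x$value
  dim(v) <- c(d[1] * d[2], K, d[4])
  m <- v[, 1L, ]
  for (k in seq_len(K)[-1L]) m <- pmax(m, v[, k, ])
  e <- v
  for (k in seq_len(K)) e[, k, ] <- exp(v[, k, ] - m)
  s <- e[, 1L, ]
  for (k in seq_len(K)[-1L]) s <- s + e[, k, ]
  p <- e
  for (k in seq_len(K)) p[, k, ] <- e[, k, ] / s
  dim(p) <- d
  if (!training) return(ag_node(p))
  ag_node(p, parents = list(x), backward = function(g) {
    gp <- g * p
    dim(gp) <- c(d[1] * d[2], K, d[4])
    dot <- gp[, 1L, ]
    for (k in seq_len(K)[-1L]) dot <- dot + gp[, k, ]
    dx <- g
    dim(dx) <- c(d[1] * d[2], K, d[4])
    pm <- p
    dim(pm) <- c(d[1] * d[2], K, d[4])
    for (k in seq_len(K)) dx[, k, ] <- pm[, k, ] * (dx[, k, ] - dot)
    dim(dx) <- d
    list(dx)
  })
}

# ---- layer constructors ------------------------------------------------

# He-normal initialization for a (kh, kw, Cin, Cout) convolution.
init_conv <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  w <- array(rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
  list(w = ag_param(w), b = ag_param(numeric(cout)))
}

make_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  layer <- new.env(parent = emptyenv())
  p <- init_conv(kh, kw, cin, cout)
  layer$w <- p$w
  layer$b <- p$b
  layer$stride <- as.integer(stride)
  layer$pad <- as.integer(pad)
  layer$kind <- "conv"
  layer
}

make_bn <- function(C) {
  layer <- new.env(parent = emptyenv())
  layer$gamma <- ag_param(rep(1, C))
  layer$beta <- ag_param(numeric(C))
  layer$running_mean <- numeric(C)
  layer$running_var <- rep(1, C)
  layer$kind <- "bn"
  layer
}

make_se <- function(C, r) {
  if (C %% r != 0L) {
    stop("SE block: channel count ", C, " is not divisible by reduction ratio ", r)
  }
  layer <- new.env(parent = emptyenv())
  Cr <- C %/% r
  layer$w1 <- ag_param(matrix(rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C))
  layer$b1 <- ag_param(numeric(Cr))
  layer$w2 <- ag_param(matrix(rnorm(C * Cr, sd = sqrt(2 / Cr)), C, Cr))
  # positive excitation bias: gates start near passthrough (sigmoid(2) ~ 0.88)
  # instead of randomly attenuating channels, which destabilizes early training
  layer$b2 <- ag_param(rep(2, C))
  layer$kind <- "se"
  layer
}

make_res_block <- function(cin, cout, stride = 1L) {
  blk <- new.env(parent = emptyenv())
  blk$conv1 <- make_conv(3L, 3L, cin, cout, stride = stride, pad = 1L)
  blk$bn1 <- make_bn(cout)
  blk$conv2 <- make_conv(3L, 3L, cout, cout, stride = 1L, pad = 1L)
  blk$bn2 <- make_bn(cout)
  # residual-branch zero-initialization: the block starts as (a projection
  # of) the identity, which substantially speeds early optimization of the
  # 34-layer encoder when training from scratch
  blk$bn2$gamma$value[] <- 0
  if (cin != cout || stride != 1L) {
    blk$proj <- make_conv(1L, 1L, cin, cout, stride = stride, pad = 0L)
    blk$proj_bn <- make_bn(cout)
  } else {
    blk$proj <- NULL
  }
  blk$kind <- "res_block"
  blk
}

make_dblock <- function(cin_up, cskip, cout, se_ratio = NULL) {
  blk <- new.env(parent = emptyenv())
  blk$conv1 <- make_conv(3L, 3L, cin_up + cskip, cout, stride = 1L, pad = 1L)
  blk$bn1 <- make_bn(cout)
  blk$conv2 <- make_conv(3L, 3L, cout, cout, stride = 1L, pad = 1L)
  blk$bn2 <- make_bn(cout)
  blk$se <- if (!is.null(se_ratio)) make_se(cout, se_ratio) else NULL
  blk$kind <- "decoder_block"
  blk
}

# ---- layer forwards ----------------------------------------------------

fwd_conv <- function(layer, x, training) {
  op_conv(x, layer$w, layer$b, layer$stride, layer$pad, training)
}

fwd_se <- function(layer, x, training) {
  s <- op_gap(x, training)
  h <- op_relu(op_dense(s, layer$w1, layer$b1, training), training)
  gates <- op_sigmoid(op_dense(h, layer$w2, layer$b2, training), training)
  op_scale_channels(x, gates, training)
}

fwd_res_block <- function(blk, x, training) {
  h <- op_relu(op_bn(fwd_conv(blk$conv1, x, training), blk$bn1, training), training)
  h <- op_bn(fwd_conv(blk$conv2, h, training), blk$bn2, training)
  shortcut <- if (is.null(blk$proj)) {
    x
  } else {
    op_bn(fwd_conv(blk$proj, x, training), blk$proj_bn, training)
  }
  op_relu(op_add(h, shortcut, training), training)
}

fwd_dblock <- function(blk, x, skip, training) {
  up <- op_upsample2(x, training)
  h <- if (is.null(skip)) up else op_concat(up, skip, training)
  h <- op_relu(op_bn(fwd_conv(blk$conv1, h, training), blk$bn1, training), training)
  h <- op_relu(op_bn(fwd_conv(blk$conv2, h, training), blk$bn2, training), training)
  if (!is.null(blk$se)) h <- fwd_se(blk$se, h, training)
  h
}

# Collect every trainable parameter node in a layer tree.
collect_params <- function(obj) {
  out <- list()
  recurse <- function(x) {
    if (inherits(x, "ag_node")) {
      out[[length(out) + 1L]] <<- x
    } else if (is.environment(x)) {
      for (nm in ls(x)) {
        v <- get(nm, envir = x)
        if (inherits(v, "ag_node") || is.environment(v) || is.list(v)) recurse(v)
      }
    } else if (is.list(x)) {
      for (v in x) recurse(v)
    }
  }
  recurse(obj)
  out
}
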