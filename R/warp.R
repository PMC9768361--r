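# Shared similarity-transform resampling engine.
#
# One coordinate convention for the whole package: 0-based (x, y) =
# (column, row), y increasing downward, and a positive rotation angle
# turning the +x axis toward +y (clockwise on screen). Output pixels are
# filled by inverse mapping: each destination pixel is mapped back into the
# source and sampled bilinearly (images) or by nearest neighbor (label
# maps). Source coordinates falling outside the image are clamped to the
# border ("clamp") or marked invalid and filled with `fill` ("fill").

rotmat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)  # columns: image of e_x, e_y
}

# Inverse-map sampling of a single-channel matrix.
# xy_src: 2 x n matrix of (x, y) source coordinates (0-based) per output px.
sample_channel <- function(m, xs, ys, method, oob, fill) {
  H <- nrow(m); W <- ncol(m)
  if (method == "nearest") {
    xi <- round(xs); yi <- round(ys)
    inside <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    xi <- pmin(pmax(xi, 0), W - 1)
    yi <- pmin(pmax(yi, 0), H - 1)
    v <- m[cbind(yi + 1, xi + 1)]
    if (oob == "fill") v[!inside] <- fill
    return(v)
  }
  inside <- xs >= 0 & xs <= W - 1 & ys >= 0 & ys <= H - 1
  x0 <- floor(pmin(pmax(xs, 0), W - 1)); y0 <- floor(pmin(pmax(ys, 0), H - 1))
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- pmin(pmax(xs, 0), W - 1) - x0
  fy <- pmin(pmax(ys, 0), H - 1) - y0
  v <- (1 - fy) * ((1 - fx) * m[cbind(y0 + 1, x0 + 1)] + fx * m[cbind(y0 + 1, x1 + 1)]) +
    fy * ((1 - fx) * m[cbind(y1 + 1, x0 + 1)] + fx * m[cbind(y1 + 1, x1 + 1)])
  if (oob == "fill") v[!inside] <- fill
  v
}

# Rotate about the image center by `deg`, preserving shape.
# method: "bilinear" (images) or "nearest" (label maps); oob "clamp"/"fill".
rotate_about_center <- function(m, deg, method = "bilinear", oob = "clamp", fill = 0) {
  d <- dim(m)
  H <- d[1]; W <- d[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  g <- expand.grid(y = seq_len(H) - 1, x = seq_len(W) - 1)
  Rinv <- rotmat(-deg)
  xs <- Rinv[1, 1] * (g$x - cx) + Rinv[1, 2] * (g$y - cy) + cx
  ys <- Rinv[2, 1] * (g$x - cx) + Rinv[2, 2] * (g$y - cy) + cy
  warp_apply(m, xs, ys, d, method, oob, fill)
}

warp_apply <- function(m, xs, ys, out_dim, method, oob, fill) {
  if (length(dim(m)) == 3L) {
    out <- array(0, c(out_dim[1], out_dim[2], dim(m)[3]))
    for (ch in seq_len(dim(m)[3])) {
      out[, , ch] <- sample_channel(m[, , ch], xs, ys, method, oob, fill)
    }
  } else {
    out <- matrix(sample_channel(m, xs, ys, method, oob, fill),
                  out_dim[1], out_dim[2])
    if (is.integer(m) && method == "nearest") storage.mode(out) <- "integer"
  }
  out
}

# Integer translation with reflection padding: output(y, x) =
# input(reflect(y - dy), reflect(x - dx)).
shift_reflect <- function(m, dx, dy) {
  d <- dim(m)
  reflect_idx <- function(i, n) {
    # reflect 0-based indices into [0, n-1] (edge-mirrored)
    if (n == 1L) return(rep(0L, length(i)))
    p <- 2L * (n - 1L)
    i <- ((i %% p) + p) %% p
    ifelse(i >= n, p - i, i)
  }
  yi <- reflect_idx(seq_len(d[1]) - 1L - as.integer(dy), d[1]) + 1L
  xi <- reflect_idx(seq_len(d[2]) - 1L - as.integer(dx), d[2]) + 1L
  if (length(d) == 3L) m[yi, xi, , drop = FALSE] else m[yi, xi, drop = FALSE]
}

flip_h <- function(m) {  # mirror left-right
  d <- dim(m)
  if (length(d) == 3L) m[, rev(seq_len(d[2])), , drop = FALSE] else m[, rev(seq_len(d[2])), drop = FALSE]
}

flip_v <- function(m) {  # mirror top-bottom
  d <- dim(m)
  if (length(d) == 3L) m[rev(seq_len(d[1])), , , drop = FALSE] else m[rev(seq_len(d[1])), , drop = FALSE]
}
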