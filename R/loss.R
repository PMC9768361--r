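# Training loss: soft Jaccard distance + cross-entropy.
#
# Both parts are means over pixels (and over class channels for the Jaccard
# part), so values are comparable across patch and batch sizes. Predictions
# p are per-pixel class probabilities in [0, 1]; references y are one-hot
# (binary) labels of the same shape.

check_pair <- function(p, y) {
  if (!identical(dim2(p), dim2(y))) {
    stop("prediction and label shapes differ: ",
         paste(dim2(p), collapse = "x"), " vs ", paste(dim2(y), collapse = "x"))
  }
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Soft Jaccard distance loss
#'
#' Per-pixel soft intersection-over-union deficit,
#' `1 - mean_i (p_i * y_i + s) / (p_i + y_i - p_i * y_i + s)`,
#' averaged over all pixels and class channels. The smoothing constant `s`
#' makes the empty-vs-empty case (`p = y = 0`) contribute a perfect-overlap
#' term instead of 0/0.
#'
#' @param p predicted probabilities in `[0, 1]`; a vector, matrix or array.
#' @param y reference labels in `{0, 1}` with the same shape.
#' @param smooth smoothing constant added to numerator and denominator;
#'   set to 0 for the unsmoothed form (0/0 terms then count as perfect
#'   overlap, the limit as smoothing goes to 0).
#' @return scalar in `[0, 1]`; 0 exactly when `p == y` and both are binary.
#' @export
jaccard_distance_loss <- function(p, y, smooth = 1) {
  check_pair(p, y)
  if (any(p < 0 | p > 1)) stop("predictions must lie in [0, 1]")
  num <- p * y + smooth
  den <- p + y - p * y + smooth
  term <- ifelse(den == 0, 1, num / den)  # den == 0 only when smooth = 0 and p = y = 0
  1 - mean(term)
}

#' Cross-entropy loss
#'
#' `-(1/N) sum_i sum_k y_ik log(max(p_ik, clip))` with `N` the number of
#' pixels: the mean over pixels of the negative log-probability assigned to
#' each pixel's reference class. Probabilities are clipped below at `clip`
#' to keep the loss finite for hard-zero predictions.
#'
#' @inheritParams jaccard_distance_loss
#' @param clip lower probability clip.
#' @return non-negative scalar; 0 iff `p` equals the one-hot `y`.
#' @export
cross_entropy_loss <- function(p, y, clip = 1e-7) {
  check_pair(p, y)
  n_pix <- length(p) / n_channels(p)
  -sum(y * log(pmax(p, clip))) / n_pix
}

# Channel count: last margin of a >=3-D array is the batch, dim 3 the class
# channel; vectors/matrices are a single channel.
n_channels <- function(p) {
  d <- dim(p)
  if (is.null(d) || length(d) < 3L) 1L else d[3]
}

#' Combined segmentation loss
#'
#' Sum of the soft Jaccard distance and the cross-entropy loss, with the
#' two parts reported separately.
#'
#' @inheritParams jaccard_distance_loss
#' @param clip lower probability clip for the cross-entropy part.
#' @return a `loss_value`: list with `total`, `jaccard_part`, `ce_part`,
#'   where `total == jaccard_part + ce_part`.
#' @export
combined_loss <- function(p, y, smooth = 1, clip = 1e-7) {
  jp <- jaccard_distance_loss(p, y, smooth)
  cp <- cross_entropy_loss(p, y, clip)
  structure(list(total = jp + cp, jaccard_part = jp, ce_part = cp),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("combined loss %.6f (jaccard %.6f + cross-entropy %.6f)\n",
              x$total, x$jaccard_part, x$ce_part))
  invisible(x)
}

# Gradient of the combined loss with respect to p (same shape as p).
# Feeds the softmax node during training.
combined_loss_grad <- function(p, y, smooth = 1, clip = 1e-7) {
  n_pix <- length(p) / n_channels(p)
  den <- p + y - p * y + smooth
  d_jacc <- -(y * den - (p * y + smooth) * (1 - y)) / (den * den) / length(p)
  d_ce <- -(y / pmax(p, clip)) * (p >= clip) / n_pix
  d_jacc + d_ce
}
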