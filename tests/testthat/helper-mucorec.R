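# Shared fixtures, all generated in code.

random_classmap <- function(h, w, num_classes = 3L, seed = NULL) {
  draw <- function() matrix(sample(0:(num_classes - 1L), h * w, replace = TRUE), h, w)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Naive double-loop pixel-count oracle for per-class IoU and Dice.
iou_dice_oracle <- function(pred, truth, num_classes = 3L) {
  inter <- pred_n <- truth_n <- numeric(num_classes)
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] + 1L
      t <- truth[i, j] + 1L
      pred_n[p] <- pred_n[p] + 1
      truth_n[t] <- truth_n[t] + 1
      if (p == t) inter[p] <- inter[p] + 1
    }
  }
  union <- pred_n + truth_n - inter
  list(iou = ifelse(union == 0, NA_real_, inter / union),
       dice = ifelse(pred_n + truth_n == 0, NA_real_, 2 * inter / (pred_n + truth_n)),
       miou = mean(ifelse(union == 0, NA_real_, inter / union), na.rm = TRUE),
       dice_mean = mean(ifelse(pred_n + truth_n == 0, NA_real_,
                               2 * inter / (pred_n + truth_n)), na.rm = TRUE))
}

# A tiny flat-texture RGB patch of one solid color plus optional noise.
solid_patch <- function(h, w, rgb, noise = 0) {
  img <- array(rep(rgb, each = h * w), c(h, w, 3L))
  if (noise > 0) img <- pmin(pmax(img + rnorm(length(img), sd = noise), 0), 1)
  img
}
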