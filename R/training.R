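# Training loop: online augmentation, Adam on the combined loss,
# per-epoch logging and optional validation MIoU.

#' Training configuration
#'
#' Defaults follow the segmentation recipe the pipeline is built around:
#' Adam at learning rate 3e-4, 50 epochs, batch size 4, and augmentation by
#' rotation over the full circle, translations up to 50 px and horizontal /
#' vertical flips.
#'
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the (oversampled) training set.
#' @param batch_size patches per optimizer step.
#' @param rotation_range rotation angles are drawn uniformly from
#'   `[rotation_range[1], rotation_range[2]]` degrees.
#' @param shift_range maximum absolute translation in pixels; shifts are
#'   drawn uniformly from `-shift_range..shift_range` in each axis
#'   (reflection padding).
#' @param flips apply horizontal and vertical flips, each with
#'   probability 1/2.
#' @param val_fraction held-out fraction used for epoch-level MIoU
#'   monitoring when no explicit validation set is given (the final model
#'   is always the last epoch; no early stopping).
#' @param rng_seed master seed: makes shuffling, augmentation draws and
#'   therefore the whole run reproducible on fixed hardware.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, epochs = 50L, batch_size = 4L,
                         rotation_range = c(0, 359), shift_range = c(0, 50),
                         flips = TRUE, val_fraction = 0.1, rng_seed = 1L) {
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  if (any(rotation_range < 0) || any(shift_range < 0)) {
    stop("augmentation ranges must be non-negative")
  }
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 rotation_range = rotation_range, shift_range = shift_range,
                 flips = flips, val_fraction = val_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Jointly augment an image patch and its class map
#'
#' Draws one rotation angle, one (dx, dy) translation and flip flags from
#' the configured ranges and applies the identical geometric transform to
#' both inputs: rotation about the patch center (bilinear for the image,
#' nearest neighbor for the class map, so no fractional classes are
#' invented), then integer translation with reflection padding, then flips.
#' Output shapes equal input shapes.
#'
#' @param image RGB patch `H x W x 3`.
#' @param cm class map `H x W`.
#' @param cfg a [train_config()] providing the ranges.
#' @param seed optional seed making this single draw reproducible; when
#'   `NULL` the current RNG stream is used (online augmentation).
#' @return list with transformed `image` and `cm` and the drawn `angle`,
#'   `shift`, `flip_h`, `flip_v`.
#' @export
augment <- function(image, cm, cfg = train_config(), seed = NULL) {
  if (!identical(dim(image)[1:2], dim(cm))) {
    stop("image and class map spatial shapes differ")
  }
  draw <- function() {
    list(angle = runif(1, cfg$rotation_range[1], cfg$rotation_range[2]),
         dx = sample(-cfg$shift_range[2]:cfg$shift_range[2], 1L),
         dy = sample(-cfg$shift_range[2]:cfg$shift_range[2], 1L),
         fh = cfg$flips && runif(1) < 0.5,
         fv = cfg$flips && runif(1) < 0.5)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  img <- image; m <- cm
  if (d$angle != 0) {
    img <- rotate_about_center(img, d$angle, "bilinear", "clamp")
    m <- rotate_about_center(m, d$angle, "nearest", "clamp")
  }
  if (d$dx != 0 || d$dy != 0) {
    img <- shift_reflect(img, d$dx, d$dy)
    m <- shift_reflect(m, d$dx, d$dy)
  }
  if (d$fh) { img <- flip_h(img); m <- flip_h(m) }
  if (d$fv) { img <- flip_v(img); m <- flip_v(m) }
  list(image = img, cm = m, angle = d$angle, shift = c(d$dx, d$dy),
       flip_h = d$fh, flip_v = d$fv)
}

# ---- Adam --------------------------------------------------------------

adam_new <- function(params) {
  # moment buffers mirror each parameter's exact shape (vector stays vector)
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- params[[i]]$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]]$value <- params[[i]]$value -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}

# ---- training ----------------------------------------------------------

#' Train a segmentation network
#'
#' Minimizes the combined soft-Jaccard + cross-entropy loss with Adam over
#' augmented patches. Each epoch logs the mean loss (total and both parts)
#' and, when a validation set is available, the validation MIoU. The run is
#' fully reproducible given `cfg$rng_seed`.
#'
#' @param net a `seunet` from [build_network()].
#' @param dataset list of training samples, each a list with `image`
#'   (`H x W x 3`) and `cm` (`H x W` class map); `H`, `W` must match
#'   `net$cfg$input_size`.
#' @param cfg a [train_config()].
#' @param val_dataset optional validation samples (same format). When
#'   `NULL` and `cfg$val_fraction > 0`, that fraction of `dataset` is
#'   held out.
#' @param balance oversample minority class-presence strata (with
#'   replacement) before training.
#' @param augment_data apply online augmentation per draw.
#' @param checkpoint_dir when given, weights are checkpointed there after
#'   every epoch (`epoch_###.rds`).
#' @param verbose print one line per epoch.
#' @return list with the trained `net` and `log`, a data frame with one
#'   row per epoch: `epoch`, `mean_loss`, `jaccard_part`, `ce_part`,
#'   `val_miou`.
#' @export
train_network <- function(net, dataset, cfg = train_config(), val_dataset = NULL,
                          balance = TRUE, augment_data = TRUE,
                          checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "seunet"), inherits(cfg, "train_config"))
  if (length(dataset) == 0L) stop("empty training set")
  set.seed(cfg$rng_seed)
  if (is.null(val_dataset) && cfg$val_fraction > 0 && length(dataset) >= 10L) {
    n_val <- max(1L, floor(cfg$val_fraction * length(dataset)))
    idx <- sample(length(dataset), n_val)
    val_dataset <- dataset[idx]
    dataset <- dataset[-idx]
  }
  manifest <- data.frame(index = seq_along(dataset),
                         stratum = vapply(dataset, function(s) class_presence(s$cm),
                                          character(1)))
  if (balance && length(unique(manifest$stratum)) > 1L) {
    manifest <- oversample(manifest, rng_seed = cfg$rng_seed)
  }
  params <- collect_params(net)
  opt <- adam_new(params)
  K <- net$cfg$num_classes
  if (!is.null(checkpoint_dir)) dir.create(checkpoint_dir, recursive = TRUE,
                                           showWarnings = FALSE)
  log <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(nrow(manifest))
    n_batch <- ceiling(length(ord) / cfg$batch_size)
    tot <- jp <- cp <- 0
    for (bi in seq_len(n_batch)) {
      sel <- manifest$index[ord[((bi - 1L) * cfg$batch_size + 1L):
                                  min(bi * cfg$batch_size, length(ord))]]
      B <- length(sel)
      sz <- dim(dataset[[sel[1]]]$image)[1:2]
      xb <- array(0, c(sz, 3L, B))
      yb <- array(0, c(sz, K, B))
      for (j in seq_len(B)) {
        smp <- dataset[[sel[j]]]
        if (augment_data) {
          a <- augment(smp$image, smp$cm, cfg)
          xb[, , , j] <- a$image
          yb[, , , j] <- one_hot(a$cm, K)
        } else {
          xb[, , , j] <- smp$image
          yb[, , , j] <- one_hot(smp$cm, K)
        }
      }
      p <- seunet_forward(net, xb, training = TRUE)
      lv <- combined_loss(p$value, yb)
      if (!is.finite(lv$total)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", bi,
             " (jaccard ", lv$jaccard_part, ", ce ", lv$ce_part, "); aborting")
      }
      ag_zero_grad(params)
      ag_backward(p, combined_loss_grad(p$value, yb))
      opt <- adam_step(params, opt, cfg$learning_rate)
      tot <- tot + lv$total; jp <- jp + lv$jaccard_part; cp <- cp + lv$ce_part
    }
    val_miou <- NA_real_
    if (!is.null(val_dataset) && length(val_dataset) > 0L) {
      val_miou <- mean(vapply(val_dataset, function(s) {
        pm <- forward_network(net, s$image)
        miou(probmap_to_classmap(pm), s$cm, K)
      }, numeric(1)))
    }
    log[[epoch]] <- data.frame(epoch = epoch, mean_loss = tot / n_batch,
                               jaccard_part = jp / n_batch, ce_part = cp / n_batch,
                               val_miou = val_miou)
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.4f (jaccard %.4f, ce %.4f)  val MIoU %s",
                      epoch, cfg$epochs, tot / n_batch, jp / n_batch, cp / n_batch,
                      ifelse(is.na(val_miou), "-", sprintf("%.4f", val_miou))))
    }
    if (!is.null(checkpoint_dir)) {
      save_checkpoint(net, file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch)))
    }
  }
  list(net = net, log = do.call(rbind, log))
}

#' Per-pixel argmax of a probability map
#' @param pm array `H x W x K`.
#' @return integer class map (ties toward the lowest class index).
#' @export
probmap_to_classmap <- function(pm) {
  d <- dim(pm)
  matrix(max.col(matrix(pm, ncol = d[3]), ties.method = "first") - 1L, d[1], d[2])
}

#' Segment a whole slide with a trained network
#'
#' Tiles the slide, runs the network on every tile, stitches the per-tile
#' probability maps back at their origins (averaging overlaps when
#' `stride < tile_size`) and takes the per-pixel argmax.
#'
#' @param net trained `seunet`.
#' @param slide RGB slide array (`H x W x 3`).
#' @param tile_size tile size; defaults to the network input size.
#' @param stride tiling stride (`<= tile_size`).
#' @param batch_size tiles per forward pass.
#' @return list with `classmap` (`H x W` integer) and `probmap`
#'   (`H x W x K`).
#' @export
predict_slide <- function(net, slide, tile_size = net$cfg$input_size,
                          stride = tile_size, batch_size = 4L) {
  ts <- tile_slide(slide, tile_size, stride)
  n <- length(ts$tiles)
  probs <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    xb <- array(0, c(tile_size, tile_size, 3L, length(sel)))
    for (j in seq_along(sel)) xb[, , , j] <- ts$tiles[[sel[j]]]
    pb <- forward_network(net, xb)
    for (j in seq_along(sel)) probs[[sel[j]]] <- pb[, , , j]
  }
  ts$tiles <- probs
  stitch_classmaps(ts)
}
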