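#' Segmentation network configuration
#'
#' Describes the SE-block ResNet-34 U-Net used for patch segmentation: a
#' ResNet-34 encoder (residual stages of 3, 4, 6 and 3 blocks, total
#' downsampling factor 32), a U-Net decoder whose stages upsample 2x and
#' concatenate the matching encoder skip, squeeze-and-excitation channel
#' recalibration on decoder stage outputs, and a final 1x1 convolution with
#' per-pixel softmax over the three mucosa classes.
#'
#' @param num_classes number of output classes (3: normal, cancerous,
#'   intestinal metaplasia).
#' @param input_size input patch height/width in pixels; must be divisible
#'   by 32 (the encoder's total downsampling factor). 512 for full-scale
#'   slides; smaller sizes are supported for desk-scale experiments.
#' @param base_channels width of the first encoder stage. 64 gives the
#'   standard ResNet-34; 16 gives the reduced preset used in small-scale
#'   experiments.
#' @param blocks residual blocks per encoder stage (ResNet-34 layout).
#' @param decoder_channels output channels of the five decoder stages
#'   (four skip-connected stages plus the final full-resolution stage).
#'   Default scales with `base_channels`.
#' @param se_reduction squeeze-and-excitation reduction ratio `r`; must
#'   divide every gated channel count.
#' @param se_placement where SE blocks sit: `"decoder"` (one per decoder
#'   stage output, the default), `"encoder"` (one per encoder stage output),
#'   `"bridge"` (one on the bottleneck), or `"none"` (plain U-Net, used as
#'   the comparison baseline).
#' @param rng_seed seed for weight initialization.
#' @return an object of class `network_config`.
#' @export
network_config <- function(num_classes = 3L,
                           input_size = 512L,
                           base_channels = 64L,
                           blocks = c(3L, 4L, 6L, 3L),
                           decoder_channels = NULL,
                           se_reduction = 16L,
                           se_placement = c("decoder", "encoder", "bridge", "none"),
                           rng_seed = 42L) {
  se_placement <- match.arg(se_placement)
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) {
    stop("input_size must be divisible by 32 (encoder downsampling factor), got ",
         input_size)
  }
  if (length(blocks) != 4L) stop("blocks must give 4 encoder stages")
  if (is.null(decoder_channels)) {
    decoder_channels <- as.integer(base_channels * c(4L, 2L, 1L, 1L, 1L) /
                                     c(1L, 1L, 1L, 2L, 4L))
    decoder_channels <- pmax(decoder_channels, se_reduction)
  }
  if (length(decoder_channels) != 5L) stop("decoder_channels must have length 5")
  enc_channels <- base_channels * c(1L, 2L, 4L, 8L)
  gated <- switch(se_placement,
                  decoder = decoder_channels,
                  encoder = enc_channels,
                  bridge = enc_channels[4],
                  none = integer(0))
  if (length(gated) && any(gated %% se_reduction != 0L)) {
    stop("se_reduction (", se_reduction, ") must divide every gated channel count: ",
         paste(gated, collapse = ", "))
  }
  cfg <- list(num_classes = as.integer(num_classes),
              input_size = input_size,
              base_channels = as.integer(base_channels),
              blocks = as.integer(blocks),
              decoder_channels = as.integer(decoder_channels),
              se_reduction = as.integer(se_reduction),
              se_placement = se_placement,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "network_config"
  cfg
}

#' Reduced network preset for desk-scale experiments
#'
#' ResNet-34 block layout at base width 16 with a slim decoder, sized so a
#' 128 px-patch experiment trains in minutes on one CPU core.
#'
#' @param input_size input patch size (divisible by 32).
#' @param se_placement SE placement, as in [network_config()].
#' @param rng_seed weight-initialization seed.
#' @return a `network_config`.
#' @export
reduced_network_config <- function(input_size = 128L,
                                   se_placement = "decoder",
                                   rng_seed = 42L) {
  network_config(input_size = input_size, base_channels = 16L,
                 decoder_channels = c(64L, 32L, 16L, 16L, 8L),
                 se_reduction = 8L, se_placement = se_placement,
                 rng_seed = rng_seed)
}

#' Build the SE ResNet-34 U-Net
#'
#' Instantiates the network described by a [network_config()]: ResNet-34
#' encoder stages exposed as skip connections, a five-stage U-Net decoder
#' (nearest-neighbor 2x upsampling + 3x3 convolutions), SE channel
#' recalibration per `cfg$se_placement`, and a softmax head. Weights use
#' seeded He initialization; previously trained weights can be restored
#' with [load_checkpoint()].
#'
#' @param cfg a `network_config`.
#' @return an object of class `seunet`.
#' @export
build_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  withr::with_seed(cfg$rng_seed, {
    b <- cfg$base_channels
    enc_ch <- b * c(1L, 2L, 4L, 8L)
    net <- new.env(parent = emptyenv())
    net$cfg <- cfg
    net$stem_conv <- make_conv(7L, 7L, 3L, b, stride = 2L, pad = 3L)
    net$stem_bn <- make_bn(b)
    stage <- function(cin, cout, n, first_stride) {
      blocks <- vector("list", n)
      blocks[[1L]] <- make_res_block(cin, cout, stride = first_stride)
      for (i in seq_len(n - 1L)) blocks[[i + 1L]] <- make_res_block(cout, cout, 1L)
      blocks
    }
    net$stage1 <- stage(b, enc_ch[1], cfg$blocks[1], 1L)
    net$stage2 <- stage(enc_ch[1], enc_ch[2], cfg$blocks[2], 2L)
    net$stage3 <- stage(enc_ch[2], enc_ch[3], cfg$blocks[3], 2L)
    net$stage4 <- stage(enc_ch[3], enc_ch[4], cfg$blocks[4], 2L)
    if (cfg$se_placement == "encoder") {
      net$enc_se <- lapply(enc_ch, make_se, r = cfg$se_reduction)
    }
    if (cfg$se_placement == "bridge") {
      net$bridge_se <- make_se(enc_ch[4], cfg$se_reduction)
    }
    dec <- cfg$decoder_channels
    dec_se <- if (cfg$se_placement == "decoder") cfg$se_reduction else NULL
    net$dec1 <- make_dblock(enc_ch[4], enc_ch[3], dec[1], dec_se)
    net$dec2 <- make_dblock(dec[1], enc_ch[2], dec[2], dec_se)
    net$dec3 <- make_dblock(dec[2], enc_ch[1], dec[3], dec_se)
    net$dec4 <- make_dblock(dec[3], b, dec[4], dec_se)
    net$dec5 <- make_dblock(dec[4], 0L, dec[5], dec_se)
    net$head <- make_conv(1L, 1L, dec[5], cfg$num_classes, stride = 1L, pad = 0L)
    class(net) <- "seunet"
    net
  })
}

# Forward pass returning the softmax probability node (autograd graph when
# training = TRUE). x: (H, W, 3, N) array with H, W divisible by 32.
seunet_forward <- function(net, x, training = FALSE) {
  cfg <- net$cfg
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("input spatial size must be divisible by 32, got ", d[1], "x", d[2])
  }
  xn <- ag_node(x)
  s0 <- op_relu(op_bn(fwd_conv(net$stem_conv, xn, training), net$stem_bn, training),
                training)
  h <- op_maxpool(s0, 3L, 2L, 1L, training)
  run_stage <- function(blocks, h) {
    for (blk in blocks) h <- fwd_res_block(blk, h, training)
    h
  }
  s1 <- run_stage(net$stage1, h)
  s2 <- run_stage(net$stage2, s1)
  s3 <- run_stage(net$stage3, s2)
  s4 <- run_stage(net$stage4, s3)
  if (cfg$se_placement == "encoder") {
    s1 <- fwd_se(net$enc_se[[1]], s1, training)
    s2 <- fwd_se(net$enc_se[[2]], s2, training)
    s3 <- fwd_se(net$enc_se[[3]], s3, training)
    s4 <- fwd_se(net$enc_se[[4]], s4, training)
  }
  if (cfg$se_placement == "bridge") s4 <- fwd_se(net$bridge_se, s4, training)
  h <- fwd_dblock(net$dec1, s4, s3, training)
  h <- fwd_dblock(net$dec2, h, s2, training)
  h <- fwd_dblock(net$dec3, h, s1, training)
  h <- fwd_dblock(net$dec4, h, s0, training)
  h <- fwd_dblock(net$dec5, h, NULL, training)
  logits <- fwd_conv(net$head, h, training)
  op_softmax(logits, training)
}

#' Forward pass of a segmentation network
#'
#' @param net a `seunet` from [build_network()].
#' @param x an RGB patch (`H x W x 3`, values in `[0, 1]`) or a batch
#'   (`H x W x 3 x N`); `H` and `W` must be divisible by 32.
#' @return class-probability array with the same spatial shape: `H x W x K`
#'   for a single patch, `H x W x K x N` for a batch. Channels sum to 1 at
#'   every pixel.
#' @export
forward_network <- function(net, x) {
  stopifnot(inherits(net, "seunet"))
  single <- length(dim(x)) == 3L
  p <- seunet_forward(net, as_batch(x), training = FALSE)$value
  if (single) dim(p) <- dim(p)[1:3]
  p
}

#' @export
print.seunet <- function(x, ...) {
  cfg <- x$cfg
  np <- sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))
  cat(sprintf(paste0("<seunet> SE ResNet-34 U-Net: input %dx%d, %d classes, ",
                     "base width %d, SE r=%d (%s), %s parameters\n"),
              cfg$input_size, cfg$input_size, cfg$num_classes, cfg$base_channels,
              cfg$se_reduction, cfg$se_placement, format(np, big.mark = ",")))
  invisible(x)
}

# ---- standalone block operations ---------------------------------------

#' Residual block forward pass
#'
#' Two 3x3 convolutions, each followed by batch normalization and ReLU, with
#' the block input added back through an identity (or 1x1-projected)
#' shortcut before the final activation.
#'
#' @param x feature map, `H x W x C` or `H x W x C x N`.
#' @param out_channels output channel count.
#' @param stride 1 or 2 (2 halves the spatial size).
#' @param block optional prebuilt block environment (from `make_res_block`);
#'   built with seeded weights when `NULL`.
#' @param training use batch statistics in the normalization layers
#'   (`TRUE`) or the stored running statistics (`FALSE`).
#' @param rng_seed seed used when `block` is `NULL`.
#' @return feature map array, same batch convention as the input.
#' @export
residual_block <- function(x, out_channels, stride = 1L, block = NULL,
                           training = FALSE, rng_seed = 1L) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  single <- length(dim(x)) == 3L
  xb <- as_batch(x)
  cin <- dim(xb)[3]
  if (is.null(block)) {
    block <- withr::with_seed(rng_seed, make_res_block(cin, as.integer(out_channels),
                                                       as.integer(stride)))
  }
  if (is.null(block$proj) && cin != out_channels) {
    stop("channel mismatch (", cin, " -> ", out_channels, ") without a projection shortcut")
  }
  y <- fwd_res_block(block, ag_node(xb), training)$value
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' Squeeze-and-excitation block forward pass
#'
#' Squeeze: per-channel global average pool. Excitation: a C -> C/r ReLU
#' layer followed by a C/r -> C logistic layer, yielding per-channel gates
#' in (0, 1). The input is rescaled channel-wise by the gates.
#'
#' @param x feature map, `H x W x C` or `H x W x C x N`.
#' @param r reduction ratio; must divide `C`.
#' @param block optional prebuilt SE layer (from `make_se`).
#' @param rng_seed seed used when `block` is `NULL`.
#' @return rescaled feature map of the same shape.
#' @export
se_block <- function(x, r = 16L, block = NULL, rng_seed = 1L) {
  single <- length(dim(x)) == 3L
  xb <- as_batch(x)
  C <- dim(xb)[3]
  if (is.null(block)) block <- withr::with_seed(rng_seed, make_se(C, as.integer(r)))
  y <- fwd_se(block, ag_node(xb), training = FALSE)$value
  if (single) dim(y) <- dim(y)[1:3]
  y
}

# ---- checkpoints -------------------------------------------------------

# Flatten all parameters and batchnorm running statistics to plain arrays.
network_weights <- function(net) {
  params <- collect_params(net)
  list(values = lapply(params, function(p) p$value),
       bn_state = bn_states(net))
}

bn_layers <- function(net) {
  out <- list()
  recurse <- function(x) {
    if (is.environment(x) && !inherits(x, "ag_node")) {
      if (identical(x$kind, "bn")) out[[length(out) + 1L]] <<- x
      for (nm in ls(x)) {
        v <- get(nm, envir = x)
        if (is.environment(v) || is.list(v)) recurse(v)
      }
    } else if (is.list(x)) {
      for (v in x) recurse(v)
    }
  }
  recurse(net)
  out
}

bn_states <- function(net) {
  lapply(bn_layers(net), function(l) list(mean = l$running_mean, var = l$running_var))
}

#' Save network weights to a checkpoint file
#'
#' The checkpoint embeds the `network_config`, so [load_checkpoint()] can
#' rebuild the architecture before restoring weights and batch-norm running
#' statistics.
#'
#' @param net a `seunet`.
#' @param path file path (RDS format).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = unclass(net$cfg), weights = network_weights(net)), path)
  invisible(path)
}

#' Load a network from a checkpoint file
#' @param path file written by [save_checkpoint()].
#' @return a `seunet` with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(network_config, ck$cfg[setdiff(names(ck$cfg), character(0))])
  net <- build_network(cfg)
  set_network_weights(net, ck$weights)
  net
}

set_network_weights <- function(net, weights) {
  params <- collect_params(net)
  stopifnot(length(params) == length(weights$values))
  for (i in seq_along(params)) {
    stopifnot(length(params[[i]]$value) == length(weights$values[[i]]))
    params[[i]]$value <- weights$values[[i]]
  }
  bns <- bn_layers(net)
  stopifnot(length(bns) == length(weights$bn_state))
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- weights$bn_state[[i]]$mean
    bns[[i]]$running_var <- weights$bn_state[[i]]$var
  }
  invisible(net)
}
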