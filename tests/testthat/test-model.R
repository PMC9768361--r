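# Network architecture contract. Desk-scale configs (small widths) keep
# these fast; the contracts are width-independent.

test_that("network config validates its invariants", {
  expect_error(network_config(input_size = 100L), "divisible by 32")
  expect_error(network_config(input_size = 64L, base_channels = 16L,
                              decoder_channels = c(64L, 32L, 16L, 16L, 8L),
                              se_reduction = 16L),
               "must divide")
  cfg <- reduced_network_config(64L)
  expect_s3_class(cfg, "network_config")
  expect_equal(cfg$blocks, c(3L, 4L, 6L, 3L))
})

test_that("forward pass preserves spatial shape and emits per-pixel probabilities", {
  net <- build_network(reduced_network_config(64L, rng_seed = 1L))
  for (size in c(64L, 128L)) {
    x <- withr::with_seed(size, array(runif(size * size * 3), c(size, size, 3L)))
    p <- forward_network(net, x)
    expect_equal(dim(p), c(size, size, 3L))
    sums <- apply(p, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-5))
    expect_true(all(p >= 0))
  }
  # batched input keeps the batch axis
  xb <- withr::with_seed(3, array(runif(64 * 64 * 3 * 2), c(64, 64, 3L, 2L)))
  pb <- forward_network(net, xb)
  expect_equal(dim(pb), c(64L, 64L, 3L, 2L))
  expect_error(forward_network(net, array(0, c(50, 50, 3))), "divisible by 32")
})

test_that("evaluation-mode forward passes are deterministic", {
  net <- build_network(reduced_network_config(64L, rng_seed = 7L))
  x <- withr::with_seed(9, array(runif(64 * 64 * 3), c(64, 64, 3L)))
  expect_identical(forward_network(net, x), forward_network(net, x))
  # identical seeds rebuild identical weights
  net2 <- build_network(reduced_network_config(64L, rng_seed = 7L))
  expect_identical(forward_network(net2, x), forward_network(net, x))
})

test_that("residual blocks implement the shortcut arithmetic", {
  blk <- mucorec:::make_res_block(4L, 4L, 1L)
  for (p in mucorec:::collect_params(blk)) p$value[] <- 0
  # zero input, zero weights, identity shortcut -> zero output
  x0 <- array(0, c(8, 8, 4))
  expect_true(all(residual_block(x0, 4L, block = blk) == 0))
  # zero conv weights with batchnorm as identity (eval mode, running stats
  # mean 0 / var 1, gamma restored to 1): pure shortcut passthrough + ReLU
  for (bn in mucorec:::bn_layers(blk)) bn$gamma$value[] <- 1
  x <- withr::with_seed(2, array(runif(8 * 8 * 4), c(8, 8, 4)))
  out <- residual_block(x, 4L, block = blk, training = FALSE)
  expect_equal(out, x, tolerance = 1e-4)  # ReLU inert on positive input; bn eps shrinks slightly
  # stride-2 halves spatial dims
  y <- residual_block(withr::with_seed(3, array(runif(64 * 64 * 8), c(64, 64, 8))),
                      16L, stride = 2L)
  expect_equal(dim(y), c(32L, 32L, 16L))
  # channel change without projection is an error
  blk_np <- mucorec:::make_res_block(4L, 4L, 1L)
  expect_error(residual_block(array(0, c(8, 8, 6)), 4L, block = blk_np),
               "channel mismatch|channels")
})

test_that("squeeze-and-excitation gates behave as the closed form predicts", {
  x <- withr::with_seed(4, array(runif(8 * 8 * 8), c(8, 8, 8)))
  # zeroed excitation weights: every gate is logistic(0) = 1/2
  se0 <- mucorec:::make_se(8L, 4L)
  for (p in mucorec:::collect_params(se0)) p$value[] <- 0
  expect_equal(se_block(x, block = se0), x * 0.5, tolerance = 1e-14)
  # zero input stays zero under any gates (multiplicative rescaling)
  se1 <- mucorec:::make_se(8L, 4L)
  expect_true(all(se_block(array(0, c(4, 4, 8)), block = se1) == 0))
  # squeeze of a constant channel is exactly that constant (vs brute-force mean)
  xc <- array(runif(16 * 16 * 4), c(16, 16, 4, 1))
  xc[, , 2, ] <- 0.37
  s <- mucorec:::op_gap(mucorec:::ag_node(xc), training = FALSE)$value
  expect_equal(s[2, 1], 0.37, tolerance = 1e-15)
  expect_equal(s[1, 1], mean(xc[, , 1, 1]), tolerance = 1e-15)
  expect_error(mucorec:::make_se(10L, 4L), "divisible")
  # gates lie strictly in (0, 1)
  gates <- se_block(x, block = se1) / ifelse(x == 0, 1, x)
  expect_true(all(gates[x != 0] > 0 & gates[x != 0] < 1))
})

test_that("network output is translation-covariant on interior pixels", {
  net <- build_network(reduced_network_config(64L, rng_seed = 5L))
  base <- withr::with_seed(6, array(runif(96 * 64 * 3), c(96, 64, 3L)))
  x1 <- base[1:64, , , drop = FALSE]
  x2 <- base[33:96, , , drop = FALSE]  # shifted by 32 px (= total stride)
  p1 <- forward_network(net, array(x1, c(64, 64, 3)))
  p2 <- forward_network(net, array(x2, c(64, 64, 3)))
  c1 <- probmap_to_classmap(p1)[49:56, 25:40]  # interior window, shifted copy
  c2 <- probmap_to_classmap(p2)[17:24, 25:40]
  expect_gte(mean(c1 == c2), 0.95)
})

test_that("checkpoints round-trip weights and running statistics", {
  net <- build_network(reduced_network_config(64L, rng_seed = 8L))
  # perturb running stats away from initialization via one training forward
  x <- withr::with_seed(10, array(runif(64 * 64 * 3 * 2), c(64, 64, 3L, 2L)))
  invisible(mucorec:::seunet_forward(net, x, training = TRUE))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  xt <- withr::with_seed(11, array(runif(64 * 64 * 3), c(64, 64, 3L)))
  expect_identical(forward_network(net2, xt), forward_network(net, xt))
})
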