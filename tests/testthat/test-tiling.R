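test_that("tile grids cover the padded slide exactly once", {
  # exact division: 1024 x 1536 into 512-tiles -> 2 x 3 grid
  cm <- random_classmap(1024, 1536, seed = 1)
  ts <- tile_slide(cm, 512L, 512L)
  expect_equal(nrow(ts$manifest), 6L)
  expect_setequal(unique(ts$manifest$y), c(0L, 512L))
  expect_setequal(unique(ts$manifest$x), c(0L, 512L, 1024L))

  # non-divisible extent is padded right/bottom to full tiles
  cm <- random_classmap(600, 1100, seed = 2)
  ts <- tile_slide(cm, 512L, 512L)
  expect_equal(ts$padded_shape, c(1024L, 1536L))
  expect_equal(nrow(ts$manifest), 6L)

  # identity tiling
  ts1 <- tile_slide(random_classmap(512, 512, seed = 3), 512L, 512L)
  expect_equal(nrow(ts1$manifest), 1L)
  expect_equal(c(ts1$manifest$x, ts1$manifest$y), c(0L, 0L))

  expect_error(tile_slide(matrix(0L, 0, 4), 8L), "empty")
  expect_error(tile_slide(random_classmap(64, 64), 32L, 48L), "stride")
})

test_that("tile counts match the closed-form grid formula across random geometries", {
  n_tiles <- function(extent, tile, stride) {
    if (extent <= tile) 1L else ceiling((extent - tile) / stride) + 1L
  }
  withr::with_seed(99, {
    for (i in 1:25) {
      H <- sample(10:300, 1)
      W <- sample(10:300, 1)
      tile <- sample(8:64, 1)
      stride <- sample(seq_len(tile), 1)
      ts <- tile_slide(matrix(0L, H, W), tile, stride)
      expect_equal(nrow(ts$manifest), n_tiles(H, tile, stride) * n_tiles(W, tile, stride))
      # origins are non-negative stride multiples; tiles are full size
      expect_true(all(ts$manifest$x %% stride == 0 & ts$manifest$x >= 0))
      expect_true(all(vapply(ts$tiles, function(t) all(dim(t)[1:2] == tile), logical(1))))
    }
  })
})

test_that("stitching inverts tiling and resolves overlaps as documented", {
  # round trip at stride == tile_size
  cm <- random_classmap(130, 77, seed = 4)
  expect_identical(stitch_classmaps(tile_slide(cm, 32L, 32L)), cm)

  # single tile on an equal-size canvas is the identity
  one <- random_classmap(32, 32, seed = 5)
  expect_identical(stitch_classmaps(list(one), data.frame(x = 0L, y = 0L), c(32L, 32L)), one)

  # overlapping probability tiles are averaged, tie broken to lowest class:
  # two constant tiles for class 1 prob 0.6/0.4 vs 0.4/0.6 average to 0.5/0.5
  # in the overlap, so class 0 (lowest index) wins there
  p1 <- array(0, c(8, 8, 2)); p1[, , 1] <- 0.4; p1[, , 2] <- 0.6
  p2 <- array(0, c(8, 8, 2)); p2[, , 1] <- 0.6; p2[, , 2] <- 0.4
  st <- stitch_classmaps(list(p1, p2), data.frame(x = c(0L, 4L), y = c(0L, 0L)),
                         c(8L, 12L))
  expect_true(all(st$classmap[, 1:4] == 1L))   # only tile 1: class 1 wins
  expect_true(all(st$classmap[, 5:8] == 0L))   # overlap: 0.5/0.5 -> class 0
  expect_true(all(st$classmap[, 9:12] == 0L))  # only tile 2: class 0 wins
  expect_equal(st$probmap[1, 6, ], c(0.5, 0.5))

  # a missing tile leaves class 0 and warns
  ts <- tile_slide(random_classmap(64, 64, seed = 6), 32L, 32L)
  ts$tiles <- ts$tiles[-2]
  ts$manifest <- ts$manifest[-2, ]
  expect_warning(st2 <- stitch_classmaps(ts), "uncovered")
  expect_true(all(st2[1:32, 33:64] == 0L))

  expect_error(stitch_classmaps(list(one), data.frame(x = -5L, y = 0L), c(32L, 32L)),
               "outside")
})

test_that("blank detection keys on HSV saturation and is rotation/flip invariant", {
  expect_true(is_blank(solid_patch(16, 16, c(1, 1, 1))))   # glass
  expect_true(is_blank(solid_patch(16, 16, c(0, 0, 0))))   # scanner dropout
  # saturation of achromatic pixels is exactly 0
  expect_equal(unname(rgb2hsv(0, 0, 0)[2, ]), 0)

  # 50% saturated pink tissue at threshold 0.05 is not blank
  half <- solid_patch(16, 16, c(1, 1, 1))
  half[, 1:8, ] <- rep(c(0.91, 0.55, 0.70), each = 16 * 8)
  expect_false(is_blank(half, tissue_frac_thresh = 0.05))

  withr::with_seed(7, {
    tile <- generate_slide(synth_params(slide_size = c(64, 64), n_lesions = c(0, 0),
                                        rng_seed = 8))$image
    expect_false(is_blank(tile))
    for (tf in list(function(m) m[64:1, , , drop = FALSE],
                    function(m) m[, 64:1, , drop = FALSE],
                    function(m) aperm(m, c(2, 1, 3)))) {
      expect_equal(is_blank(tf(tile)), is_blank(tile))
    }
  })
})

test_that("oversampling balances class-presence strata without deleting rows", {
  manifest <- data.frame(index = 1:115,
                         stratum = rep(c("normal", "cancerous", "metaplasia"),
                                       c(100L, 10L, 5L)))
  out <- oversample(manifest, rng_seed = 3L)
  counts <- table(out$stratum)
  expect_true(all(abs(counts - max(counts)) <= 1))
  expect_equal(unname(counts["normal"]), 100L)
  # super-multiset: every original row survives at least once
  expect_true(all(table(out$index)[as.character(1:115)] >= 1))
  # duplicates only from minority strata
  expect_true(all(out$stratum[duplicated(out)] %in% c("cancerous", "metaplasia")))

  balanced <- data.frame(index = 1:150, stratum = rep(c("a", "b", "c"), each = 50L))
  expect_identical(oversample(balanced, 1L), balanced)
  single <- data.frame(index = 1:7, stratum = "normal")
  expect_identical(oversample(single, 1L), single)
  expect_error(oversample(manifest[0, ], 1L), "empty")
  # deterministic given the seed
  expect_identical(oversample(manifest, 42L), oversample(manifest, 42L))
})
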