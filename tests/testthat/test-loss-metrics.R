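test_that("soft Jaccard distance matches hand-evaluated closed forms", {
  ones <- rep(1, 10)
  zeros <- rep(0, 10)
  expect_equal(jaccard_distance_loss(ones, ones, smooth = 0), 0)
  expect_equal(jaccard_distance_loss(ones, zeros, smooth = 0), 1)
  # term-by-term: (1*1)/(1+1-1) = 1 and (0.5*0)/(0.5+0-0) = 0 -> 1 - 1/2
  expect_equal(jaccard_distance_loss(c(1, 0.5), c(1, 0), smooth = 0), 0.5,
               tolerance = 1e-12)
  # empty-vs-empty with smoothing contributes a perfect-overlap term
  expect_equal(jaccard_distance_loss(zeros, zeros, smooth = 1), 0)
  expect_error(jaccard_distance_loss(c(1, 2), c(1, 0)), "\\[0, 1\\]")
  expect_error(jaccard_distance_loss(rep(0.5, 3), rep(1, 4)), "shapes differ")
})

test_that("soft Jaccard distance is bounded, symmetric and zero only at binary equality", {
  withr::with_seed(21, {
    for (i in 1:50) {
      p <- runif(32)
      y <- as.numeric(runif(32) > 0.5)
      l <- jaccard_distance_loss(p, y, smooth = 0)
      expect_gte(l, 0)
      expect_lte(l, 1)
      expect_equal(l, jaccard_distance_loss(y, p, smooth = 0))
    }
    yb <- as.numeric(runif(32) > 0.5)
    expect_equal(jaccard_distance_loss(yb, yb, smooth = 0), 0)
  })
})

test_that("cross-entropy matches closed forms and the combined loss is exactly additive", {
  # perfect one-hot prediction
  y <- one_hot(matrix(c(0L, 1L, 2L, 0L), 2, 2), 3L)
  expect_equal(cross_entropy_loss(y, y), 0)
  # single pixel, y = class 0, p = (0.5, 0.25, 0.25) -> -log(0.5)
  p1 <- array(c(0.5, 0.25, 0.25), c(1, 1, 3))
  y1 <- array(c(1, 0, 0), c(1, 1, 3))
  expect_equal(cross_entropy_loss(p1, y1), -log(0.5), tolerance = 1e-12)
  # uniform prediction costs log(3) per pixel for any one-hot reference
  pu <- array(1 / 3, c(4, 4, 3))
  yu <- one_hot(random_classmap(4, 4, seed = 1), 3L)
  expect_equal(cross_entropy_loss(pu, yu), log(3), tolerance = 1e-12)

  lv <- combined_loss(y, y, smooth = 0)
  expect_equal(lv$total, 0)
  # additivity is exact by construction, including on the worked example
  lv2 <- combined_loss(c(1, 0.5), c(1, 0), smooth = 0)
  expect_identical(lv2$total, lv2$jaccard_part + lv2$ce_part)
  expect_equal(lv2$jaccard_part, 0.5)
  expect_equal(lv2$ce_part, cross_entropy_loss(c(1, 0.5), c(1, 0)))
})

test_that("analytic loss gradient matches finite differences", {
  withr::with_seed(33, {
    p <- array(runif(2 * 2 * 3, 0.05, 0.95), c(2, 2, 3))
    y <- one_hot(random_classmap(2, 2), 3L)
    g <- mucorec:::combined_loss_grad(p, y)
    eps <- 1e-6
    for (k in sample(length(p), 6)) {
      pp <- p; pp[k] <- p[k] + eps
      pm <- p; pm[k] <- p[k] - eps
      fd <- (combined_loss(pp, y)$total - combined_loss(pm, y)$total) / (2 * eps)
      expect_equal(g[k], fd, tolerance = 1e-5)
    }
  })
})

test_that("IoU and Dice match pixel-count oracles on worked examples", {
  cm <- random_classmap(12, 12, seed = 2)
  expect_equal(miou(cm, cm), 1.0)
  expect_equal(dice(cm, cm), 1.0)

  # binary case: truth 4 px, pred 6 px, overlap 3 -> IoU 3/7, Dice 6/10
  truth <- matrix(0L, 4, 4); truth[1, 1:4] <- 1L
  pred <- matrix(0L, 4, 4); pred[1, 2:4] <- 1L; pred[2, 2:4] <- 1L
  expect_equal(sum(truth == 1), 4); expect_equal(sum(pred == 1), 6)
  expect_equal(sum(pred == 1 & truth == 1), 3)
  expect_equal(unname(class_iou(pred, truth, 2L)["class1"]), 3 / 7)
  expect_equal(unname(class_dice(pred, truth, 2L)["class1"]), 6 / 10)

  # 2x2 grid: class-0 IoU 1/2, class-1 IoU 2/3 -> MIoU 7/12
  t2 <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  p2 <- matrix(c(0L, 1L, 1L, 1L), 2, 2)
  expect_equal(miou(p2, t2, 2L), 7 / 12, tolerance = 1e-15)

  expect_error(miou(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shapes differ")
  # classes absent from both maps are excluded from the mean
  expect_equal(miou(matrix(0L, 3, 3), matrix(0L, 3, 3), 3L), 1.0)
})

test_that("metrics agree with the double-loop oracle and the Dice/IoU identity holds", {
  withr::with_seed(11, {
    for (i in 1:40) {
      pred <- random_classmap(16, 16)
      truth <- random_classmap(16, 16)
      o <- iou_dice_oracle(pred, truth)
      expect_equal(unname(class_iou(pred, truth)), o$iou, tolerance = 1e-15)
      expect_equal(unname(class_dice(pred, truth)), o$dice, tolerance = 1e-15)
      iou <- class_iou(pred, truth)
      expect_equal(unname(class_dice(pred, truth)), unname(2 * iou / (1 + iou)),
                   tolerance = 1e-15)
      expect_true(all(class_dice(pred, truth) >= iou, na.rm = TRUE))
      # invariance under a simultaneous label permutation
      perm <- sample(0:2)
      pp <- matrix(perm[pred + 1L], 16, 16)
      tp <- matrix(perm[truth + 1L], 16, 16)
      expect_equal(miou(pp, tp), miou(pred, truth))
      expect_equal(dice(pp, tp), dice(pred, truth))
    }
  })
})

test_that("evaluation reports aggregate mean and sd per patch and per group", {
  withr::with_seed(12, {
    truths <- lapply(1:6, function(i) random_classmap(8, 8))
    preds <- lapply(truths, function(t) {
      t[1, 1] <- (t[1, 1] + 1L) %% 3L  # one flipped pixel
      t
    })
    path <- withr::local_tempfile(fileext = ".json")
    rep <- evaluation_report(preds, truths, groups = rep(c("s1", "s2"), each = 3),
                             path = path)
    expect_equal(nrow(rep$per_patch), 6)
    expect_equal(rep$aggregate$miou_mean, mean(rep$per_patch$miou))
    expect_equal(rep$aggregate$miou_sd, sd(rep$per_patch$miou))
    expect_equal(nrow(rep$per_group), 2)
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(js$aggregate$dice_mean, rep$aggregate$dice_mean, tolerance = 1e-12)
  })
})
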