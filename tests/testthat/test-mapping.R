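test_that("identity layouts place class maps unchanged and placement is equivariant", {
  cm <- random_classmap(20, 30, seed = 1)
  lay <- section_layout(1L, anchor = c(0, 0), rotation = 0, scale = 1)
  pl <- place_section(cm, lay, c(20L, 30L))
  expect_identical(pl$classes, cm)
  expect_true(all(pl$footprint))

  # shifting the layout shifts the placement rigidly (equivariance)
  lay2 <- section_layout(1L, anchor = c(10, 5), rotation = 0, scale = 1)
  pl2 <- place_section(cm, lay2, c(40L, 60L))
  expect_identical(pl2$classes[6:25, 11:40], cm)

  # 180-degree rotation applied twice about a fixed pivot is the identity
  sq <- random_classmap(15, 15, seed = 2)
  r180 <- function(m) {
    lay <- section_layout(1L, anchor = c(14, 14), rotation = 180, scale = 1)
    place_section(m, lay, c(15L, 15L))$classes
  }
  expect_identical(r180(r180(sq)), sq)
})

test_that("downscaled placement shrinks lesion areas by the squared scale", {
  cm <- matrix(0L, 60, 60)
  cm[15:45, 15:45] <- 1L
  lay <- section_layout(1L, anchor = c(0, 0), rotation = 0, scale = 0.5)
  pl <- place_section(cm, lay, c(40L, 40L))
  expect_equal(sum(pl$classes == 1L), 0.25 * sum(cm == 1L), tolerance = 0.1)
  # area conservation at scale 1 under rotation, within resampling tolerance
  lay_r <- section_layout(1L, anchor = c(40, 5), rotation = 33, scale = 1)
  pl_r <- place_section(cm, lay_r, c(120L, 120L))
  expect_equal(sum(pl_r$classes == 1L), sum(cm == 1L), tolerance = 0.1)
  # strips beyond the canvas clip with a warning
  expect_warning(place_section(cm, section_layout(1L, c(-10, 0)), c(60L, 60L)),
                 "clipped")
})

test_that("cross-correlation refinement recovers known displacements", {
  params <- synth_params(slide_size = c(160, 200), n_lesions = c(1, 1),
                         lesion_radius_range = c(14, 22), rng_seed = 11L)
  case <- generate_case(params, n_sections = 4L)
  for (s in case$sections[c(1, 3)]) {
    ref <- refine_layout(s$image, s$layout, case$specimen_photo, mask = s$tissue)
    err <- sqrt(sum((ref$anchor - s$layout_true$anchor)^2))
    expect_lte(err, 2)
    expect_false(attr(ref, "low_confidence"))
  }
})

test_that("refinement is a fixed point at the optimum and flags featureless strips", {
  params <- synth_params(slide_size = c(120, 160), n_lesions = c(1, 0),
                         lesion_radius_range = c(12, 16), rng_seed = 12L)
  case <- generate_case(params, n_sections = 3L, jitter_px = 0, jitter_deg = 0)
  s <- case$sections[[2]]
  ref <- refine_layout(s$image, s$layout, case$specimen_photo,
                       search_window = 6L, rotations = seq(-2, 2, 1), mask = s$tissue)
  expect_equal(ref$anchor, s$layout$anchor)
  expect_equal(ref$rotation, s$layout$rotation)

  flat <- array(0.5, c(40, 20, 3))
  ref2 <- refine_layout(flat, s$layout, case$specimen_photo, search_window = 4L)
  expect_true(attr(ref2, "low_confidence"))
  expect_equal(ref2$anchor, s$layout$anchor)
})

test_that("the recovery map composites sections deterministically with provenance", {
  params <- synth_params(slide_size = c(140, 180), n_lesions = c(2, 1),
                         lesion_radius_range = c(12, 20), rng_seed = 13L)
  case <- generate_case(params, n_sections = 4L)
  secs <- lapply(case$sections, function(s) list(cm = s$cm, layout = s$layout_true))
  rm <- build_recovery_map(secs, case$specimen_photo, microns_per_pixel = 50)

  expect_equal(dim(rm$overlay), c(dim(case$specimen_photo)[1:2], 4))
  lesion <- rm$classmap > 0L
  # opaque exactly over lesion pixels; every such pixel traces to one section
  expect_true(all(rm$overlay[, , 4][lesion] == 1))
  expect_true(all(rm$overlay[, , 4][!lesion] == 0))
  expect_true(all(rm$provenance[lesion] >= 1L))
  # overlaps resolve to the lower section index: provenance is the first
  # (lowest-index) section whose footprint covers each pixel
  expect_true(all(rm$provenance %in% 0:4))

  # single identity section reduces to place_section
  one <- build_recovery_map(list(list(cm = case$sections[[1]]$cm,
                                      layout = case$sections[[1]]$layout_true)),
                            case$specimen_photo, microns_per_pixel = 50)
  pl <- place_section(case$sections[[1]]$cm, case$sections[[1]]$layout_true,
                      dim(case$specimen_photo)[1:2])
  expect_identical(one$classmap, pl$classes)

  # lesion-free case: fully transparent overlay, zero-area summary
  params0 <- synth_params(slide_size = c(80, 100), n_lesions = c(0, 0), rng_seed = 14L)
  case0 <- generate_case(params0, n_sections = 2L)
  rm0 <- build_recovery_map(lapply(case0$sections,
                                   function(s) list(cm = s$cm, layout = s$layout_true)),
                            case0$specimen_photo, microns_per_pixel = 50)
  expect_true(all(rm0$overlay[, , 4] == 0))
  expect_equal(rm0$summary$area_px, c(0L, 0L))

  dup <- list(list(cm = matrix(0L, 2, 2), layout = section_layout(1L, c(0, 0))),
              list(cm = matrix(0L, 2, 2), layout = section_layout(1L, c(5, 5))))
  expect_error(suppressWarnings(build_recovery_map(dup, case0$specimen_photo)),
               "duplicate")

  # physical areas use the supplied resolution; missing resolution warns
  expect_equal(rm$summary$area_mm2, rm$summary$area_px * (50 / 1000)^2)
  expect_warning(build_recovery_map(secs, case$specimen_photo), "microns_per_pixel")
})

test_that("lesion area is approximately conserved through the whole mapping", {
  params <- synth_params(slide_size = c(140, 180), n_lesions = c(1, 1),
                         lesion_radius_range = c(14, 20), rng_seed = 15L)
  case <- generate_case(params, n_sections = 4L)
  canvas <- dim(case$specimen_photo)[1:2]
  for (s in case$sections) {
    placed <- sum(place_section(s$cm, s$layout_true, canvas)$classes > 0L)
    # similarity transform at scale 1: nearest-neighbor resampling keeps
    # the area within a few percent
    expect_equal(placed, sum(s$cm > 0L) * s$layout_true$scale^2, tolerance = 0.05)
  }
  # composited with the generating layouts, the map reproduces the stored truth
  secs <- lapply(case$sections, function(s) list(cm = s$cm, layout = s$layout_true))
  rm <- suppressWarnings(build_recovery_map(secs, case$specimen_photo))
  expect_gte(mean(rm$classmap == case$truth), 0.999)
})
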