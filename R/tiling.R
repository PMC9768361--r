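# Slide tiling and reassembly.
#
# Slides (and their class maps) are split into fixed-size square tiles on a
# stride grid; the slide is zero-padded on the right/bottom so every tile is
# full size, and stitching crops the padding back off. Coordinates are
# 0-based (x, y) = (column, row) offsets of each tile's top-left corner.

grid_starts <- function(extent, tile_size, stride) {
  n <- if (extent <= tile_size) 1L else as.integer(ceiling((extent - tile_size) / stride)) + 1L
  (seq_len(n) - 1L) * stride
}

pad_extent <- function(extent, tile_size, stride) {
  starts <- grid_starts(extent, tile_size, stride)
  max(starts) + tile_size
}

#' Split a slide into fixed-size tiles
#'
#' @param slide an RGB array (`H x W x 3`) or a class-map matrix (`H x W`).
#' @param tile_size tile height/width in pixels (512 at 10x magnification
#'   for full-scale slides).
#' @param stride grid step; must satisfy `1 <= stride <= tile_size`
#'   (a larger stride would leave gaps). `stride == tile_size` gives a
#'   disjoint cover.
#' @param slide_id identifier recorded in the manifest.
#' @param blank_filter when `TRUE`, each tile is tested with [is_blank()]
#'   and flagged in the manifest (tiles are kept; filtering is a
#'   downstream choice applied to training and/or testing splits).
#' @param saturation_thresh,tissue_frac_thresh thresholds for [is_blank()].
#' @return a `tile_set`: list with `tiles` (list of tile pixel arrays in
#'   row-major grid order), `manifest` (data frame with `slide_id`, `x`,
#'   `y`, `is_blank`, `path`), `slide_shape`, `padded_shape`, `tile_size`,
#'   `stride`.
#' @export
tile_slide <- function(slide, tile_size = 512L, stride = tile_size,
                       slide_id = "slide", blank_filter = FALSE,
                       saturation_thresh = 0.07, tissue_frac_thresh = 0.05) {
  tile_size <- as.integer(tile_size)
  stride <- as.integer(stride)
  if (is.null(dim(slide)) || any(dim(slide)[1:2] < 1L)) stop("empty slide image")
  if (tile_size < 1L) stop("tile_size must be >= 1")
  if (stride < 1L || stride > tile_size) {
    stop("stride must lie in [1, tile_size]; stride ", stride, " > tile ",
         tile_size, " would lose pixels in the gaps")
  }
  d <- dim(slide)
  H <- d[1]; W <- d[2]
  is_img <- length(d) == 3L
  ys <- grid_starts(H, tile_size, stride)
  xs <- grid_starts(W, tile_size, stride)
  padded <- c(max(ys) + tile_size, max(xs) + tile_size)
  if (is_img) {
    canvas <- array(0, c(padded, d[3]))
    canvas[seq_len(H), seq_len(W), ] <- slide
  } else {
    canvas <- matrix(if (is.integer(slide)) 0L else 0, padded[1], padded[2])
    canvas[seq_len(H), seq_len(W)] <- slide
  }
  tiles <- vector("list", length(ys) * length(xs))
  rows <- vector("list", length(tiles))
  k <- 0L
  for (y in ys) {       # row-major: sweep a row of tiles, then the next row
    for (x in xs) {
      k <- k + 1L
      tile <- if (is_img) {
        canvas[y + seq_len(tile_size), x + seq_len(tile_size), , drop = FALSE]
      } else {
        canvas[y + seq_len(tile_size), x + seq_len(tile_size), drop = FALSE]
      }
      blank <- if (blank_filter && is_img) {
        is_blank(tile, saturation_thresh, tissue_frac_thresh)
      } else {
        NA
      }
      tiles[[k]] <- tile
      rows[[k]] <- data.frame(slide_id = slide_id, x = x, y = y,
                              is_blank = blank, path = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(tiles = tiles, manifest = do.call(rbind, rows),
                 slide_shape = c(H, W), padded_shape = padded,
                 tile_size = tile_size, stride = stride),
            class = "tile_set")
}

#' Blank-tile detector
#'
#' A tile is blank when it carries (almost) no tissue. Tissue is detected
#' by HSV saturation: stained tissue is strongly colored while slide glass
#' is near-white (and scanner dropouts near-black), both with saturation
#' approximately 0. The tile is blank iff the fraction of pixels with
#' saturation above `saturation_thresh` falls below `tissue_frac_thresh`.
#'
#' @param tile RGB array `H x W x 3` in `[0, 1]`.
#' @param saturation_thresh saturation (0-1) above which a pixel counts as
#'   tissue.
#' @param tissue_frac_thresh minimum tissue fraction for a non-blank tile.
#' @return logical.
#' @export
is_blank <- function(tile, saturation_thresh = 0.07, tissue_frac_thresh = 0.05) {
  if (!is_rgb_array(tile)) stop("tile must be an H x W x 3 RGB array")
  px <- matrix(tile, ncol = 3L)
  s <- rgb2hsv(t(px), maxColorValue = 1)[2L, ]
  mean(s > saturation_thresh) < tissue_frac_thresh
}

#' Reassemble tiles into a slide-level map
#'
#' Places each patch at its recorded origin on the padded canvas and crops
#' back to the original slide shape. Class-map patches overwrite on overlap
#' (last writer wins); probability-map patches (`H x W x K`) are averaged
#' per pixel over all covering tiles before the per-pixel argmax, with
#' exact ties broken toward the lowest class index.
#'
#' @param tiles a `tile_set` whose tiles are class maps / probability maps,
#'   or a plain list of patches.
#' @param origins data frame or matrix with columns `x`, `y` (0-based
#'   offsets); taken from the `tile_set` manifest when `tiles` is one.
#' @param slide_shape `c(H, W)` of the unpadded slide; from the `tile_set`
#'   when available.
#' @return for class-map tiles, an integer `H x W` class map. For
#'   probability tiles, a list with `classmap` and the averaged `probmap`.
#'   Canvas pixels covered by no tile stay class 0 and trigger a warning.
#' @export
stitch_classmaps <- function(tiles, origins = NULL, slide_shape = NULL) {
  if (inherits(tiles, "tile_set")) {
    origins <- tiles$manifest
    slide_shape <- tiles$slide_shape
    tiles <- tiles$tiles
  }
  stopifnot(!is.null(origins), !is.null(slide_shape))
  if (length(tiles) == 0L) stop("no tiles to stitch")
  td <- dim(tiles[[1L]])
  tile_size <- td[1]
  probs <- length(td) == 3L
  if (any(origins$x < 0 | origins$y < 0) ||
      any(origins$y >= slide_shape[1] + tile_size) ||
      any(origins$x >= slide_shape[2] + tile_size)) {
    stop("tile origin outside canvas")
  }
  pad_h <- max(max(origins$y) + tile_size, slide_shape[1])
  pad_w <- max(max(origins$x) + tile_size, slide_shape[2])
  coverage <- matrix(0L, pad_h, pad_w)
  if (probs) {
    K <- td[3]
    acc <- array(0, c(pad_h, pad_w, K))
    for (i in seq_along(tiles)) {
      ri <- origins$y[i] + seq_len(tile_size)
      ci <- origins$x[i] + seq_len(tile_size)
      acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] + tiles[[i]]
      coverage[ri, ci] <- coverage[ri, ci] + 1L
    }
    cov_pos <- pmax(coverage, 1L)
    for (k in seq_len(K)) acc[, , k] <- acc[, , k] / cov_pos
    acc[, , 1L][coverage == 0L] <- 1  # uncovered pixels: class 0
    probmap <- acc[seq_len(slide_shape[1]), seq_len(slide_shape[2]), , drop = FALSE]
    flat <- matrix(probmap, ncol = K)
    cm <- matrix(max.col(flat, ties.method = "first") - 1L,
                 slide_shape[1], slide_shape[2])
    if (any(coverage[seq_len(slide_shape[1]), seq_len(slide_shape[2])] == 0L)) {
      warning("uncovered slide pixels left as class 0")
    }
    return(list(classmap = cm, probmap = probmap))
  }
  canvas <- matrix(0L, pad_h, pad_w)
  for (i in seq_along(tiles)) {
    ri <- origins$y[i] + seq_len(tile_size)
    ci <- origins$x[i] + seq_len(tile_size)
    canvas[ri, ci] <- as.integer(tiles[[i]])
    coverage[ri, ci] <- 1L
  }
  if (any(coverage[seq_len(slide_shape[1]), seq_len(slide_shape[2])] == 0L)) {
    warning("uncovered slide pixels left as class 0")
  }
  canvas[seq_len(slide_shape[1]), seq_len(slide_shape[2]), drop = FALSE]
}

#' Class-presence stratum of a tile
#'
#' @param cm class-map matrix of one tile.
#' @return one of `"normal"`, `"cancerous"`, `"metaplasia"`,
#'   `"cancerous+metaplasia"`.
#' @export
class_presence <- function(cm) {
  has1 <- any(cm == 1L)
  has2 <- any(cm == 2L)
  if (has1 && has2) "cancerous+metaplasia"
  else if (has1) "cancerous"
  else if (has2) "metaplasia"
  else "normal"
}

#' Random oversampling of minority class-presence strata
#'
#' Lesion tiles are far rarer than normal tiles; duplicates of minority
#' strata are drawn with replacement until every stratum matches the
#' majority stratum count. The original manifest rows are all retained
#' (the output is a super-multiset of the input) and the resampling is
#' deterministic given `rng_seed`.
#'
#' @param manifest data frame with a `stratum` column (see
#'   [class_presence()]), e.g. a `tile_set` manifest augmented with strata.
#' @param rng_seed integer seed.
#' @return the manifest with duplicated minority rows appended.
#' @export
oversample <- function(manifest, rng_seed = 1L) {
  if (is.null(manifest) || nrow(manifest) == 0L) stop("empty manifest")
  if (is.null(manifest$stratum)) stop("manifest needs a 'stratum' column")
  counts <- table(manifest$stratum)
  target <- max(counts)
  extra <- list()
  withr::with_seed(rng_seed, {
    for (s in names(counts)) {
      need <- target - counts[[s]]
      if (need > 0L) {
        pool <- which(manifest$stratum == s)
        extra[[s]] <- manifest[sample(pool, need, replace = TRUE), , drop = FALSE]
      }
    }
  })
  out <- rbind(manifest, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}
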