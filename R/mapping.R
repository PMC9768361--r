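# Section-to-specimen mapping.
#
# Each histology section is placed back onto the macroscopic specimen
# photograph by a rigid similarity transform (scale, rotation, translation):
# slide pixel (x, y) maps to photo pixel anchor + scale * R(rotation) (x, y),
# with the package-wide coordinate convention of warp.R. Placement is
# rasterized by inverse mapping with nearest-neighbor sampling so class
# labels stay exact. Initial layouts come from a manifest (cut order and
# approximate position); a normalized cross-correlation search refines the
# translation (and optionally rotation) of each strip against the photo.

#' Section layout
#'
#' Rigid placement of one cut section on the specimen photograph.
#'
#' @param section_index cut order (unique within a case).
#' @param anchor `c(x, y)` photo-pixel position of the section's (0, 0)
#'   corner.
#' @param rotation rotation in degrees (positive turns +x toward +y).
#' @param scale specimen-photo pixels per slide pixel (> 0).
#' @return a `section_layout`.
#' @export
section_layout <- function(section_index, anchor, rotation = 0, scale = 1) {
  stopifnot(length(anchor) == 2L, scale > 0)
  structure(list(section_index = as.integer(section_index),
                 anchor = as.numeric(anchor), rotation = as.numeric(rotation),
                 scale = as.numeric(scale)),
            class = "section_layout")
}

# Inverse-map a section raster onto the canvas. Returns, over the canvas,
# the sampled values (list per channel for 3-D input) and a logical
# footprint of pixels that sample inside the section (optionally inside
# `mask`). Used by place_section, the photo renderer and the NCC refiner.
place_section_values <- function(m, layout, canvas_shape, mask = NULL) {
  d <- dim(m)
  H <- d[1]; W <- d[2]
  ch <- if (length(d) == 3L) d[3] else 0L
  corners <- cbind(c(0, 0), c(W - 1, 0), c(0, H - 1), c(W - 1, H - 1))
  R <- rotmat(layout$rotation)
  tc <- layout$scale * (R %*% corners) + layout$anchor
  x0 <- max(0L, floor(min(tc[1, ])) - 1L)
  x1 <- min(canvas_shape[2] - 1L, ceiling(max(tc[1, ])) + 1L)
  y0 <- max(0L, floor(min(tc[2, ])) - 1L)
  y1 <- min(canvas_shape[1] - 1L, ceiling(max(tc[2, ])) + 1L)
  clipped <- min(tc[1, ]) < -0.5 || max(tc[1, ]) > canvas_shape[2] - 0.5 ||
    min(tc[2, ]) < -0.5 || max(tc[2, ]) > canvas_shape[1] - 0.5
  footprint <- matrix(FALSE, canvas_shape[1], canvas_shape[2])
  empty_vals <- if (ch > 0L) {
    lapply(seq_len(ch), function(i) matrix(0, canvas_shape[1], canvas_shape[2]))
  } else {
    matrix(if (is.integer(m)) 0L else 0, canvas_shape[1], canvas_shape[2])
  }
  if (x1 < x0 || y1 < y0) {
    return(list(values = empty_vals, footprint = footprint, clipped = clipped))
  }
  g <- expand.grid(y = y0:y1, x = x0:x1)
  Rinv <- rotmat(-layout$rotation) / layout$scale
  sx <- Rinv[1, 1] * (g$x - layout$anchor[1]) + Rinv[1, 2] * (g$y - layout$anchor[2])
  sy <- Rinv[2, 1] * (g$x - layout$anchor[1]) + Rinv[2, 2] * (g$y - layout$anchor[2])
  xi <- round(sx); yi <- round(sy)
  inside <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
  if (!is.null(mask)) {
    ok <- inside
    ok[inside] <- mask[cbind(yi[inside] + 1, xi[inside] + 1)]
    inside <- ok
  }
  rows <- g$y + 1L; cols <- g$x + 1L
  footprint[cbind(rows[inside], cols[inside])] <- TRUE
  vals <- empty_vals
  src <- cbind(yi[inside] + 1, xi[inside] + 1)
  dst <- cbind(rows[inside], cols[inside])
  if (ch > 0L) {
    for (i in seq_len(ch)) vals[[i]][dst] <- m[, , i][src]
  } else {
    vals[dst] <- m[src]
  }
  list(values = vals, footprint = footprint, clipped = clipped)
}

#' Place one section's class map on the specimen photo canvas
#'
#' Applies the layout's similarity transform with nearest-neighbor
#' resampling. Strips extending beyond the canvas are clipped with a
#' warning.
#'
#' @param cm section class map (`H x W` integer).
#' @param layout a [section_layout()].
#' @param canvas_shape `c(H, W)` of the specimen photo.
#' @return list with `classes` (canvas-sized integer map, 0 outside the
#'   strip), `footprint` (logical canvas mask of the transformed strip)
#'   and `clipped`.
#' @export
place_section <- function(cm, layout, canvas_shape) {
  stopifnot(is.matrix(cm), inherits(layout, "section_layout"))
  pl <- place_section_values(cm, layout, canvas_shape)
  if (pl$clipped) warning("section ", layout$section_index,
                          " extends beyond the photo canvas; clipped")
  classes <- pl$values
  classes[!pl$footprint] <- 0L
  storage.mode(classes) <- "integer"
  list(classes = classes, footprint = pl$footprint, clipped = pl$clipped)
}

#' Refine a section layout by normalized cross-correlation
#'
#' Renders the section at the initial layout and searches an integer
#' translation window (and a coarse rotation grid) for the placement
#' maximizing the Pearson correlation between the transformed section's
#' luminance and the underlying photo region. The returned layout never
#' scores below the initial one; a flat or weak correlation surface
#' (featureless strip, peak below `min_score`) returns the initial layout
#' flagged low-confidence.
#'
#' @param slide_image section RGB image.
#' @param layout initial [section_layout()] (from the manifest; assumed
#'   within the search window of the true placement).
#' @param specimen_photo photo RGB array.
#' @param search_window half-width of the translation search in photo px.
#' @param rotations rotation offsets (degrees) to scan.
#' @param mask optional logical tissue mask of the section; only masked
#'   pixels enter the correlation.
#' @param min_score minimum acceptable correlation peak.
#' @return the refined `section_layout`, with attributes `score` and
#'   `low_confidence`.
#' @export
refine_layout <- function(slide_image, layout, specimen_photo,
                          search_window = 15L, rotations = seq(-4, 4, by = 1),
                          mask = NULL, min_score = 0.2) {
  photo_l <- luma(specimen_photo)
  ph <- nrow(photo_l); pw <- ncol(photo_l)
  slide_l <- luma(slide_image)
  sw <- as.integer(search_window)
  best <- list(score = -Inf, dx = 0L, dy = 0L, rot = 0)
  for (rot in rotations) {
    lay_r <- layout
    lay_r$rotation <- layout$rotation + rot
    pl <- place_section_values(slide_l, lay_r, c(ph, pw), mask = mask)
    fp <- which(pl$footprint)
    if (length(fp) < 16L) next
    rows <- ((fp - 1L) %% ph) + 1L
    cols <- ((fp - 1L) %/% ph) + 1L
    interior <- rows > sw & rows <= ph - sw & cols > sw & cols <= pw - sw
    fp <- fp[interior]
    if (length(fp) < 16L) next
    a <- pl$values[fp]
    if (sd(a) == 0) next  # featureless: flat correlation surface
    for (dx in -sw:sw) {
      base <- fp + as.integer(dx) * ph
      for (dy in -sw:sw) {
        b <- photo_l[base + as.integer(dy)]
        sc <- if (sd(b) == 0) -Inf else cor(a, b)
        better <- sc > best$score + 1e-12 ||
          (abs(sc - best$score) <= 1e-12 &&
             dx^2 + dy^2 + rot^2 < best$dx^2 + best$dy^2 + best$rot^2)
        if (better) best <- list(score = sc, dx = dx, dy = dy, rot = rot)
      }
    }
  }
  if (!is.finite(best$score) || best$score < min_score) {
    attr(layout, "score") <- if (is.finite(best$score)) best$score else NA_real_
    attr(layout, "low_confidence") <- TRUE
    return(layout)
  }
  out <- layout
  out$anchor <- layout$anchor + c(best$dx, best$dy)
  out$rotation <- layout$rotation + best$rot
  attr(out, "score") <- best$score
  attr(out, "low_confidence") <- FALSE
  out
}

#' Build the mucosal recovery map
#'
#' Composites every section's lesion annotation onto the specimen
#' photograph. Sections are placed in cut order; where transformed strips
#' overlap, the lower section index wins and the overlap area is recorded.
#' The result carries an RGBA overlay (opaque scheme colors over lesion
#' pixels, transparent elsewhere), a per-pixel provenance map, a flattened
#' composite for viewing and a per-class area summary.
#'
#' @param sections list of sections, each a list with `cm` (class map) and
#'   `layout` (a [section_layout()]); e.g. the `sections` of a
#'   [generate_case()] (nominal or refined layouts).
#' @param specimen_photo photo RGB array.
#' @param scheme annotation [color_scheme()].
#' @param microns_per_pixel photo resolution; when `NULL`, areas are
#'   reported in pixels only, with a warning.
#' @return a `recovery_map`: list with `overlay` (`H x W x 4` RGBA),
#'   `classmap` (canvas-level recovered class map), `provenance` (integer
#'   matrix; 0 = no section), `composite` (RGB), `summary` (per-class
#'   data frame), `section_presence` (section x class table),
#'   `overlap_px`.
#' @export
build_recovery_map <- function(sections, specimen_photo,
                               scheme = default_color_scheme(),
                               microns_per_pixel = NULL) {
  idx <- vapply(sections, function(s) s$layout$section_index, integer(1))
  if (anyDuplicated(idx)) stop("duplicate section_index in layouts")
  cs <- dim(specimen_photo)[1:2]
  classes <- matrix(0L, cs[1], cs[2])
  provenance <- matrix(0L, cs[1], cs[2])
  overlap_px <- 0L
  presence <- list()
  for (s in sections[order(idx)]) {
    pl <- place_section(s$cm, s$layout, cs)
    free <- provenance == 0L
    overlap_px <- overlap_px + sum(pl$footprint & !free)
    claim <- pl$footprint & free
    provenance[claim] <- s$layout$section_index
    classes[claim] <- pl$classes[claim]
    presence[[length(presence) + 1L]] <-
      data.frame(section_index = s$layout$section_index,
                 has_cancerous = any(pl$classes == 1L),
                 has_metaplasia = any(pl$classes == 2L))
  }
  overlay <- array(0, c(cs, 4L))
  lesion <- classes > 0L
  col_idx <- classes + 1L
  for (ch in 1:3) {
    plane <- overlay[, , ch]
    plane[lesion] <- scheme[col_idx[lesion], ch] / 255
    overlay[, , ch] <- plane
  }
  alpha <- overlay[, , 4L]
  alpha[lesion] <- 1
  overlay[, , 4L] <- alpha
  composite <- specimen_photo
  blend <- 0.55
  for (ch in 1:3) {
    plane <- composite[, , ch]
    plane[lesion] <- (1 - blend) * plane[lesion] + blend * overlay[, , ch][lesion]
    composite[, , ch] <- plane
  }
  area_px <- c(cancerous = sum(classes == 1L), metaplasia = sum(classes == 2L))
  if (is.null(microns_per_pixel)) {
    warning("no microns_per_pixel supplied; areas reported in pixels only")
    area_mm2 <- c(NA_real_, NA_real_)
  } else {
    area_mm2 <- area_px * (microns_per_pixel / 1000)^2
  }
  summary <- data.frame(class = names(area_px), area_px = as.integer(area_px),
                        area_mm2 = as.numeric(area_mm2))
  structure(list(overlay = overlay, classmap = classes, provenance = provenance,
                 composite = composite, summary = summary,
                 section_presence = do.call(rbind, presence),
                 overlap_px = overlap_px),
            class = "recovery_map")
}

#' @export
print.recovery_map <- function(x, ...) {
  cat("<recovery_map>", nrow(x$section_presence), "sections;",
      x$summary$area_px[1], "cancerous px,", x$summary$area_px[2],
      "metaplasia px; overlap", x$overlap_px, "px\n")
  invisible(x)
}
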