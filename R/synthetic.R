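# Synthetic histology generator.
#
# Emulates the data the pipeline consumes without any real specimens:
# stained-tissue textures (base color + Poisson-scattered darker "nuclei"
# spots + Gaussian noise) for the three mucosa classes, smooth blob-shaped
# lesion regions with pixel-exact paired class maps, and whole synthetic
# cases: a virtual specimen cut into parallel strips at 2-3 mm intervals
# and re-photographed as a macroscopic specimen image.
#
# Class textures are separable by construction: normal mucosa is pale pink
# with sparse nuclei, cancerous tissue is darker and densely nucleated
# (basophilic), intestinal metaplasia is shifted toward blue-purple.

#' Synthetic-slide parameters
#'
#' @param slide_size `c(H, W)` of generated slides in pixels.
#' @param n_lesions integer vector `c(cancerous, metaplasia)`: number of
#'   lesion blobs per class.
#' @param lesion_radius_range blob semi-axis range in pixels.
#' @param textures per-class texture settings; see
#'   [default_class_textures()].
#' @param noise_sd Gaussian pixel noise standard deviation (on `[0, 1]`).
#' @param microns_per_pixel resolution metadata carried through the
#'   pipeline (1.0 corresponds to 10x magnification).
#' @param rng_seed seed; identical seeds give bit-identical slides.
#' @return a `synth_params` list.
#' @export
synth_params <- function(slide_size = c(384L, 512L),
                         n_lesions = c(2L, 2L),
                         lesion_radius_range = c(30, 70),
                         textures = default_class_textures(),
                         noise_sd = 0.02,
                         microns_per_pixel = 1.0,
                         rng_seed = 1L) {
  stopifnot(length(slide_size) == 2L, all(slide_size >= 8L),
            length(n_lesions) == 2L, all(n_lesions >= 0L),
            length(lesion_radius_range) == 2L,
            diff(lesion_radius_range) >= 0, noise_sd >= 0)
  structure(list(slide_size = as.integer(slide_size),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_range = lesion_radius_range,
                 textures = textures, noise_sd = noise_sd,
                 microns_per_pixel = microns_per_pixel,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_params")
}

#' Default per-class texture settings
#'
#' `base` is the background stain color, `spot_rgb` the nuclei color,
#' `spot_density` the expected nuclei per pixel and `spot_radius` their
#' radius in pixels. The three classes differ in mean hue and spot density
#' by margins large enough that the classes remain distinguishable after
#' noise.
#'
#' @return named list with entries `normal`, `cancerous`, `metaplasia`.
#' @export
default_class_textures <- function() {
  list(
    normal = list(base = c(0.94, 0.78, 0.84), spot_rgb = c(0.60, 0.35, 0.55),
                  spot_density = 0.002, spot_radius = 2),
    cancerous = list(base = c(0.55, 0.25, 0.45), spot_rgb = c(0.25, 0.05, 0.25),
                     spot_density = 0.030, spot_radius = 2),
    metaplasia = list(base = c(0.55, 0.60, 0.92), spot_rgb = c(0.20, 0.25, 0.60),
                      spot_density = 0.010, spot_radius = 2)
  )
}

# One full-field texture: base color + Poisson-scattered nuclei + noise.
texture_field <- function(H, W, tex, noise_sd) {
  img <- array(rep(tex$base, each = H * W), c(H, W, 3L))
  n_spots <- rpois(1L, tex$spot_density * H * W)
  if (n_spots > 0L) {
    cx <- runif(n_spots, 1, W)
    cy <- runif(n_spots, 1, H)
    r <- tex$spot_radius
    off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    for (s in seq_len(n_spots)) {
      yy <- round(cy[s]) + off$dy
      xx <- round(cx[s]) + off$dx
      ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      for (ch in 1:3) img[cbind(yy[ok], xx[ok], ch)] <- tex$spot_rgb[ch]
    }
  }
  if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
  clamp01(img)
}

# Membership matrix of one perturbed-ellipse blob on an H x W grid.
# Boundary radius r(theta) = 1 + sum_k a_k sin(k theta + phi_k), k = 2..4,
# in the ellipse's normalized polar coordinates.
blob_mask <- function(H, W, cx, cy, rx, ry, angle_deg, amp = NULL, phase = NULL) {
  if (is.null(amp)) amp <- runif(3, 0, 0.12)
  if (is.null(phase)) phase <- runif(3, 0, 2 * pi)
  g <- expand.grid(y = seq_len(H) - 1, x = seq_len(W) - 1)
  Rinv <- rotmat(-angle_deg)
  u <- (Rinv[1, 1] * (g$x - cx) + Rinv[1, 2] * (g$y - cy)) / rx
  v <- (Rinv[2, 1] * (g$x - cx) + Rinv[2, 2] * (g$y - cy)) / ry
  rho <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  rb <- 1 + amp[1] * sin(2 * th + phase[1]) + amp[2] * sin(3 * th + phase[2]) +
    amp[3] * sin(4 * th + phase[3])
  matrix(rho <= rb, H, W)
}

#' Generate one synthetic annotated slide
#'
#' Fills the slide with normal-mucosa texture, stamps non-overlapping
#' smooth lesion blobs (perturbed ellipses) for the cancerous and
#' intestinal-metaplasia classes and textures each region with its class's
#' appearance. The returned class map is pixel-exact by construction.
#'
#' @param params a [synth_params()].
#' @return list with `image` (`H x W x 3` in `[0, 1]`), `cm` (`H x W`
#'   integer class map) and `microns_per_pixel`.
#' @export
generate_slide <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  withr::with_seed(params$rng_seed, generate_slide_impl(params))
}

generate_slide_impl <- function(params) {
  H <- params$slide_size[1]; W <- params$slide_size[2]
  cm <- matrix(0L, H, W)
  rr <- params$lesion_radius_range
  for (cls in c(1L, 2L)) {
    for (b in seq_len(params$n_lesions[cls])) {
      placed <- FALSE
      for (try in 1:50) {
        rx <- runif(1, rr[1], rr[2])
        ry <- runif(1, rr[1], rr[2])
        ang <- runif(1, 0, 180)
        margin <- max(rx, ry) * 1.15
        if (2 * margin >= min(H, W)) stop("lesion radius too large for slide size")
        cx <- runif(1, margin, W - 1 - margin)
        cy <- runif(1, margin, H - 1 - margin)
        mask <- blob_mask(H, W, cx, cy, rx, ry, ang)
        if (!any(cm[mask] != 0L)) {
          cm[mask] <- cls
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place a class-", cls, " lesion without overlap after 50 tries; ",
             "reduce n_lesions or lesion_radius_range")
      }
    }
  }
  tex <- params$textures
  img <- texture_field(H, W, tex$normal, params$noise_sd)
  for (cls in c(1L, 2L)) {
    if (any(cm == cls)) {
      field <- texture_field(H, W, tex[[cls + 1L]], params$noise_sd)
      sel <- cm == cls
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- field[, , ch][sel]
        img[, , ch] <- plane
      }
    }
  }
  list(image = img, cm = cm, microns_per_pixel = params$microns_per_pixel)
}

#' Generate a patch dataset for desk-scale training experiments
#'
#' Draws independent small slides (patches) with 0-2 lesions per class so
#' all class-presence strata occur, at radii scaled to the patch size.
#'
#' @param n number of patches.
#' @param size patch height/width in pixels.
#' @param rng_seed seed.
#' @param noise_sd texture noise level.
#' @return list of samples, each with `image` and `cm`.
#' @export
generate_patch_dataset <- function(n, size = 128L, rng_seed = 1L, noise_sd = 0.02) {
  withr::with_seed(rng_seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        p <- synth_params(slide_size = c(size, size),
                          n_lesions = c(sample(0:2, 1), sample(0:2, 1)),
                          lesion_radius_range = c(size / 10, size / 5),
                          noise_sd = noise_sd,
                          rng_seed = sample.int(.Machine$integer.max, 1))
        # infeasible blob layouts (no non-overlapping placement) are redrawn
        s <- tryCatch(generate_slide(p), error = function(e) NULL)
        if (!is.null(s)) return(list(image = s$image, cm = s$cm))
      }
    })
  })
}

#' Generate a synthetic ESD case
#'
#' Builds one virtual 2-D specimen (an oval tissue pad with lesion fields),
#' cuts it into `n_sections` parallel vertical strips at a 2-3 mm interval,
#' renders each strip as a section slide (image + class map + tissue mask)
#' and composes the macroscopic specimen photo by drawing every strip at
#' its true position with slight per-section rotation and translation
#' jitter. Both the true layouts (used to draw the photo) and the nominal
#' unjittered layouts (the manifest a user would supply) are returned,
#' together with the ground-truth recovery map for end-to-end testing.
#'
#' @param params a [synth_params()]; `slide_size[1]` sets the specimen
#'   height in pixels and `microns_per_pixel` should be the thumbnail
#'   scale (default 50 microns/px).
#' @param n_sections number of cut sections (>= 1).
#' @param cut_interval_mm cut spacing in millimetres; drawn uniformly from
#'   `[2, 3]` when `NULL`.
#' @param jitter_px,jitter_deg per-section placement jitter bounds.
#' @param microns_per_pixel photo/section resolution.
#' @return a `synthetic_case`: list with `specimen_photo`, `sections`
#'   (each: `image`, `cm`, `tissue`, `layout` nominal, `layout_true`),
#'   `cut_interval_mm`, `truth` (ground-truth recovery class map on the
#'   photo canvas), `specimen_cm` and `specimen_tissue` (the uncut virtual
#'   specimen), `microns_per_pixel`.
#' @export
generate_case <- function(params = synth_params(rng_seed = 1L),
                          n_sections = 6L, cut_interval_mm = NULL,
                          jitter_px = 10, jitter_deg = 3,
                          microns_per_pixel = 50) {
  stopifnot(n_sections >= 1L)
  withr::with_seed(params$rng_seed, {
    if (is.null(cut_interval_mm)) cut_interval_mm <- runif(1, 2, 3)
    stopifnot(cut_interval_mm >= 2, cut_interval_mm <= 3)
    strip_w <- max(8L, round(cut_interval_mm * 1000 / microns_per_pixel))
    H <- params$slide_size[1]
    W <- as.integer(n_sections * strip_w)
    spec_params <- params
    spec_params$slide_size <- c(H, W)
    spec <- generate_slide_impl(spec_params)
    # oval tissue pad: outside is slide glass (white), class 0
    cyx <- c((H - 1) / 2, (W - 1) / 2)
    g <- expand.grid(y = seq_len(H) - 1, x = seq_len(W) - 1)
    tissue <- matrix(((g$y - cyx[1]) / (0.47 * H))^2 +
                       ((g$x - cyx[2]) / (0.49 * W))^2 <= 1, H, W)
    spec$cm[!tissue] <- 0L
    for (ch in 1:3) {
      plane <- spec$image[, , ch]
      plane[!tissue] <- 1
      spec$image[, , ch] <- plane
    }
    margin <- as.integer(ceiling(jitter_px) + 20L)
    photo_h <- H + 2L * margin
    photo_w <- W + 2L * margin
    photo <- array(0.42, c(photo_h, photo_w, 3L))  # cork board
    photo[, , 1] <- 0.72; photo[, , 2] <- 0.55; photo[, , 3] <- 0.42
    sections <- vector("list", n_sections)
    truth <- matrix(0L, photo_h, photo_w)
    claimed <- matrix(FALSE, photo_h, photo_w)  # strip overlaps: lowest index wins
    for (i in seq_len(n_sections)) {
      cols <- ((i - 1L) * strip_w + 1L):(i * strip_w)
      sec_img <- spec$image[, cols, , drop = FALSE]
      sec_cm <- spec$cm[, cols, drop = FALSE]
      sec_tissue <- tissue[, cols, drop = FALSE]
      nominal <- section_layout(i, anchor = c(margin + (i - 1L) * strip_w, margin),
                                rotation = 0, scale = 1)
      true <- section_layout(i,
                             anchor = nominal$anchor + runif(2, -jitter_px, jitter_px),
                             rotation = runif(1, -jitter_deg, jitter_deg),
                             scale = 1)
      # draw strip tissue into the photo at its true placement
      pl <- place_section_values(sec_img, true, c(photo_h, photo_w),
                                 mask = sec_tissue)
      draw <- pl$footprint & !claimed
      for (ch in 1:3) {
        plane <- photo[, , ch]
        plane[draw] <- pl$values[[ch]][draw]
        photo[, , ch] <- plane
      }
      pt <- place_section(sec_cm, true, c(photo_h, photo_w))
      keep <- pt$classes > 0L & !claimed
      truth[keep] <- pt$classes[keep]
      claimed <- claimed | pt$footprint
      sections[[i]] <- list(image = sec_img, cm = sec_cm, tissue = sec_tissue,
                            layout = nominal, layout_true = true)
    }
    structure(list(specimen_photo = photo, sections = sections,
                   cut_interval_mm = cut_interval_mm, truth = truth,
                   specimen_cm = spec$cm, specimen_tissue = tissue,
                   microns_per_pixel = microns_per_pixel),
              class = "synthetic_case")
  })
}
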