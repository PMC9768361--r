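# RGB annotation-mask codec.
#
# Annotated slides use a three-color convention: cancerous regions red,
# intestinal-metaplasia regions blue, normal mucosa green. Class maps use
# integer labels 0 = normal (majority/background class), 1 = cancerous,
# 2 = intestinal metaplasia.

#' Annotation color scheme
#'
#' Bijective mapping between the three mucosa classes and mask RGB colors.
#'
#' @param normal,cancerous,metaplasia RGB triples on the 0-255 scale.
#' @return a 3 x 3 integer matrix (rows = classes 0, 1, 2 in order normal,
#'   cancerous, metaplasia; columns = R, G, B), class `color_scheme`.
#' @export
color_scheme <- function(normal = c(0L, 255L, 0L),
                         cancerous = c(255L, 0L, 0L),
                         metaplasia = c(0L, 0L, 255L)) {
  m <- rbind(normal = as.integer(normal), cancerous = as.integer(cancerous),
             metaplasia = as.integer(metaplasia))
  colnames(m) <- c("R", "G", "B")
  if (any(m < 0 | m > 255)) stop("scheme colors must be 8-bit (0-255)")
  if (anyDuplicated(m)) stop("scheme colors must be distinct (class/color bijection)")
  class(m) <- c("color_scheme", class(m))
  m
}

#' Default annotation colors (red / blue / green)
#' @return the standard `color_scheme`: cancerous red, intestinal
#'   metaplasia blue, normal green.
#' @export
default_color_scheme <- function() color_scheme()

#' Decode an RGB annotation mask to a class map
#'
#' Each pixel is assigned the class whose scheme color is nearest in RGB
#' space, provided the distance does not exceed `tolerance`; pixels
#' matching no class within tolerance (e.g. anti-aliased edges of
#' hand-drawn masks) are conservatively assigned class 0 (normal) and
#' counted. Pixel values are quantized to 8 bits before matching, so the
#' rendering round trip is exact even at tolerance 0.
#'
#' @param rgb_image numeric array `H x W x 3` with values in `[0, 1]`.
#' @param scheme a [color_scheme()].
#' @param tolerance maximum Euclidean RGB distance (0-255 scale) for a
#'   color to match a class.
#' @return integer matrix `H x W` with values in `{0, 1, 2}` and attribute
#'   `n_unmatched` (number of off-scheme pixels mapped to class 0). A
#'   warning reports a nonzero tally.
#' @export
rgb_mask_to_classmap <- function(rgb_image, scheme = default_color_scheme(),
                                 tolerance = 0) {
  if (!is_rgb_array(rgb_image)) {
    stop("rgb_image must be an H x W x 3 array")
  }
  if (tolerance < 0) stop("tolerance must be >= 0")
  d <- dim(rgb_image)
  px <- round(matrix(rgb_image, d[1] * d[2], 3) * 255)
  n_class <- nrow(scheme)
  d2 <- matrix(0, nrow(px), n_class)
  for (k in seq_len(n_class)) {
    d2[, k] <- (px[, 1] - scheme[k, 1])^2 + (px[, 2] - scheme[k, 2])^2 +
      (px[, 3] - scheme[k, 3])^2
  }
  nearest <- max.col(-d2, ties.method = "first")
  matched <- d2[cbind(seq_len(nrow(px)), nearest)] <= tolerance^2
  labels <- ifelse(matched, nearest - 1L, 0L)
  n_unmatched <- sum(!matched)
  if (n_unmatched > 0) {
    warning(n_unmatched, " pixel(s) matched no scheme color within tolerance ",
            tolerance, "; assigned to class 0 (normal)")
  }
  cm <- matrix(as.integer(labels), d[1], d[2])
  attr(cm, "n_unmatched") <- n_unmatched
  cm
}

#' Render a class map as an RGB annotation mask
#'
#' Emits exact scheme colors; `rgb_mask_to_classmap(classmap_to_rgb(cm))`
#' recovers `cm` identically.
#'
#' @param cm integer matrix with values in `{0, 1, 2}`.
#' @param scheme a [color_scheme()].
#' @return numeric array `H x W x 3` in `[0, 1]`.
#' @export
classmap_to_rgb <- function(cm, scheme = default_color_scheme()) {
  stopifnot(is.matrix(cm))
  if (any(cm < 0 | cm >= nrow(scheme))) {
    stop("class labels must lie in 0:", nrow(scheme) - 1L)
  }
  d <- dim(cm)
  idx <- as.integer(cm) + 1L
  img <- array(0, c(d, 3L))
  for (ch in 1:3) img[, , ch] <- scheme[idx, ch] / 255
  img
}
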