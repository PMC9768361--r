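#' @useDynLib mucorec, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois sd cor
#' @importFrom utils head read.csv write.csv
#' @importFrom grDevices rgb2hsv
"_PACKAGE"

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Luma (grayscale) of an RGB array
#' @param img numeric array `H x W x 3` with values in `[0, 1]`.
#' @return numeric `H x W` matrix.
#' @keywords internal
luma <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' One-hot encode a class map
#'
#' @param cm integer matrix of class labels in `0:(num_classes-1)`.
#' @param num_classes number of classes.
#' @return numeric array `H x W x num_classes` with a single 1 per pixel.
#' @export
one_hot <- function(cm, num_classes = 3L) {
  stopifnot(is.matrix(cm))
  y <- array(0, c(dim(cm), num_classes))
  for (k in seq_len(num_classes)) {
    y[, , k] <- as.numeric(cm == (k - 1L))
  }
  y
}

# Internal: is x an H x W x 3 RGB array?
is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

# Ensure an image batch axis: H x W x C -> H x W x C x 1
as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}
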