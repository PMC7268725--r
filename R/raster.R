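#' Raster containers
#'
#' Images are stored as plain numeric arrays in row-major photographic
#' orientation: `pixels[i, j]` is the pixel in image row `i` (top to bottom)
#' and column `j` (left to right). Three lightweight classes are used:
#'
#' * `rgb_image`  — an `H x W x 3` array, channel values in `[0, 255]`.
#' * `gray_image` — an `H x W` matrix, values in `[0, 255]`.
#' * `binary_mask` — an `H x W` matrix holding only 0 (background) and
#'   255 (foreground).
#'
#' @param pixels numeric array (`H x W x 3`) or matrix (`H x W`).
#' @return An object of the corresponding class.
#' @examples
#' img <- rgb_image(array(128, dim = c(4, 6, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  pixels <- unclass(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("rgb_image: 'pixels' must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("rgb_image: empty image")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("rgb_image: channel values must lie in [0, 255]")
  structure(pixels, class = "rgb_image")
}

#' @rdname rgb_image
#' @export
gray_image <- function(pixels) {
  pixels <- as.matrix(unclass(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("gray_image: values must lie in [0, 255]")
  structure(pixels, class = "gray_image")
}

#' @rdname rgb_image
#' @export
binary_mask <- function(pixels) {
  pixels <- as.matrix(unclass(pixels))
  if (is.logical(pixels)) pixels <- pixels * 255
  if (!all(pixels %in% c(0, 255)))
    stop("binary_mask: values must be 0 or 255")
  structure(pixels, class = "binary_mask")
}

is_rgb <- function(x) inherits(x, "rgb_image")

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, range [%.0f, %.0f]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%.1f, %.1f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x != 0)))
  invisible(x)
}

channel <- function(img, k) {
  a <- unclass(img)
  matrix(a[, , k], nrow = dim(a)[1])
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Read and write raster images
#'
#' Thin wrappers around [EBImage::readImage()]/[EBImage::writeImage()] that
#' convert between EBImage's `(x, y)` column-major layout on `[0, 1]` and the
#' row-major 8-bit-per-channel arrays used throughout this package. PNG, JPEG
#' and TIFF are supported.
#'
#' @param path file path.
#' @return `read_image()` returns an [rgb_image] (colour input) or
#'   [gray_image] (single-channel input).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  x <- EBImage::readImage(path)
  a <- EBImage::imageData(x) * 255
  if (length(dim(a)) == 2L) return(gray_image(t(a)))
  a <- a[, , 1:3, drop = FALSE]
  rgb_image(aperm(a, c(2, 1, 3)))
}

#' @rdname read_image
#' @param img an [rgb_image], [gray_image] or [binary_mask].
#' @export
write_image <- function(img, path) {
  a <- unclass(img) / 255
  if (length(dim(a)) == 3L) {
    x <- EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
  } else {
    x <- EBImage::Image(t(a))
  }
  EBImage::writeImage(x, path)
  invisible(path)
}

# Separable 2-D convolution with replicate-edge padding. kr runs down rows
# (vertical), kc across columns; both must have odd length. Exact (no FFT),
# so constants are preserved bit-for-bit.
conv_sep <- function(mat, kr, kc = kr) {
  H <- nrow(mat); W <- ncol(mat)
  rr <- (length(kr) - 1L) %/% 2L
  acc <- matrix(0, H, W)
  for (m in seq_along(kr)) {
    idx <- pmin(pmax(seq_len(H) + (m - 1L - rr), 1L), H)
    acc <- acc + kr[m] * mat[idx, , drop = FALSE]
  }
  out <- matrix(0, H, W)
  rc <- (length(kc) - 1L) %/% 2L
  for (m in seq_along(kc)) {
    idx <- pmin(pmax(seq_len(W) + (m - 1L - rc), 1L), W)
    out <- out + kc[m] * acc[, idx, drop = FALSE]
  }
  out
}

# Apply a matrix-valued function to each channel of an image (or to the
# matrix itself for single-channel input), preserving the input class.
map_channels <- function(img, f) {
  if (is_rgb(img)) {
    ch <- lapply(1:3, function(k) f(channel(img, k)))
    rgb_image(array(c(ch[[1]], ch[[2]], ch[[3]]),
                    dim = c(dim(ch[[1]]), 3L)))
  } else {
    gray_image(f(unclass(img)))
  }
}
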