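#' Mean-shift filtering parameters
#'
#' Controls the joint spatial-range mean-shift filter used to flatten kernel
#' texture before colour thresholding. `sp` (spatial radius, pixels) and
#' `sr` (colour radius, intensity units) default to 40 and 60, the values
#' balancing kernel smoothness against fruit-edge preservation;
#' `max_pyramid_level = 3` runs the filter coarse-to-fine over that many
#' internal pyramid layers.
#'
#' @param sp spatial window radius, pixels (> 0).
#' @param sr colour window radius, intensity units (> 0).
#' @param max_pyramid_level internal coarse-to-fine pyramid depth (>= 0).
#' @param max_iters maximum mode-seeking iterations per pixel.
#' @param eps colour-movement convergence tolerance (intensity units).
#' @return A `mean_shift_params` list.
#' @export
mean_shift_params <- function(sp = 40, sr = 60, max_pyramid_level = 3,
                              max_iters = 5, eps = 1.0) {
  stopifnot(sp > 0, sr > 0, max_pyramid_level >= 0, max_iters >= 1, eps > 0)
  structure(list(sp = sp, sr = sr, max_pyramid_level = max_pyramid_level,
                 max_iters = max_iters, eps = eps),
            class = "mean_shift_params")
}

#' Mean-shift filtering of a colour image
#'
#' Each pixel seeds a mode search in the joint spatial-colour domain: the
#' window (spatial radius `sp`, colour radius `sr`) is iterated to its local
#' mode and the pixel is replaced by the converged window-mean colour. This
#' removes local similar texture while retaining strong edges, grouping
#' kernel pixels of similar colour. The filter runs coarse-to-fine: the
#' coarsest internal pyramid layer is filtered first and its result, expanded,
#' initialises the colour estimate at the next finer layer.
#'
#' @param img an [rgb_image].
#' @param params a [mean_shift_params] object.
#' @return The filtered [rgb_image].
#' @export
mean_shift_filter <- function(img, params = mean_shift_params()) {
  stopifnot(inherits(params, "mean_shift_params"))
  # build internal pyramid; stop before layers get degenerate
  layers <- list(img)
  for (l in seq_len(params$max_pyramid_level)) {
    d <- dim(unclass(layers[[l]]))[1:2]
    if (any(d < 16)) break
    layers[[l + 1]] <- pyr_down(layers[[l]], 1L)
  }
  init <- NULL
  for (l in rev(seq_along(layers))) {
    x <- unclass(layers[[l]])
    if (is.null(init)) {
      init <- x
    } else {
      # accept the expanded coarse seed only where it is colour-compatible
      # with the pixel itself, so coarse averaging cannot overwrite fine
      # structure that the colour radius would have kept apart
      d2 <- (init[, , 1] - x[, , 1])^2 + (init[, , 2] - x[, , 2])^2 +
            (init[, , 3] - x[, , 3])^2
      far <- d2 > params$sr^2
      for (ch in 1:3) {
        pl <- init[, , ch]
        pl[far] <- x[, , ch][far]
        init[, , ch] <- pl
      }
    }
    # the spatial window shrinks with the layer so it covers the same
    # physical extent at every level
    sp_l <- max(2L, as.integer(round(params$sp / 2^(l - 1))))
    res <- cpp_mean_shift(x[, , 1], x[, , 2], x[, , 3],
                          init[, , 1], init[, , 2], init[, , 3],
                          sp_l, params$sr,
                          as.integer(params$max_iters), params$eps)
    out <- array(c(res$r, res$g, res$b), dim = dim(x))
    if (l > 1L) {
      up <- pyr_up(rgb_image(clamp255(out)), 1L,
                   out_dim = dim(unclass(layers[[l - 1L]]))[1:2])
      init <- unclass(up)
    }
  }
  rgb_image(clamp255(out))
}

# Otsu threshold of 8-bit values: exhaustive maximisation of the
# between-class variance over the 256-bin histogram. Returns the cut c such
# that foreground is `value > c`; NA for a degenerate (single-bin) histogram.
otsu_cut <- function(values) {
  h <- tabulate(pmin(pmax(floor(as.numeric(values)), 0), 255) + 1L,
                nbins = 256L)
  if (sum(h > 0) < 2L) return(NA_real_)
  w0 <- cumsum(h)[1:255]
  w1 <- sum(h) - w0
  s0 <- cumsum(h * (0:255))[1:255]
  m0 <- s0 / w0
  m1 <- (sum(h * (0:255)) - s0) / w1
  bc <- w0 * w1 * (m0 - m1)^2
  bc[w0 == 0 | w1 == 0] <- -Inf
  which.max(bc) - 0.5
}

#' Separate the maize fruit from the background
#'
#' Colour-feature thresholding of the mean-shift-filtered image. Against a
#' blue background the fruit has the lower blue-channel intensity, so a
#' pixel is fruit iff its blue value falls below the cut (the blue histogram
#' of a filtered ear image is clearly bimodal); against a dark background a
#' pixel is fruit iff `max(R, G, B)` exceeds the cut. When no fixed
#' threshold is supplied the Otsu cut of the relevant channel is used.
#'
#' @param filtered an [rgb_image], normally the output of
#'   [mean_shift_filter()].
#' @param mode `"blue"` or `"dark"` background.
#' @param threshold optional fixed cut in `[0, 255]`; default Otsu.
#' @return A [binary_mask] of the fruit region.
#' @export
segment_fruit <- function(filtered, mode = c("blue", "dark"),
                          threshold = NULL) {
  mode <- match.arg(mode)
  stat <- if (mode == "blue") channel(filtered, 3)
          else pmax(channel(filtered, 1), channel(filtered, 2),
                    channel(filtered, 3))
  if (is.null(threshold)) threshold <- otsu_cut(stat)
  if (is.na(threshold)) {
    warning("segment_fruit: degenerate (unimodal) histogram; empty mask")
    return(binary_mask(matrix(0, nrow(stat), ncol(stat))))
  }
  fruit <- if (mode == "blue") stat < threshold else stat > threshold
  binary_mask(fruit * 255)
}

#' Fill holes in a binary mask
#'
#' Every background component (4-connected) not connected to the image
#' border becomes foreground; foreground pixels are never removed. Used to
#' close dark holes inside kernels after fruit segmentation.
#'
#' @param mask a [binary_mask].
#' @return The filled [binary_mask].
#' @export
fill_holes <- function(mask) {
  m <- unclass(mask)
  bg <- matrix(as.integer(m == 0), nrow(m), ncol(m))
  lab <- cpp_label(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0]
  hole <- lab != 0 & !(lab %in% border)
  binary_mask((m != 0 | hole) * 255)
}

#' Remove small foreground components
#'
#' Deletes every 8-connected foreground component whose pixel area is below
#' `min_area`; components at or above the limit are untouched. The default
#' of 20 pixels removes segmentation noise at the working scale.
#'
#' @param mask a [binary_mask].
#' @param min_area minimum component area kept, pixels (>= 1).
#' @return The cleaned [binary_mask].
#' @export
remove_small_areas <- function(mask, min_area = 20) {
  stopifnot(min_area >= 1)
  m <- unclass(mask)
  lab <- cpp_label(matrix(as.integer(m != 0), nrow(m), ncol(m)), 8L)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab != 0], nbins = max(lab))
  keep <- lab != 0 & sizes[pmax(lab, 1L)] >= min_area
  binary_mask(keep * 255)
}
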