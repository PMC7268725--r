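`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Collects every tunable of the kernel-counting pipeline with its default.
#' The printed working parameters are: pyramid working level 2, mean-shift
#' radii `sp = 40` / `sr = 60` (with internal pyramid depth 3), blue
#' background mode, minimum component area 20 px, and Canny hysteresis
#' 80 / 176. Window sizes left `NULL` are derived at run time from the
#' kernel MBR estimate: adaptive block = average MBR length, Gaussian and
#' detection windows = average MBR width (each rounded up to odd).
#'
#' `sp` is interpreted at the original image scale; because the filter runs
#' on the compressed working layer, it is divided by the compression factor
#' (`2^pyramid_level`) so the spatial window covers the same physical
#' extent (disable with `scale_sp = FALSE`).
#'
#' @param pyramid_level working pyramid level (0 = original resolution).
#' @param mean_shift a [mean_shift_params] object.
#' @param scale_sp divide `sp` by the compression factor (see Details).
#' @param background_mode `"blue"` or `"dark"`.
#' @param background_threshold optional fixed fruit threshold.
#' @param min_area small-component removal limit, pixels.
#' @param canny_low,canny_high edge-diagnostic hysteresis thresholds.
#' @param stain_library list of [stain_combination] or a YAML path;
#'   `NULL` loads the shipped library.
#' @param lab_channel_order channel order fed to the OD matrix
#'   (see [color_deconvolve()]).
#' @param blocksize,gaussian_window,local_block optional overrides of the
#'   MBR-derived window sizes (odd pixels).
#' @param merge_factor spurious-point merge radius as a fraction of the
#'   detection block.
#' @param mbr_fallback `c(length, width)` working-scale kernel MBR used
#'   when too few components support the bootstrap estimate.
#' @param hough_r_factor Hough baseline radius bounds as fractions of the
#'   average MBR width.
#' @param rate_rounding rounding convention for correct rates
#'   (see [evaluate_detections()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pyramid_level = 2L,
                            mean_shift = mean_shift_params(),
                            scale_sp = TRUE,
                            background_mode = c("blue", "dark"),
                            background_threshold = NULL,
                            min_area = 20,
                            canny_low = 80, canny_high = 176,
                            stain_library = NULL,
                            lab_channel_order = "Lab",
                            blocksize = NULL,
                            gaussian_window = NULL,
                            local_block = NULL,
                            merge_factor = 0.5,
                            mbr_fallback = c(length = 10, width = 7),
                            hough_r_factor = c(0.3, 0.7),
                            rate_rounding = c("half_up", "truncate")) {
  background_mode <- match.arg(background_mode)
  rate_rounding <- match.arg(rate_rounding)
  stopifnot(pyramid_level >= 0, inherits(mean_shift, "mean_shift_params"),
            min_area >= 1, merge_factor > 0)
  structure(list(pyramid_level = as.integer(pyramid_level),
                 mean_shift = mean_shift, scale_sp = scale_sp,
                 background_mode = background_mode,
                 background_threshold = background_threshold,
                 min_area = min_area,
                 canny_low = canny_low, canny_high = canny_high,
                 stain_library = stain_library,
                 lab_channel_order = lab_channel_order,
                 blocksize = blocksize,
                 gaussian_window = gaussian_window,
                 local_block = local_block,
                 merge_factor = merge_factor,
                 mbr_fallback = mbr_fallback,
                 hough_r_factor = hough_r_factor,
                 rate_rounding = rate_rounding),
            class = "pipeline_config")
}

resolve_library <- function(config) {
  lib <- config$stain_library
  if (is.null(lib)) load_stain_library()
  else if (is.character(lib)) load_stain_library(lib)
  else lib
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Count kernels on a maize ear image
#'
#' Runs the full recognition pipeline: pyramid compression to the working
#' layer, mean-shift filtering, colour-threshold background separation with
#' hole filling and small-area removal, Lab conversion, automatic
#' stain-combination selection, colour-deconvolution grey extraction,
#' kernel-MBR estimation, local adaptive thresholding, Gaussian smoothing,
#' block-scan local-maxima detection, and spurious-point elimination.
#' Recognition points are reported at original-image coordinates. The
#' pipeline contains no randomness: identical input and configuration give
#' identical results.
#'
#' @param img an [rgb_image] (or a file path readable by [read_image()]).
#' @param config a [pipeline_config].
#' @param keep_stages keep intermediate stage images in the result.
#' @return A `kernel_detection` object: `count`, `points` (data.frame of
#'   `row`, `col`, `peak_value` at original scale), `points_working`,
#'   `mbr`, `stain`, `config`, and optionally `stages`.
#' @examples
#' fix <- generate_ear(ear_spec(rows = 5, cols = 4, seed = 1))
#' det <- count_kernels(fix$image)
#' det$count
#' @export
count_kernels <- function(img, config = pipeline_config(),
                          keep_stages = FALSE) {
  if (is.character(img)) img <- read_image(img)
  stopifnot(is_rgb(img), inherits(config, "pipeline_config"))
  d0 <- dim(unclass(img))[1:2]
  lvl <- config$pyramid_level
  scale <- 2^lvl

  work <- with_stage("compress",
    if (lvl >= 1L) pyr_down(img, lvl) else img)

  ms <- config$mean_shift
  if (config$scale_sp && lvl >= 1L)
    ms$sp <- max(2, round(ms$sp / scale))
  filtered <- with_stage("mean_shift", mean_shift_filter(work, ms))

  fruit <- with_stage("background", {
    f <- segment_fruit(filtered, config$background_mode,
                       config$background_threshold)
    remove_small_areas(fill_holes(f), config$min_area)
  })

  empty <- structure(list(count = 0L,
                          points = data.frame(row = numeric(0),
                                              col = numeric(0),
                                              peak_value = numeric(0)),
                          points_working = NULL, mbr = NULL, stain = NULL,
                          config = config, dim = d0),
                     class = "kernel_detection")
  if (!any(unclass(fruit) != 0)) return(empty)

  lab <- with_stage("lab", rgb_to_lab(filtered))
  combo <- with_stage("stain_selection",
    select_stain_combination(lab, fruit, resolve_library(config)))
  gray <- with_stage("deconvolve", {
    maps <- color_deconvolve(lab, build_od_matrix(combo),
                             config$lab_channel_order)
    extract_gray(maps, combo)
  })

  mbr <- with_stage("mbr",
    estimate_kernel_mbr(gray, fruit, min_area = config$min_area,
                        fallback = config$mbr_fallback))
  blocksize <- config$blocksize %||% round_odd(mbr$avg_mbr_length)
  bin <- with_stage("adaptive_threshold", {
    b <- adaptive_threshold(gray, blocksize, fruit)
    # the same small-area rule used on the fruit mask also cleans the
    # kernel binary: speckle blobs below the noise floor would otherwise
    # survive smoothing as weak spurious peaks
    remove_small_areas(b, config$min_area)
  })

  nwin <- config$gaussian_window %||% round_odd(mbr$avg_mbr_width)
  lblk <- config$local_block %||% round_odd(mbr$avg_mbr_width)
  smoothed <- with_stage("smooth", gaussian_smooth(bin, nwin))
  pts <- with_stage("local_maxima", find_local_maxima(smoothed, lblk))
  pts <- with_stage("eliminate_spurious",
    eliminate_spurious(pts, lblk, config$merge_factor))

  orig <- data.frame(row = (pts$row - 0.5) * scale + 0.5,
                     col = (pts$col - 0.5) * scale + 0.5,
                     peak_value = pts$peak_value)
  res <- list(count = nrow(orig), points = orig, points_working = pts,
              mbr = mbr, stain = combo$name, config = config, dim = d0)
  if (keep_stages)
    res$stages <- list(compressed = work, filtered = filtered,
                       fruit = fruit, gray = gray, binary = bin,
                       smoothed = smoothed)
  structure(res, class = "kernel_detection")
}

#' @export
print.kernel_detection <- function(x, ...) {
  cat(sprintf("Maize kernel detection: %d kernels\n", x$count))
  if (!is.null(x$stain))
    cat(sprintf("  stain combination: %s\n", x$stain))
  if (!is.null(x$mbr))
    cat(sprintf("  kernel MBR (working scale): %.1f x %.1f px%s\n",
                x$mbr$avg_mbr_length, x$mbr$avg_mbr_width,
                if (x$mbr$fallback_used) " (fallback)" else ""))
  invisible(x)
}

#' @export
summary.kernel_detection <- function(object, ...) {
  print(object)
  if (object$count > 0) {
    cat("  point coordinate ranges (original scale):\n")
    cat(sprintf("    rows [%.0f, %.0f], cols [%.0f, %.0f]\n",
                min(object$points$row), max(object$points$row),
                min(object$points$col), max(object$points$col)))
  }
  invisible(object)
}

#' @export
as.data.frame.kernel_detection <- function(x, ...) x$points

#' Plot detection points over the ear image
#'
#' @param x a `kernel_detection`.
#' @param img the original [rgb_image] (optional; points alone otherwise).
#' @param cross_col,cross_cex cross colour and size.
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kernel_detection <- function(x, img = NULL, cross_col = "red",
                                  cross_cex = 1, xlab = "col", ylab = "row",
                                  ...) {
  H <- x$dim[1]; W <- x$dim[2]
  graphics::plot(NA, xlim = c(1, W), ylim = c(H, 1), asp = 1,
                 xlab = xlab, ylab = ylab, ...)
  if (!is.null(img))
    graphics::rasterImage(grDevices::as.raster(unclass(img) / 255),
                          1, H, W, 1)
  if (x$count > 0)
    graphics::points(x$points$col, x$points$row, pch = 3,
                     col = cross_col, cex = cross_cex, lwd = 2)
  invisible(x)
}
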