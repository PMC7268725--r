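#' Count kernels on a single image file and write result artifacts
#'
#' Runs [count_kernels()] on one image and, if `out_dir` is given, writes
#' `\<stem\>.json` (count, points, configuration snapshot), `\<stem\>.csv`
#' (one recognition point per row) and `\<stem\>_overlay.png` (crosses at
#' the points). With `debug_dir` set, every stage intermediate is written
#' as an image.
#'
#' @param image an image path or [rgb_image].
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if needed), or `NULL`.
#' @param debug_dir directory for per-stage intermediates, or `NULL`.
#' @param name output file stem; default derived from the path.
#' @return The `kernel_detection`, invisibly augmented with `files`.
#' @export
run_single <- function(image, config = pipeline_config(), out_dir = NULL,
                       debug_dir = NULL, name = NULL) {
  if (is.character(image)) {
    if (is.null(name))
      name <- sub("\\.[^.]+$", "", basename(image))
    image <- read_image(image)
  }
  if (is.null(name)) name <- "detection"
  t0 <- proc.time()[["elapsed"]]
  det <- count_kernels(image, config, keep_stages = !is.null(debug_dir))
  elapsed <- proc.time()[["elapsed"]] - t0
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jf <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(
      list(image = name, count = det$count, elapsed_s = round(elapsed, 3),
           points = det$points,
           config = config_snapshot(det$config)),
      jf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cf <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(det$points, cf, row.names = FALSE)
    pf <- file.path(out_dir, paste0(name, "_overlay.png"))
    grDevices::png(pf, width = det$dim[2], height = det$dim[1])
    graphics::par(mar = c(0, 0, 0, 0))
    plot(det, img = image, axes = FALSE, xlab = "", ylab = "")
    grDevices::dev.off()
    files <- c(jf, cf, pf)
  }
  if (!is.null(debug_dir) && !is.null(det$stages)) {
    dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in names(det$stages)) {
      f <- file.path(debug_dir, paste0(name, "_", s, ".png"))
      write_image(det$stages[[s]], f)
      files <- c(files, f)
    }
  }
  det$files <- files
  det$elapsed_s <- elapsed
  invisible(det)
}

# Flatten the config into a serialisable snapshot.
config_snapshot <- function(config) {
  cfg <- unclass(config)
  cfg$mean_shift <- unclass(cfg$mean_shift)
  cfg$stain_library <- if (is.character(cfg$stain_library))
    cfg$stain_library else NULL
  cfg
}

#' Batch kernel counting with optional evaluation
#'
#' Processes a directory of images (or a list of [rgb_image]s) and returns
#' one row per image with the kernel count. When per-image ground truth is
#' supplied, matched / false-positive / false-negative counts and the
#' per-image correct rate are added, and the batch average correct rate is
#' the arithmetic mean of the per-image rates (not the pooled-count rate).
#'
#' @param images a directory path, a character vector of files, or a named
#'   list of [rgb_image]s.
#' @param config a [pipeline_config].
#' @param truth optional: a CSV path or data.frame with columns `image`,
#'   `row`, `col` of true centres, or a named list of truth objects as
#'   returned by [generate_ear()].
#' @param match_radius matching radius passed to [evaluate_detections()]
#'   (required when `truth` has no kernel width).
#' @return A data.frame (one row per image) with attribute
#'   `average_correct_rate` when truth was given.
#' @export
run_batch <- function(images, config = pipeline_config(), truth = NULL,
                      match_radius = NULL) {
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.(png|jpe?g|tiff?)$",
                         ignore.case = TRUE, full.names = TRUE)
    if (length(images) == 0L) {
      warning("run_batch: no images found")
      return(data.frame(image = character(0), count = integer(0)))
    }
  }
  nm <- if (!is.null(names(images))) names(images)
        else if (is.character(images))
          sub("\\.[^.]+$", "", basename(images))
        else sprintf("image_%03d", seq_along(images))
  if (is.character(truth) && length(truth) == 1L) {
    tdf <- utils::read.csv(truth)
    truth <- split(tdf[, c("row", "col")], tdf$image)
  }
  rows <- lapply(seq_along(images), function(i) {
    img <- if (is.character(images)) images[[i]] else images[[i]]
    det <- count_kernels(if (is.character(img)) read_image(img) else img,
                         config)
    out <- data.frame(image = nm[i], count = det$count)
    if (!is.null(truth)) {
      tr <- truth[[nm[i]]]
      if (!is.null(tr)) {
        ev <- evaluate_detections(det, tr, match_radius = match_radius,
                                  rounding = config$rate_rounding)
        out$n_truth <- ev$n_truth
        out$n_correct <- ev$n_correct
        out$n_false_positive <- ev$n_false_positive
        out$n_false_negative <- ev$n_false_negative
        out$correct_rate <- ev$correct_rate
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  if (!is.null(res$correct_rate))
    attr(res, "average_correct_rate") <-
      mean(res$correct_rate, na.rm = TRUE)
  res
}
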