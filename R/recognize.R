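#' Gaussian smoothing of the kernel binary image
#'
#' Step 1 of kernel recognition: the segmented binary image is convolved
#' with an `N x N` Gaussian (`sigma = N/6`, truncated at the window edge,
#' replicate borders) so that intensity grows towards each kernel centre --
#' the maxima to be detected. `N` should be the average kernel MBR width;
#' even or fractional values are rounded up to the next odd integer.
#'
#' @param mask a [binary_mask] (or [gray_image]).
#' @param window window side `N` in pixels (>= 3).
#' @return A [gray_image] of real-valued intensities.
#' @export
gaussian_smooth <- function(mask, window) {
  n <- round_odd(window)
  r <- (n - 1L) %/% 2L
  k <- stats::dnorm(-r:r, sd = n / 6)
  k <- k / sum(k)
  gray_image(clamp255(conv_sep(unclass(mask), k)))
}

#' Find local grayscale maxima (initial recognition points)
#'
#' Step 2: an `L x L` detection block scans the smoothed image line by line;
#' a pixel is an initial kernel recognition point iff its value is positive,
#' no block member exceeds it, and it strictly exceeds at least one block
#' member. On plateaus (ties) every member qualifies under that rule; with
#' `plateau = "centroid"` (default) each 8-connected run of qualifying
#' pixels is reduced to the member nearest its centroid, making the result
#' independent of scan order. `L` should be the average kernel MBR width.
#'
#' @param smoothed a [gray_image] from [gaussian_smooth()].
#' @param block detection block side `L` (>= 3, rounded up to odd).
#' @param plateau `"centroid"` reduces plateau runs; `"all"` returns every
#'   qualifying pixel (used for oracle comparison).
#' @return A data.frame with columns `row`, `col`, `peak_value`.
#' @export
find_local_maxima <- function(smoothed, block, plateau = c("centroid", "all")) {
  plateau <- match.arg(plateau)
  L <- round_odd(block)
  g <- unclass(smoothed)
  cand <- cpp_local_max(g, L)
  if (!any(cand))
    return(data.frame(row = numeric(0), col = numeric(0),
                      peak_value = numeric(0)))
  if (plateau == "all") {
    w <- which(cand, arr.ind = TRUE)
    return(data.frame(row = w[, 1], col = w[, 2], peak_value = g[cand]))
  }
  lab <- cpp_label(matrix(as.integer(cand), nrow(g), ncol(g)), 8L)
  pts <- lapply(seq_len(max(lab)), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    cy <- mean(w[, 1]); cx <- mean(w[, 2])
    i <- which.min((w[, 1] - cy)^2 + (w[, 2] - cx)^2)
    data.frame(row = w[i, 1], col = w[i, 2], peak_value = g[w[i, 1], w[i, 2]])
  })
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  out
}

#' Eliminate spurious kernel recognition points
#'
#' Step 3: several maxima can arise for the same kernel. Points closer than
#' `L/2` (Euclidean) are single-linkage clustered and each cluster collapses
#' to a single point at the intensity-weighted centroid of its members
#' (weights = peak values), carrying the cluster's maximal peak value.
#' Merging repeats until all pairwise distances are at least `L/2`, so the
#' operation is idempotent.
#'
#' @param points data.frame from [find_local_maxima()].
#' @param block the detection block side `L` used upstream.
#' @param merge_factor merge radius as a fraction of `L` (default 0.5).
#' @return A data.frame with columns `row`, `col`, `peak_value`.
#' @export
eliminate_spurious <- function(points, block, merge_factor = 0.5) {
  L <- round_odd(block)
  radius <- merge_factor * L
  pts <- points
  repeat {
    if (nrow(pts) <= 1L) break
    d <- stats::dist(pts[, c("row", "col")])
    if (min(d) >= radius) break
    cl <- stats::cutree(stats::hclust(d, method = "single"),
                        h = radius * (1 - 1e-9))
    pts <- do.call(rbind, lapply(split(pts, cl), function(p) {
      w <- p$peak_value / sum(p$peak_value)
      data.frame(row = sum(w * p$row), col = sum(w * p$col),
                 peak_value = max(p$peak_value))
    }))
    rownames(pts) <- NULL
  }
  pts
}

#' Hough-circle detection baseline
#'
#' The comparison method: a gradient-based circular Hough transform over the
#' fruit region. Canny edge pixels vote along their gradient direction for
#' centres at each candidate radius; accumulator cells above `min_votes`
#' are accepted greedily with non-maximum suppression at `2 * r_min`
#' spacing. Kernels with low contour roundness are characteristically
#' either missed or detected twice by this baseline.
#'
#' @param gray a [gray_image].
#' @param fruit a [binary_mask]; detections outside it are discarded.
#' @param r_min,r_max candidate radius bounds in pixels, `0 < r_min < r_max`.
#' @param min_votes accumulator acceptance threshold; default scales with
#'   the circumference at `r_min`.
#' @param canny_low,canny_high edge-detector hysteresis thresholds.
#' @return A data.frame with columns `row`, `col`, `peak_value` (votes).
#' @export
hough_baseline <- function(gray, fruit, r_min, r_max,
                           min_votes = NULL,
                           canny_low = 80, canny_high = 176) {
  stopifnot(r_min > 0, r_min < r_max)
  g <- unclass(gray)
  H <- nrow(g); W <- ncol(g)
  if (is.null(min_votes)) min_votes <- max(6, round(0.9 * pi * r_min))
  edges <- edge_integrity(gray, canny_low, canny_high)$mask
  e <- unclass(edges) != 0 & unclass(fruit) != 0
  if (!any(e))
    return(data.frame(row = numeric(0), col = numeric(0),
                      peak_value = numeric(0)))
  g1 <- stats::dnorm(-2:2, sd = 1.4); g1 <- g1 / sum(g1)
  sm <- conv_sep(g, g1)
  gx <- conv_sep(sm, c(1, 2, 1), c(1, 0, -1))
  gy <- conv_sep(sm, c(1, 0, -1), c(1, 2, 1))
  mag <- sqrt(gx^2 + gy^2)
  idx <- which(e & mag > 1e-6)
  ei <- ((idx - 1) %% H) + 1
  ej <- ((idx - 1) %/% H) + 1
  uy <- gy[idx] / mag[idx]
  ux <- gx[idx] / mag[idx]
  acc <- matrix(0L, H, W)
  for (r in seq(ceiling(r_min), floor(r_max))) {
    for (s in c(-1, 1)) {
      ci <- round(ei + s * r * uy)
      cj <- round(ej + s * r * ux)
      ok <- ci >= 1 & ci <= H & cj >= 1 & cj <= W
      t <- tabulate((cj[ok] - 1L) * H + ci[ok], nbins = H * W)
      acc <- acc + matrix(t, H, W)
    }
  }
  acc[unclass(fruit) == 0] <- 0L
  cand <- which(acc >= min_votes)
  if (length(cand) == 0L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      peak_value = numeric(0)))
  cand <- cand[order(acc[cand], decreasing = TRUE)]
  ci <- ((cand - 1) %% H) + 1
  cj <- ((cand - 1) %/% H) + 1
  keep_i <- numeric(0); keep_j <- numeric(0); keep_v <- numeric(0)
  min_d2 <- (2 * r_min)^2
  for (k in seq_along(cand)) {
    if (length(keep_i) == 0L ||
        min((keep_i - ci[k])^2 + (keep_j - cj[k])^2) >= min_d2) {
      keep_i <- c(keep_i, ci[k])
      keep_j <- c(keep_j, cj[k])
      keep_v <- c(keep_v, acc[cand[k]])
    }
  }
  data.frame(row = keep_i, col = keep_j, peak_value = keep_v)
}

#' Iterative-erosion separation baseline
#'
#' Applies repeated 3x3 morphological erosion to a binary blob until it
#' splits into two or more 8-connected parts. Corner-to-corner and
#' edge-to-corner touching kernels separate after a few iterations, but an
#' edge-to-edge pair cannot be split before the smaller kernel erodes away
#' entirely -- the failure mode that motivates the local-maxima recognizer.
#'
#' @param mask a [binary_mask] containing one touching blob.
#' @param max_iters iteration cap.
#' @return A list: `split` (logical), `n_parts`, `iterations`.
#' @export
erosion_separation <- function(mask, max_iters = 100) {
  m <- unclass(mask) != 0
  brush <- EBImage::makeBrush(3, shape = "box")
  for (it in seq_len(max_iters)) {
    m <- EBImage::imageData(EBImage::erode(EBImage::Image(m * 1), brush)) > 0
    if (!any(m))
      return(list(split = FALSE, n_parts = 0L, iterations = it))
    n <- max(cpp_label(matrix(as.integer(m), nrow(m), ncol(m)), 8L))
    if (n >= 2L)
      return(list(split = TRUE, n_parts = n, iterations = it))
  }
  list(split = FALSE, n_parts = 1L, iterations = max_iters)
}
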