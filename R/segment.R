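#' Estimate the average kernel minimum bounding rectangle
#'
#'
#' Bootstraps a kernel-size estimate from the enhanced grey image: the grey
#' values inside the fruit are Otsu-thresholded, 8-connected components are
#' labelled, components below `min_area` pixels and the largest 5 percent
#' (fused blobs) are dropped, and the mean longer and shorter sides of the
#' axis-aligned minimum bounding rectangles (MBRs) of the remainder are
#' returned. The average MBR length sets the adaptive-threshold block size
#' and the average MBR width the smoothing/detection windows downstream.
#' With fewer than three usable components the configured fallback is
#' returned with a warning.
#'
#' @param gray a [gray_image] (enhanced grey map).
#' @param fruit a [binary_mask] of the fruit region.
#' @param min_area smallest component area used, pixels.
#' @param drop_top fraction of largest components dropped as fused blobs.
#' @param fallback `c(length, width)` used when too few components exist.
#' @return A `kernel_size_estimate` list: `avg_mbr_length`, `avg_mbr_width`,
#'   `n_components`, `fallback_used`.
#' @export
estimate_kernel_mbr <- function(gray, fruit, min_area = 20, drop_top = 0.05,
                                fallback = c(length = 10, width = 7)) {
  g <- unclass(gray)
  sel <- unclass(fruit) != 0
  fb <- structure(list(avg_mbr_length = unname(fallback[1]),
                       avg_mbr_width = unname(fallback[2]),
                       n_components = 0L, fallback_used = TRUE),
                  class = "kernel_size_estimate")
  if (!any(sel)) {
    warning("estimate_kernel_mbr: empty fruit mask; using fallback")
    return(fb)
  }
  thr <- otsu_cut(g[sel])
  if (is.na(thr)) {
    warning("estimate_kernel_mbr: degenerate grey histogram; using fallback")
    return(fb)
  }
  bin <- matrix(as.integer(g > thr & sel), nrow(g), ncol(g))
  lab <- cpp_label(bin, 8L)
  n <- max(lab)
  if (n > 0L) {
    sizes <- tabulate(lab[lab != 0], nbins = n)
    ids <- which(sizes >= min_area)
    if (length(ids) > 0L) {
      ord <- ids[order(sizes[ids])]
      ids <- ord[seq_len(max(1L, length(ord) - floor(length(ord) * drop_top)))]
    }
  } else ids <- integer(0)
  if (length(ids) < 3L) {
    warning("estimate_kernel_mbr: fewer than 3 usable components; ",
            "using fallback")
    return(fb)
  }
  dims <- t(vapply(ids, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    c(diff(range(w[, 1])) + 1, diff(range(w[, 2])) + 1)
  }, numeric(2)))
  longer <- pmax(dims[, 1], dims[, 2])
  shorter <- pmin(dims[, 1], dims[, 2])
  structure(list(avg_mbr_length = mean(longer),
                 avg_mbr_width = mean(shorter),
                 n_components = length(ids), fallback_used = FALSE),
            class = "kernel_size_estimate")
}

#' @export
print.kernel_size_estimate <- function(x, ...) {
  cat(sprintf("<kernel MBR estimate: length %.1f px, width %.1f px (%d components%s)>\n",
              x$avg_mbr_length, x$avg_mbr_width, x$n_components,
              if (x$fallback_used) ", fallback" else ""))
  invisible(x)
}

# Windowed mean with replicate-edge padding via an integral image.
box_mean <- function(m, blocksize) {
  r <- (blocksize - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  p <- m[pmin(pmax(seq_len(H + 2 * r) - r, 1L), H),
         pmin(pmax(seq_len(W + 2 * r) - r, 1L), W), drop = FALSE]
  S <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  S <- rbind(0, cbind(0, t(S)))
  i1 <- seq_len(H); i2 <- i1 + blocksize - 1L
  j1 <- seq_len(W); j2 <- j1 + blocksize - 1L
  (S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
     S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]) / blocksize^2
}

#' Local adaptive mean thresholding
#'
#' Each pixel `c(i, j)` is compared against its own threshold `M(i, j)`, the
#' mean grey value of the `blocksize x blocksize` block centred on it
#' (replicate-edge padding): pixels strictly greater than their block mean
#' become foreground (255), all others background (0). Because the mean
#' shifts with any global offset, the output is exactly invariant under
#' uniform illumination changes, which is what lets it segment kernels under
#' uneven lighting where a single global cut fails. The block size should be
#' the average kernel MBR length (see [estimate_kernel_mbr()]): too small a
#' block yields noise, an oversized one loses edge information.
#'
#' @param gray a [gray_image].
#' @param blocksize odd window side, `>= 3`, at most the smaller image side.
#' @param fruit optional [binary_mask]; pixels outside it are forced to 0.
#' @return A [binary_mask].
#' @export
adaptive_threshold <- function(gray, blocksize, fruit = NULL) {
  stopifnot(blocksize >= 3, blocksize %% 2 == 1)
  g <- unclass(gray)
  if (blocksize > min(dim(g)))
    stop("adaptive_threshold: blocksize larger than image")
  out <- (g > box_mean(g, as.integer(blocksize))) * 255
  if (!is.null(fruit)) out[unclass(fruit) == 0] <- 0
  binary_mask(out)
}

#' Global Otsu thresholding (negative control)
#'
#' A single global threshold maximising the between-class variance of the
#' within-fruit grey histogram. Under uneven illumination this
#' under-segments touching kernels; it is kept as the baseline against
#' which [adaptive_threshold()] is compared.
#'
#' @param gray a [gray_image].
#' @param fruit optional [binary_mask] restricting the histogram and output.
#' @return A [binary_mask].
#' @export
otsu_threshold <- function(gray, fruit = NULL) {
  g <- unclass(gray)
  sel <- if (is.null(fruit)) matrix(TRUE, nrow(g), ncol(g))
         else unclass(fruit) != 0
  thr <- if (any(sel)) otsu_cut(g[sel]) else NA_real_
  if (is.na(thr)) {
    warning("otsu_threshold: degenerate histogram; empty mask")
    return(binary_mask(matrix(0, nrow(g), ncol(g))))
  }
  binary_mask((g > thr & sel) * 255)
}

# Round up to the nearest odd integer >= 3.
round_odd <- function(x) {
  n <- max(3L, as.integer(ceiling(x)))
  if (n %% 2L == 0L) n + 1L else n
}
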