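#' RGB to offset-Lab conversion
#'
#' Converts to the offset-128 Lab encoding used by the edge-enhancement
#' stage, applied per pixel and clamped to `[0, 255]`:
#' \deqn{L = 0.2126 R + 0.7152 G + 0.0722 B}
#' \deqn{a = 1.4749 (0.2213 R - 0.339 G + 0.1177 B) + 128}
#' \deqn{b = 0.6245 (0.1949 R + 0.6057 G - 0.8006 B) + 128}
#' The a and b coefficient rows sum to zero, so any grey input (`R = G = B`)
#' maps to `a = b = 128` exactly: brightness and hue are carried by separate
#' channels, which is what makes the brightness feature extractable.
#'
#' @param img an [rgb_image].
#' @return A `lab_image`: an `H x W x 3` array of (L, a, b) in `[0, 255]`.
#' @export
rgb_to_lab <- function(img) {
  r <- channel(img, 1); g <- channel(img, 2); b <- channel(img, 3)
  L <- 0.2126 * r + 0.7152 * g + 0.0722 * b
  # a and b written in difference form: algebraically identical to the
  # stated coefficients (0.2213 + 0.1177 = 0.339, 0.1949 + 0.6057 = 0.8006)
  # and exactly zero for grey inputs even in floating point
  a <- 1.4749 * (0.2213 * (r - g) + 0.1177 * (b - g)) + 128
  bb <- 0.6245 * (0.1949 * (r - b) + 0.6057 * (g - b)) + 128
  structure(array(c(clamp255(L), clamp255(a), clamp255(bb)),
                  dim = c(dim(r), 3L)),
            class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lab_image %d x %d>\n", d[1], d[2]))
  invisible(x)
}

#' Stain combinations and the stain library
#'
#' A stain combination names a single optical-density (OD) direction used as
#' a virtual dye for colour-deconvolution edge enhancement, together with
#' the mean (L, a, b) centroid of the image group it serves best (used by
#' [select_stain_combination()]). The shipped library holds the three
#' combinations `methyl green` (0.98003, 0.144316, 0.133146),
#' `hematoxylin GL` (0.644211, 0.716556, 0.266844) and `white` (0, 0, 0);
#' the all-zero `white` vector denotes a pure-brightness absorber and is
#' resolved to the uniform unit vector `(1, 1, 1)/sqrt(3)` when the OD
#' matrix is built (see [build_od_matrix()]).
#'
#' @param name label of the combination.
#' @param vector numeric length-3 OD absorption factors (non-negative).
#' @param lab_centroid optional mean (L, a, b) of the combination's group.
#' @return A `stain_combination` object.
#' @export
stain_combination <- function(name, vector, lab_centroid = NULL) {
  vector <- as.numeric(vector)
  stopifnot(length(vector) == 3L, all(vector >= 0))
  if (!is.null(lab_centroid)) {
    lab_centroid <- as.numeric(lab_centroid)
    stopifnot(length(lab_centroid) == 3L)
  }
  structure(list(name = name, vector = vector, lab_centroid = lab_centroid),
            class = "stain_combination")
}

#' @rdname stain_combination
#' @param path YAML file of `{name, vector, lab_centroid}` entries; the
#'   default is the library shipped with the package.
#' @export
load_stain_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "stain_library.yaml",
                        package = "maizekern", mustWork = TRUE)
  entries <- yaml::read_yaml(path)
  lapply(entries, function(e)
    stain_combination(e$name, unlist(e$vector), unlist(e$lab_centroid)))
}

#' Build the optical-density (OD) matrix and its inverse
#'
#' Completes a single-stain combination to a full 3x3 OD matrix `C` in the
#' Ruifrok residual convention: the supplied vector is normalised to unit
#' Euclidean norm and becomes row 1; row 2 is a unit vector orthogonal to it
#' (component swap/negation); row 3 is the normalised cross product. The
#' all-zero "white" vector is mapped to `(1, 1, 1)/sqrt(3)` (a pure
#' brightness absorber) before completion. Returns `C` together with the
#' colour-deconvolution matrix `D = C^-1`.
#'
#' @param combo a [stain_combination] (or bare length-3 vector).
#' @return A list with matrices `C` (rows = stains, columns = channels) and
#'   `D`, satisfying `C %*% D = I`.
#' @export
build_od_matrix <- function(combo) {
  v <- if (inherits(combo, "stain_combination")) combo$vector
       else as.numeric(combo)
  if (all(v == 0)) v <- c(1, 1, 1)
  v1 <- v / sqrt(sum(v^2))
  v2 <- if (abs(v1[1]) > 1e-12 || abs(v1[2]) > 1e-12) c(-v1[2], v1[1], 0)
        else c(0, -v1[3], v1[2])
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  v3 <- v3 / sqrt(sum(v3^2))
  C <- rbind(v1, v2, v3)
  dimnames(C) <- NULL
  if (abs(det(C)) < 1e-9)
    stop("build_od_matrix: completed stain vectors are linearly dependent")
  D <- solve(C)
  if (max(abs(C %*% D - diag(3))) > 1e-9)
    stop("build_od_matrix: inversion failed")
  list(C = C, D = D)
}

#' Colour deconvolution of a Lab image
#'
#' Separates the image into per-stain density maps under the Lambert-Beer
#' model. Each channel value `v` is mapped to optical density
#' `v' = -ln((v + 1)/256)` (the +1 offset forestalls `ln 0`); the density
#' vector is `R* = solve(t(C)) %*% v'`, i.e. channel ODs are the
#' stain-weighted sum `t(C) %*% R*`; each stain map is rescaled to display
#' range by `v_out = clamp(256 * exp(-R*) - 1)`. A white pixel (255 in all
#' channels) has zero density in every stain and displays as 255.
#'
#' @param lab a `lab_image` from [rgb_to_lab()].
#' @param od an OD matrix pair from [build_od_matrix()].
#' @param channel_order `"Lab"` feeds the (L, a, b) planes to the OD columns
#'   in that order; `"baL"` reverses them (sensitivity switch for the
#'   BGR-display reading of the deconvolution input).
#' @return A list of three [gray_image] stain-density display maps.
#' @export
color_deconvolve <- function(lab, od, channel_order = c("Lab", "baL")) {
  channel_order <- match.arg(channel_order)
  a <- unclass(lab)
  d <- dim(a)
  ord <- if (channel_order == "Lab") 1:3 else 3:1
  V <- rbind(as.vector(a[, , ord[1]]),
             as.vector(a[, , ord[2]]),
             as.vector(a[, , ord[3]]))
  Vp <- -log((V + 1) / 256)
  Rstar <- solve(t(od$C)) %*% Vp
  lapply(1:3, function(s) {
    gray_image(matrix(clamp255(256 * exp(-Rstar[s, ]) - 1), d[1], d[2]))
  })
}

#' Automatic stain-combination selection
#'
#' Computes the mean (L, a, b) over the fruit pixels only and returns the
#' library combination whose stored centroid is nearest in Euclidean
#' distance; ties go to the earlier library entry.
#'
#' @param lab a `lab_image`.
#' @param fruit a [binary_mask] of the fruit region (non-empty).
#' @param library list of [stain_combination] with centroids.
#' @return The selected [stain_combination].
#' @export
select_stain_combination <- function(lab, fruit, library) {
  stopifnot(length(library) >= 1L)
  sel <- unclass(fruit) != 0
  if (!any(sel)) stop("select_stain_combination: empty fruit mask")
  a <- unclass(lab)
  m <- c(mean(a[, , 1][sel]), mean(a[, , 2][sel]), mean(a[, , 3][sel]))
  dists <- vapply(library, function(s) {
    if (is.null(s$lab_centroid))
      stop("select_stain_combination: combination '", s$name,
           "' has no lab_centroid")
    sqrt(sum((m - s$lab_centroid)^2))
  }, numeric(1))
  library[[which.min(dists)]]
}

#' Grey image extraction from stain maps
#'
#' Returns the first stain's density display map -- the "R channel" of the
#' deconvolved display image -- which carries the enhanced kernel-edge
#' contrast used for segmentation.
#'
#' @param stain_maps list of maps from [color_deconvolve()].
#' @param combo the [stain_combination] used (recorded, not consulted).
#' @return A [gray_image].
#' @export
extract_gray <- function(stain_maps, combo = NULL) {
  stain_maps[[1]]
}
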