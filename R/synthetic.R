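#' Colourways for synthetic ears
#'
#' Three kernel colour schemes emulating common market classes: `yellow`
#' (dent/flint yellow), `pale` (waxy white) and `red` (red-orange flint).
#' Each defines the kernel crown colour, the shadowed rim/crevice colour
#' seen where kernels meet, and the deep-gap (cob shadow) colour. Brightness
#' is the main feature separating kernel crowns from the crevices between
#' them; the crown-to-rim transition is rendered as a narrow band, so that
#' touching kernels are joined only by a thin darker line -- the narrow
#' colour gradient the enhancement stage widens.
#'
#' @format A named list of lists with entries `kernel`, `rim`, `gap` (RGB).
#' @export
ear_colorways <- list(
  yellow = list(kernel = c(240, 210, 90), rim = c(150, 115, 55),
                gap = c(95, 65, 35)),
  pale   = list(kernel = c(238, 228, 180), rim = c(150, 140, 112),
                gap = c(110, 95, 62)),
  red    = list(kernel = c(220, 120, 70), rim = c(140, 75, 50),
                gap = c(90, 50, 32))
)

#' Specify a synthetic ear fixture
#'
#' Describes an ear-like test image with exact ground truth: a convex ear
#' silhouette on a blue or black background, tiled with a `rows x cols`
#' grid of shaded elliptical kernels (bright crown, desaturated rim) whose
#' sizes jitter around the nominal kernel MBR, optionally with touching
#' pairs of the three contact topologies, a kernel-free bald tip, and a
#' smooth illumination field. All randomness derives from `seed`, so a spec
#' renders bit-identically across runs.
#'
#' @param rows,cols kernel grid dimensions (>= 1).
#' @param kernel_length,kernel_width nominal kernel MBR sides, pixels
#'   (length runs along the ear axis / image rows).
#' @param size_jitter relative axis jitter, in `[0, 0.5)`.
#' @param touching named fractions of kernels involved in touching pairs,
#'   entries `corner_corner`, `edge_corner`, `edge_edge`; total <= 1.
#' @param background `"blue"` or `"black"`.
#' @param illumination list: `mode` one of `"uniform"`,
#'   `"linear_gradient"`, `"highlight"`; `amplitude` intensity units;
#'   `sigma` highlight radius (pixels).
#' @param bald_tip add a kernel-free pale region at the ear apex.
#' @param colorway one of `names(ear_colorways)`.
#' @param color_jitter s.d. of a per-image shift applied to kernel and rim
#'   colours (intensity units).
#' @param noise_sd per-pixel Gaussian noise s.d. (intensity units).
#' @param gap_frac inter-kernel spacing as a fraction of kernel size.
#' @param seed RNG seed (integer).
#' @return An `ear_fixture_spec` list.
#' @export
ear_spec <- function(rows = 6, cols = 5,
                     kernel_length = 40, kernel_width = 28,
                     size_jitter = 0.10,
                     touching = c(corner_corner = 0, edge_corner = 0,
                                  edge_edge = 0),
                     background = c("blue", "black"),
                     illumination = list(mode = "uniform", amplitude = 0,
                                         sigma = NULL),
                     bald_tip = FALSE,
                     colorway = "yellow",
                     color_jitter = 0,
                     noise_sd = 3,
                     gap_frac = 0.25,
                     seed = 1L) {
  background <- match.arg(background)
  stopifnot(rows >= 1, cols >= 1, kernel_length > 0, kernel_width > 0,
            size_jitter >= 0, size_jitter < 0.5,
            colorway %in% names(ear_colorways), gap_frac >= 0)
  touch <- c(corner_corner = 0, edge_corner = 0, edge_edge = 0)
  touch[names(touching)] <- touching
  stopifnot(all(touch >= 0), sum(touch) <= 1)
  if (gap_frac < (1 + size_jitter)^2 - 1)
    stop("ear_spec: grid too dense for the kernel size jitter")
  structure(list(rows = rows, cols = cols,
                 kernel_length = kernel_length, kernel_width = kernel_width,
                 size_jitter = size_jitter, touching = touch,
                 background = background, illumination = illumination,
                 bald_tip = bald_tip, colorway = colorway,
                 color_jitter = color_jitter, noise_sd = noise_sd,
                 gap_frac = gap_frac, seed = as.integer(seed)),
            class = "ear_fixture_spec")
}

# Support radius of an axis-aligned ellipse along a unit direction (dy, dx).
ellipse_radius <- function(ay, ax, dy, dx) 1 / sqrt((dy / ay)^2 + (dx / ax)^2)

#' Render a synthetic ear image with ground truth
#'
#' Deterministically renders the fixture described by an [ear_spec()]. The
#' returned ground truth holds the exact kernel centres (image row/col),
#' per-kernel MBR sides, and the pixel area of the ear region.
#'
#' @param spec an `ear_fixture_spec`.
#' @return A list: `image` (an [rgb_image]) and `truth` (list with
#'   `centres` data.frame, `n_kernels`, `mbr` data.frame, `ear_area`,
#'   `kernel_width`, `kernel_length`).
#' @examples
#' fix <- generate_ear(ear_spec(rows = 5, cols = 4, seed = 7))
#' fix$truth$n_kernels
#' @export
generate_ear <- function(spec) {
  stopifnot(inherits(spec, "ear_fixture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  py <- spec$kernel_length * (1 + spec$gap_frac)
  px <- spec$kernel_width * (1 + spec$gap_frac)
  bald_h <- if (spec$bald_tip) 1.3 * spec$kernel_length else 0
  pad_y <- 0.10 * spec$kernel_length
  pad_x <- 0.12 * spec$kernel_width
  margin <- 18
  grid_h <- spec$rows * py
  grid_w <- spec$cols * px
  H <- ceiling(grid_h + bald_h + 2 * pad_y + 2 * margin)
  W <- ceiling(grid_w + 2 * pad_x + 2 * margin)
  top <- margin + pad_y + bald_h
  left <- margin + pad_x

  n <- spec$rows * spec$cols
  rr <- rep(seq_len(spec$rows), each = spec$cols)
  cc <- rep(seq_len(spec$cols), times = spec$rows)
  cy <- top + (rr - 0.5) * py + stats::runif(n, -0.04, 0.04) * py
  cx <- left + (cc - 0.5) * px + stats::runif(n, -0.04, 0.04) * px
  ay <- spec$kernel_length / 2 *
    (1 + stats::runif(n, -spec$size_jitter, spec$size_jitter))
  ax <- spec$kernel_width / 2 *
    (1 + stats::runif(n, -spec$size_jitter, spec$size_jitter))
  bright <- stats::runif(n, 0.94, 1.06)

  # --- touching pairs: pull selected neighbour pairs into contact ---------
  cell <- function(r, c) (r - 1) * spec$cols + c
  used <- rep(FALSE, n)
  place_pairs <- function(n_pairs, neighbours, factor, lateral = 0) {
    if (n_pairs == 0 || nrow(neighbours) == 0) return(invisible())
    ok <- !used[neighbours[, 1]] & !used[neighbours[, 2]]
    nb <- neighbours[ok, , drop = FALSE]
    if (nrow(nb) == 0) return(invisible())
    pick <- nb[sample(nrow(nb), min(n_pairs, nrow(nb))), , drop = FALSE]
    for (q in seq_len(nrow(pick))) {
      i <- pick[q, 1]; j <- pick[q, 2]
      if (used[i] || used[j]) next
      if (lateral != 0) {
        sh <- lateral * spec$kernel_width * sample(c(-1, 1), 1)
        cx[j] <<- cx[j] + sh
      }
      dy <- cy[j] - cy[i]; dx <- cx[j] - cx[i]
      dd <- sqrt(dy^2 + dx^2); uy <- dy / dd; ux <- dx / dd
      target <- factor * (ellipse_radius(ay[i], ax[i], uy, ux) +
                          ellipse_radius(ay[j], ax[j], uy, ux))
      shift <- (dd - target) / 2
      cy[i] <<- cy[i] + shift * uy; cx[i] <<- cx[i] + shift * ux
      cy[j] <<- cy[j] - shift * uy; cx[j] <<- cx[j] - shift * ux
      used[i] <<- TRUE; used[j] <<- TRUE
    }
    invisible()
  }
  # candidate pairs are pre-matched disjointly, so a touching fraction of 1
  # really does pair every kernel
  horiz <- if (spec$cols >= 2) {
    g <- expand.grid(r = seq_len(spec$rows),
                     c = seq(1, spec$cols - 1, by = 2))
    cbind(cell(g$r, g$c), cell(g$r, g$c + 1))
  } else matrix(0L, 0, 2)
  vert <- if (spec$rows >= 2) {
    g <- expand.grid(r = seq(1, spec$rows - 1, by = 2),
                     c = seq_len(spec$cols))
    cbind(cell(g$r, g$c), cell(g$r + 1, g$c))
  } else matrix(0L, 0, 2)
  diag_nb <- if (spec$rows >= 2 && spec$cols >= 2) {
    g <- expand.grid(r = seq(1, spec$rows - 1, by = 2),
                     c = seq(1, spec$cols - 1, by = 2))
    cbind(cell(g$r, g$c), cell(g$r + 1, g$c + 1))
  } else matrix(0L, 0, 2)
  tp <- spec$touching
  place_pairs(floor(tp["edge_edge"] * n / 2), horiz, factor = 0.68)
  place_pairs(floor(tp["edge_corner"] * n / 2), vert, factor = 0.96,
              lateral = 0.45)
  if (nrow(diag_nb) > 0) {
    place_pairs(floor(tp["corner_corner"] * n / 2), diag_nb, factor = 0.99)
  } else {
    # single-column grids: realise the corner contact by a strong lateral
    # offset of a vertical pair
    place_pairs(floor(tp["corner_corner"] * n / 2), vert, factor = 0.99,
                lateral = 0.6)
  }

  # --- canvas and ear silhouette around the placed kernels ---------------
  # (touching-pair placement can shift kernels, so both the canvas and the
  # silhouette follow the actual kernel bounding box; the silhouette hugs
  # and slightly clips the outer crowns, as edge kernels form the outline
  # of a real ear)
  H <- ceiling(max(cy + ay) + pad_y + margin)
  W <- ceiling(max(cx + ax) + pad_x + margin)
  ymin <- min(cy - ay) - bald_h - pad_y
  ymax <- max(cy + ay) + pad_y
  xmin <- min(cx - ax) - pad_x
  xmax <- max(cx + ax) + pad_x
  ey <- (ymin + ymax) / 2
  ex <- (xmin + xmax) / 2
  eh <- (ymax - ymin) / 2 * 0.99
  ew <- (xmax - xmin) / 2 * 0.93
  Y <- matrix(seq_len(H), H, W)
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  ear <- (abs((Y - ey) / eh))^6 + (abs((X - ex) / ew))^6 <= 1

  # --- per-pixel nearest- and second-nearest-kernel distances ------------
  ndmin <- matrix(Inf, H, W)
  nd2 <- matrix(Inf, H, W)
  who <- matrix(0L, H, W)
  reach <- 1.6
  for (k in seq_len(n)) {
    r0 <- max(1L, floor(cy[k] - reach * ay[k]))
    r1 <- min(H, ceiling(cy[k] + reach * ay[k]))
    c0 <- max(1L, floor(cx[k] - reach * ax[k]))
    c1 <- min(W, ceiling(cx[k] + reach * ax[k]))
    ys <- ((r0:r1 - cy[k]) / ay[k])^2
    xs <- ((c0:c1 - cx[k]) / ax[k])^2
    nd <- sqrt(outer(ys, xs, `+`))
    sub <- ndmin[r0:r1, c0:c1]
    sub2 <- nd2[r0:r1, c0:c1]
    better <- nd < sub
    sub2[better] <- sub[better]
    mid <- !better & nd < sub2
    sub2[mid] <- nd[mid]
    sub[better] <- nd[better]
    ndmin[r0:r1, c0:c1] <- sub
    nd2[r0:r1, c0:c1] <- sub2
    wsub <- who[r0:r1, c0:c1]
    wsub[better] <- k
    who[r0:r1, c0:c1] <- wsub
  }

  # --- colour composition ------------------------------------------------
  cw <- ear_colorways[[spec$colorway]]
  cshift <- stats::rnorm(3, 0, spec$color_jitter)
  kcol <- clamp255(cw$kernel + cshift)
  rcol <- clamp255(cw$rim + cshift)
  gcol <- cw$gap
  bgcol <- if (spec$background == "blue") c(40, 60, 205) else c(18, 18, 18)
  baldcol <- c(208, 190, 152)

  inside <- ndmin <= 1
  # crown shading and crown-to-rim blend (t: 0 at crown, 1 at rim)
  t_rim <- pmin(pmax((ndmin - 0.70) / 0.30, 0), 1)^1.2
  # crease: where two kernels overlap deeply, the groove between them is a
  # narrow band equidistant from both centres; it is drawn in the deep-gap
  # colour with a flat-topped profile so the contact line stays visible
  # after pyramid compression
  crease <- pmax(0, 1 - (abs(nd2 - ndmin) / 0.5)^3)
  crease[ndmin < 0.6 | nd2 > 1.25] <- 0
  shade <- 1 - 0.12 * pmin(ndmin, 1)^2
  bmap <- matrix(1, H, W)
  bmap[inside] <- bright[who[inside]]
  # gap blend just outside kernels (rim colour fading into deep gap)
  t_gap <- pmin(pmax((ndmin - 1) / 0.18, 0), 1)
  chan <- vector("list", 3)
  for (ch in 1:3) {
    m <- matrix(bgcol[ch], H, W)
    m[ear] <- gcol[ch]
    if (spec$bald_tip) m[ear & Y < top - 0.35 * spec$kernel_length] <-
      baldcol[ch]
    kern_v <- (1 - t_rim) * kcol[ch] * shade * bmap + t_rim * rcol[ch]
    kern_v <- (1 - crease) * kern_v + crease * gcol[ch]
    near <- ndmin <= 1 + 0.18 & !inside & ear
    m[near] <- (1 - t_gap[near]) * rcol[ch] + t_gap[near] * gcol[ch]
    m[inside] <- kern_v[inside]
    chan[[ch]] <- m
  }

  img <- array(c(chan[[1]], chan[[2]], chan[[3]]), dim = c(H, W, 3))
  # illumination is multiplicative (reflectance times light field); the
  # field is normalised so `amplitude` is the intensity span realised on a
  # nominally bright (160-unit) surface -- a dark background stays dark
  il <- spec$illumination
  if (!is.null(il$mode) && il$mode == "linear_gradient" && il$amplitude != 0) {
    ramp <- matrix(1 + seq(-il$amplitude / 2, il$amplitude / 2,
                           length.out = W) / 160,
                   H, W, byrow = TRUE)
    img <- img * as.vector(ramp)
  } else if (!is.null(il$mode) && il$mode == "highlight" &&
             il$amplitude != 0) {
    sg <- il$sigma %||% (min(H, W) / 4)
    hy <- stats::runif(1, ey - eh / 2, ey + eh / 2)
    hx <- stats::runif(1, ex - ew / 2, ex + ew / 2)
    bump <- 1 + il$amplitude *
      exp(-((Y - hy)^2 + (X - hx)^2) / (2 * sg^2)) / 160
    img <- img * as.vector(bump)
  }
  img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  img <- clamp255(img)

  truth <- list(centres = data.frame(row = cy, col = cx),
                n_kernels = n,
                mbr = data.frame(length = 2 * ay, width = 2 * ax),
                ear_area = sum(ear),
                kernel_width = spec$kernel_width,
                kernel_length = spec$kernel_length)
  list(image = rgb_image(img), truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render an isolated touching pair
#'
#' A two-kernel fixture of a single touching topology on an ear-coloured
#' pad, used to exercise the separation capability of the recognizer and of
#' the erosion baseline in isolation.
#'
#' @param topology `"corner_corner"`, `"edge_corner"` or `"edge_edge"`.
#' @param kernel_length,kernel_width,colorway,background,noise_sd,seed as
#'   in [ear_spec()].
#' @return As [generate_ear()].
#' @export
generate_touching_pair <- function(topology = c("corner_corner",
                                                "edge_corner", "edge_edge"),
                                   kernel_length = 40, kernel_width = 28,
                                   colorway = "yellow",
                                   background = "blue",
                                   noise_sd = 3, seed = 1L) {
  topology <- match.arg(topology)
  touching <- stats::setNames(c(0, 0, 0),
                              c("corner_corner", "edge_corner", "edge_edge"))
  touching[topology] <- 1
  rows <- if (topology == "edge_edge") 1 else 2
  cols <- if (topology == "edge_edge") 2 else 1
  sp <- ear_spec(rows = rows, cols = cols,
                 kernel_length = kernel_length, kernel_width = kernel_width,
                 size_jitter = 0, touching = touching,
                 background = background, colorway = colorway,
                 noise_sd = noise_sd, seed = seed)
  generate_ear(sp)
}

#' Binary mask of a touching pair (geometry only)
#'
#' The union of the two kernel ellipses of [generate_touching_pair()] as a
#' [binary_mask], for baselines that operate directly on a segmented blob.
#'
#' @inheritParams generate_touching_pair
#' @return A [binary_mask].
#' @export
touching_pair_mask <- function(topology, kernel_length = 40,
                               kernel_width = 28, seed = 1L) {
  fix <- generate_touching_pair(topology, kernel_length = kernel_length,
                                kernel_width = kernel_width,
                                noise_sd = 0, seed = seed)
  tr <- fix$truth
  d <- dim(unclass(fix$image))[1:2]
  Y <- matrix(seq_len(d[1]), d[1], d[2])
  X <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  m <- matrix(FALSE, d[1], d[2])
  for (k in seq_len(tr$n_kernels)) {
    m <- m | (((Y - tr$centres$row[k]) / (tr$mbr$length[k] / 2))^2 +
              ((X - tr$centres$col[k]) / (tr$mbr$width[k] / 2))^2 <= 1)
  }
  binary_mask(m * 255)
}

#' The standard 50-fixture validation suite
#'
#' Fifty ear specs with seeds 1-50 covering 20 to 48 kernels per ear, up to
#' 30 percent of kernels in touching pairs spread over the three contact
#' topologies, linear-gradient illumination of 60 intensity units, and
#' alternating blue (odd seeds) and black (even seeds) backgrounds.
#'
#' @param n number of fixtures (seeds `1:n`).
#' @return A list of `ear_fixture_spec`.
#' @export
standard_suite <- function(n = 50) {
  lapply(seq_len(n), function(i) {
    tf <- ((i * 7) %% 31) / 100          # 0 .. 0.30
    ear_spec(rows = 5 + (i %% 4),        # 5..8
             cols = 4 + (i %% 3),        # 4..6
             touching = c(corner_corner = tf / 3, edge_corner = tf / 3,
                          edge_edge = tf / 3),
             background = if (i %% 2 == 1) "blue" else "black",
             illumination = list(mode = "linear_gradient", amplitude = 60),
             seed = i)
  })
}

round_rate <- function(x, convention = c("half_up", "truncate")) {
  convention <- match.arg(convention)
  if (convention == "half_up") floor(x * 10 + 0.5) / 10 else floor(x * 10) / 10
}

#' Evaluate detections against ground-truth centres
#'
#' Greedy one-to-one matching of detection points to true kernel centres by
#' ascending Euclidean distance; pairs farther apart than `match_radius`
#' never match. Correctly recognized = matched detections; false positives
#' = unmatched detections; false negatives = unmatched truths. The correct
#' rate is `100 * n_correct / n_truth`, reported to one decimal under the
#' chosen rounding convention (conventional half-up by default; `truncate`
#' is also exposed because published tables are ambiguous between the two).
#'
#' @param points data.frame with `row`, `col` (detections), or a
#'   `kernel_detection`.
#' @param truth ground truth from [generate_ear()] (or a data.frame of
#'   centres, or a list with `centres`).
#' @param match_radius maximum matching distance, pixels; default half the
#'   nominal kernel width when the truth carries one.
#' @param rounding `"half_up"` or `"truncate"`.
#' @return An `evaluation_result` list: `n_truth`, `n_correct`,
#'   `n_false_positive`, `n_false_negative`, `correct_rate`.
#' @examples
#' ev <- evaluation_result(n_truth = 204, n_correct = 191,
#'                         n_false_positive = 0)
#' ev$correct_rate  # 93.6
#' @export
evaluate_detections <- function(points, truth, match_radius = NULL,
                                rounding = c("half_up", "truncate")) {
  rounding <- match.arg(rounding)
  if (inherits(points, "kernel_detection")) points <- points$points
  centres <- if (is.data.frame(truth)) truth else truth$centres
  if (is.null(match_radius)) {
    kw <- if (!is.data.frame(truth)) truth$kernel_width else NULL
    if (is.null(kw))
      stop("evaluate_detections: match_radius required")
    match_radius <- 0.5 * kw
  }
  stopifnot(match_radius > 0)
  nt <- nrow(centres)
  if (nt == 0) stop("evaluate_detections: no ground-truth kernels")
  np <- nrow(points)
  matched_p <- rep(FALSE, np); matched_t <- rep(FALSE, nt)
  if (np > 0) {
    dm <- outer(points$row, centres$row, `-`)^2 +
          outer(points$col, centres$col, `-`)^2
    ok <- which(dm <= match_radius^2)
    for (ix in ok[order(dm[ok])]) {
      p <- ((ix - 1) %% np) + 1
      t <- ((ix - 1) %/% np) + 1
      if (!matched_p[p] && !matched_t[t]) {
        matched_p[p] <- TRUE; matched_t[t] <- TRUE
      }
    }
  }
  evaluation_result(n_truth = nt, n_correct = sum(matched_t),
                    n_false_positive = np - sum(matched_p),
                    rounding = rounding)
}

#' @rdname evaluate_detections
#' @param n_truth,n_correct,n_false_positive the raw matching counts; the
#'   false-negative count is implied (`n_truth - n_correct`).
#' @export
evaluation_result <- function(n_truth, n_correct, n_false_positive = 0,
                              rounding = c("half_up", "truncate")) {
  rounding <- match.arg(rounding)
  stopifnot(n_truth >= 1, n_correct >= 0, n_correct <= n_truth,
            n_false_positive >= 0)
  structure(list(n_truth = n_truth, n_correct = n_correct,
                 n_false_positive = n_false_positive,
                 n_false_negative = n_truth - n_correct,
                 correct_rate = round_rate(100 * n_correct / n_truth,
                                           rounding)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation: %d/%d correct, %d FP, %d FN, correct rate %.1f%%>\n",
    x$n_correct, x$n_truth, x$n_false_positive, x$n_false_negative,
    x$correct_rate))
  invisible(x)
}
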