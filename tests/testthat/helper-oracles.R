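# Brute-force reference implementations, kept deliberately independent of
# the package internals: plain loops and sub-matrix arithmetic only.

# replicate-padded pixel lookup
px_rep <- function(m, i, j) {
  m[min(max(i, 1), nrow(m)), min(max(j, 1), ncol(m))]
}

# direct 5x5 binomial convolution + take every 2nd row/col
oracle_pyr_down <- function(m) {
  w <- outer(c(1, 4, 6, 4, 1), c(1, 4, 6, 4, 1)) / 256
  H <- nrow(m); W <- ncol(m)
  blur <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (a in -2:2) for (b in -2:2)
      s <- s + w[a + 3, b + 3] * px_rep(m, i + a, j + b)
    blur[i, j] <- s
  }
  blur[seq(1, H, by = 2), seq(1, W, by = 2), drop = FALSE]
}

# windowed-mean comparison, replicate borders
oracle_adaptive <- function(m, blocksize) {
  r <- (blocksize - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (a in -r:r) for (b in -r:r) s <- s + px_rep(m, i + a, j + b)
    out[i, j] <- if (m[i, j] > s / blocksize^2) 255 else 0
  }
  out
}

# every-pixel block scan for local maxima candidates
oracle_local_max <- function(m, L) {
  r <- L %/% 2
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- m[i, j]
    if (v <= 0) next
    blk <- m[max(1, i - r):min(H, i + r), max(1, j - r):min(W, j + r)]
    out[i, j] <- all(blk <= v) && any(blk < v)
  }
  out
}

# flood fill background from the border (4-connected); unreached
# background becomes foreground
oracle_fill_holes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- mask == 0
  reach <- matrix(FALSE, H, W)
  queue <- which(bg & (row(mask) %in% c(1, H) | col(mask) %in% c(1, W)))
  reach[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    i <- ((p - 1) %% H) + 1; j <- ((p - 1) %/% H) + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      qi <- i + d[1]; qj <- j + d[2]
      if (qi >= 1 && qi <= H && qj >= 1 && qj <= W) {
        q <- (qj - 1) * H + qi
        if (bg[q] && !reach[q]) { reach[q] <- TRUE; queue <- c(queue, q) }
      }
    }
  }
  out <- mask
  out[bg & !reach] <- 255
  out
}

# BFS connected-component labelling (8-connected foreground)
oracle_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (p in which(mask != 0)) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p; lab[p] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      i <- ((q - 1) %% H) + 1; j <- ((q - 1) %/% H) + 1
      for (a in -1:1) for (b in -1:1) {
        qi <- i + a; qj <- j + b
        if (qi >= 1 && qi <= H && qj >= 1 && qj <= W) {
          r <- (qj - 1) * H + qi
          if (mask[r] != 0 && lab[r] == 0L) { lab[r] <- cur; queue <- c(queue, r) }
        }
      }
    }
  }
  lab
}

oracle_remove_small <- function(mask, min_area) {
  lab <- oracle_label8(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab != 0], nbins = max(lab))
  out <- mask
  for (k in which(sizes < min_area)) out[lab == k] <- 0
  out
}

# exhaustive between-class-variance search over all 256 cuts
oracle_otsu <- function(values) {
  h <- tabulate(findInterval(values, 0:255, rightmost.closed = FALSE),
                nbins = 256)
  best <- -1; bt <- NA
  for (t in 1:255) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum((0:(t - 1)) * h[1:t]) / w0
    m1 <- sum((t:255) * h[(t + 1):256]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best) { best <- bc; bt <- t }
  }
  bt
}

rand_gray <- function(H, W, smooth = FALSE) {
  m <- matrix(runif(H * W, 0, 255), H, W)
  if (smooth) {
    k <- c(1, 4, 6, 4, 1) / 16
    m <- maizekern:::conv_sep(m, k)
  }
  m
}

# a small non-touching ear used by several tests
default_fixture <- function(seed = 1, ...) {
  generate_ear(ear_spec(rows = 5, cols = 4, seed = seed, ...))
}
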