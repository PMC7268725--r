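flat_params <- mean_shift_params(sp = 5, sr = 20, max_pyramid_level = 0)

test_that("mean-shift filtering fixes constants and preserves strong edges", {
  cimg <- rgb_image(array(90, dim = c(20, 20, 3)))
  expect_equal(unclass(mean_shift_filter(cimg, flat_params)), unclass(cimg),
               tolerance = 1e-9)
  # half-planes separated by twice the colour radius stay put
  a <- array(60, dim = c(24, 24, 3))
  a[, 13:24, ] <- 60 + 2 * 20 / sqrt(3)   # euclidean distance = 2*sr
  out <- unclass(mean_shift_filter(rgb_image(a), flat_params))
  interior <- cbind(out[, 1:11, 1], out[, 15:24, 1])
  expect_lt(max(abs(interior - a[, c(1:11, 15:24), 1])), 1)
})

test_that("mean-shift filtering merges weakly separated textures", {
  set.seed(7)
  a <- array(100, dim = c(24, 24, 3))
  a[, 13:24, ] <- 100 + 20 / 4 / sqrt(3)  # colour distance sr/4
  a <- a + array(rnorm(length(a), 0, 1), dim = dim(a))
  out <- unclass(mean_shift_filter(rgb_image(pmin(pmax(a, 0), 255)),
                                   flat_params))
  expect_lt(var(as.vector(out[, , 1])), var(as.vector(a[, , 1])))
})

test_that("mean-shift filtering is idempotent on mode-structured scenes", {
  # piecewise-constant regions plus noise: after one converged pass every
  # pixel sits at its mode, so a second pass moves (almost) nothing
  set.seed(5)
  a <- array(0, dim = c(48, 48, 3))
  for (ch in 1:3) {
    m <- matrix(60, 48, 48)
    m[17:32, ] <- 150
    m[33:48, 1:24] <- 220
    a[, , ch] <- m + rnorm(48 * 48, 0, 4)
  }
  img <- rgb_image(pmin(pmax(a, 0), 255))
  p <- mean_shift_params(sp = 8, sr = 40, max_pyramid_level = 0,
                         max_iters = 30, eps = 0.5)
  once <- mean_shift_filter(img, p)
  twice <- mean_shift_filter(once, p)
  moved <- sqrt(apply((unclass(twice) - unclass(once))^2, c(1, 2), sum))
  expect_lt(mean(moved > p$eps), 0.01)
})

test_that("fruit segmentation isolates a disc on a uniform blue field", {
  a <- array(0, dim = c(40, 40, 3))
  a[, , 3] <- 255
  d <- (row(a[, , 1]) - 20)^2 + (col(a[, , 1]) - 20)^2 <= 100
  a[, , 1][d] <- 230; a[, , 2][d] <- 200; a[, , 3][d] <- 40
  mask <- segment_fruit(rgb_image(a), "blue")
  expect_identical(unclass(mask) != 0, d)
  expect_warning(
    m0 <- segment_fruit(rgb_image(array(rep(c(0, 0, 255), each = 100),
                                  c(10, 10, 3))), "blue"),
    "degenerate")
  expect_equal(sum(unclass(m0)), 0)
})

test_that("segmented fruit area matches the generated ear region", {
  fix <- default_fixture(seed = 3)
  work <- pyr_down(fix$image, 2)
  filt <- mean_shift_filter(work, mean_shift_params(sp = 10, sr = 60))
  fruit <- remove_small_areas(fill_holes(segment_fruit(filt, "blue")), 20)
  ratio <- sum(unclass(fruit) != 0) / (fix$truth$ear_area / 16)
  # the residual excess is the 1-2 px boundary-mixing halo at the
  # 16-fold-compressed working layer, a perimeter effect
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("fruit segmentation tolerates background hue jitter", {
  fix <- default_fixture(seed = 6)
  seg_area <- function(img) {
    filt <- mean_shift_filter(pyr_down(img, 2),
                              mean_shift_params(sp = 10, sr = 60))
    sum(unclass(segment_fruit(filt, "blue")) != 0)
  }
  base <- seg_area(fix$image)
  a <- unclass(fix$image)
  bg <- a[, , 3] > 150
  for (dj in c(-10, 10)) {
    a2 <- a
    a2[, , 3][bg] <- pmin(pmax(a2[, , 3][bg] + dj, 0), 255)
    jit <- seg_area(rgb_image(a2))
    expect_lt(abs(jit - base) / base, 0.01)
  }
})

test_that("hole filling matches the border-flood oracle", {
  disc <- matrix(0, 21, 21)
  disc[(row(disc) - 11)^2 + (col(disc) - 11)^2 <= 64] <- 255
  holed <- disc
  holed[10:12, 10:12] <- 0
  expect_identical(unclass(fill_holes(binary_mask(holed))), disc)
  # border-touching background is never filled
  notch <- disc; notch[1:11, 11] <- 0
  notch[1, ] <- 0
  expect_identical(unclass(fill_holes(binary_mask(notch))), notch)
  set.seed(11)
  for (i in 1:25) {
    m <- matrix(sample(c(0, 255), 64 * 64, replace = TRUE, prob = c(.4, .6)),
                64, 64)
    expect_identical(unclass(fill_holes(binary_mask(m))),
                     oracle_fill_holes(m))
  }
  # idempotence
  m <- matrix(sample(c(0, 255), 900, replace = TRUE), 30, 30)
  once <- fill_holes(binary_mask(m))
  expect_identical(unclass(fill_holes(once)), unclass(once))
})

test_that("small-area removal drops only sub-threshold components", {
  m <- matrix(0, 40, 80)
  m[2:6, 2] <- 255                      # 5 px
  m[10, 2:20] <- 255                    # 19 px
  m[20, 2:21] <- 255                    # 20 px
  m[25:34, 30:69] <- 255                # 400 px
  out <- unclass(remove_small_areas(binary_mask(m), 20))
  expect_equal(sum(out != 0), 420)
  expect_true(all(out[20, 2:21] == 255))
  expect_true(all(out[2:6, 2] == 0))
  empty <- binary_mask(matrix(0, 8, 8))
  expect_identical(unclass(remove_small_areas(empty, 20)), unclass(empty))
  set.seed(12)
  for (i in 1:25) {
    m <- matrix(sample(c(0, 255), 64 * 64, replace = TRUE, prob = c(.7, .3)),
                64, 64)
    a <- sample(2:30, 1)
    expect_identical(unclass(remove_small_areas(binary_mask(m), a)),
                     oracle_remove_small(m, a))
  }
})

test_that("small-area removal is monotone in the area threshold", {
  set.seed(13)
  m <- matrix(sample(c(0, 255), 48 * 48, replace = TRUE, prob = c(.6, .4)),
              48, 48)
  prev <- unclass(remove_small_areas(binary_mask(m), 1))
  for (a in c(5, 10, 20, 50)) {
    cur <- unclass(remove_small_areas(binary_mask(m), a))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})
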