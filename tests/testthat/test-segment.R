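# paint axis-aligned ellipses (value 200 on 50) into a grey canvas
ellipse_field <- function(H, W, centres, ay, ax) {
  m <- matrix(50, H, W)
  for (k in seq_len(nrow(centres))) {
    sel <- ((row(m) - centres[k, 1]) / ay[k])^2 +
           ((col(m) - centres[k, 2]) / ax[k])^2 <= 1
    m[sel] <- 200
  }
  m
}

test_that("kernel MBR estimation recovers known ellipse dimensions", {
  centres <- as.matrix(expand.grid(seq(20, 140, by = 30),
                                   seq(15, 95, by = 20)))
  g <- ellipse_field(160, 110, centres, rep(10, nrow(centres)),
                     rep(6, nrow(centres)))
  est <- estimate_kernel_mbr(gray_image(g),
                             binary_mask(matrix(255, 160, 110)))
  expect_false(est$fallback_used)
  expect_equal(est$avg_mbr_length, 20, tolerance = 0.08)
  expect_equal(est$avg_mbr_width, 12, tolerance = 0.1)
})

test_that("kernel MBR estimation averages mixed sizes", {
  centres <- as.matrix(expand.grid(seq(25, 145, by = 40),
                                   seq(20, 100, by = 25)))
  n <- nrow(centres)
  ay <- rep(c(8, 12), length.out = n)   # 16 px and 24 px lengths
  ax <- rep(c(5, 7), length.out = n)    # 10 px and 14 px widths
  g <- ellipse_field(170, 120, centres, ay, ax)
  est <- estimate_kernel_mbr(gray_image(g),
                             binary_mask(matrix(255, 170, 120)))
  expect_equal(est$avg_mbr_length, 20, tolerance = 0.1)
  expect_equal(est$avg_mbr_width, 12, tolerance = 0.1)
})

test_that("kernel MBR estimation falls back when components are scarce", {
  g <- ellipse_field(40, 40, matrix(c(20, 20), 1), 10, 6)
  expect_warning(
    est <- estimate_kernel_mbr(gray_image(g),
                               binary_mask(matrix(255, 40, 40))),
    "fewer than 3")
  expect_true(est$fallback_used)
  expect_equal(est$avg_mbr_length, 10)
})

test_that("adaptive thresholding matches the sliding-mean oracle", {
  # constants produce empty output under the strict comparison rule
  expect_equal(sum(unclass(adaptive_threshold(gray_image(matrix(7, 20, 20)),
                                              5))), 0)
  # ideal step: full agreement with the oracle on the exact map
  step <- matrix(0, 24, 24); step[, 13:24] <- 255
  expect_identical(unclass(adaptive_threshold(gray_image(step), 5)),
                   oracle_adaptive(step, 5))
  set.seed(31)
  for (i in 1:12) {
    H <- sample(10:40, 1); W <- sample(10:40, 1)
    m <- rand_gray(H, W)
    bs <- sample(c(3, 5, 7, 9), 1)
    expect_identical(unclass(adaptive_threshold(gray_image(m), bs)),
                     oracle_adaptive(m, bs))
  }
  expect_error(adaptive_threshold(gray_image(matrix(0, 5, 5)), 7),
               "larger than image")
  expect_error(adaptive_threshold(gray_image(matrix(0, 9, 9)), 4))
})

test_that("adaptive thresholding is exactly invariant to global offsets", {
  set.seed(32)
  m <- matrix(runif(40 * 40, 10, 180), 40, 40)
  base <- unclass(adaptive_threshold(gray_image(m), 7))
  for (off in c(12.5, 40, 70)) {
    expect_identical(unclass(adaptive_threshold(gray_image(m + off), 7)),
                     base)
  }
})

test_that("a gradient field favours adaptive over global thresholding", {
  fix <- generate_ear(ear_spec(rows = 5, cols = 4, seed = 2,
    illumination = list(mode = "linear_gradient", amplitude = 60)))
  det <- suppressWarnings(count_kernels(fix$image, keep_stages = TRUE))
  gray <- det$stages$gray
  fruit <- det$stages$fruit
  # kernel-core ground truth mapped to the working layer
  tr <- fix$truth
  core <- matrix(FALSE, nrow(unclass(gray)), ncol(unclass(gray)))
  for (k in seq_len(tr$n_kernels)) {
    sel <- ((row(core) - tr$centres$row[k] / 4) / (tr$mbr$length[k] / 8 * 0.6))^2 +
           ((col(core) - tr$centres$col[k] / 4) / (tr$mbr$width[k] / 8 * 0.6))^2 <= 1
    core <- core | sel
  }
  blocksize <- maizekern:::round_odd(det$mbr$avg_mbr_length)
  rec_adapt <- sum(unclass(adaptive_threshold(gray, blocksize, fruit)) != 0 &
                   core) / sum(core)
  rec_otsu <- sum(unclass(otsu_threshold(gray, fruit)) != 0 & core) /
    sum(core)
  expect_gte(rec_adapt, 0.9)
  expect_lt(rec_otsu, rec_adapt)
})

test_that("halving the block size never reduces the component count", {
  fix <- generate_ear(ear_spec(rows = 5, cols = 4, seed = 8))
  det <- suppressWarnings(count_kernels(fix$image, keep_stages = TRUE))
  ncomp <- function(bs) {
    b <- adaptive_threshold(det$stages$gray, bs, det$stages$fruit)
    max(maizekern:::cpp_label(matrix(as.integer(unclass(b) != 0),
                                     nrow(unclass(b))), 8L))
  }
  big <- maizekern:::round_odd(det$mbr$avg_mbr_length)
  small <- maizekern:::round_odd(big / 2)
  expect_gte(ncomp(small), ncomp(big))
})

test_that("global Otsu matches the exhaustive-search oracle", {
  v <- c(rep(50, 100), rep(200, 100))
  thr <- maizekern:::otsu_cut(v)
  expect_gt(thr, 50); expect_lte(thr, 200)
  m <- matrix(v, 20, 10)
  out <- otsu_threshold(gray_image(m))
  expect_identical(unclass(out) != 0, m > 125)
  set.seed(33)
  for (i in 1:10) {
    m <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    ours <- maizekern:::otsu_cut(m)
    ref <- oracle_otsu(m)
    split_ours <- m > ours
    split_ref <- m > (ref - 0.5)
    expect_identical(split_ours, split_ref)
  }
  expect_warning(out0 <- otsu_threshold(gray_image(matrix(100, 5, 5))),
                 "degenerate")
  expect_equal(sum(unclass(out0)), 0)
})
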