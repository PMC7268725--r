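test_that("Lab conversion reproduces the printed coefficients", {
  one <- function(r, g, b) {
    px <- rgb_image(array(c(r, g, b), dim = c(1, 1, 3)))
    as.vector(unclass(rgb_to_lab(px)))
  }
  expect_equal(one(255, 255, 255), c(255, 128, 128), tolerance = 1e-6)
  expect_equal(one(0, 0, 0), c(0, 128, 128), tolerance = 1e-6)
  expect_equal(one(255, 0, 0), c(54.213, 211.24, 159.03), tolerance = 1e-2)
})

test_that("grey inputs are chromatically neutral in Lab", {
  g <- 0:255
  img <- rgb_image(array(rep(g, 3), dim = c(256, 1, 3)))
  lab <- unclass(rgb_to_lab(img))
  expect_true(all(lab[, , 2] == 128))
  expect_true(all(lab[, , 3] == 128))
})

test_that("OD matrix completion is orthonormal and invertible", {
  lib <- load_stain_library()
  expect_equal(vapply(lib, function(s) s$name, ""),
               c("methyl green", "hematoxylin GL", "white"))
  mg <- build_od_matrix(lib[[1]])
  # the printed vector is unit-norm only to four decimals
  expect_equal(mg$C[1, ], lib[[1]]$vector, tolerance = 1e-3)
  for (combo in lib) {
    od <- build_od_matrix(combo)
    gram <- od$C %*% t(od$C)
    expect_lt(max(abs(gram - diag(3))), 1e-6)      # pairwise orthonormal rows
    expect_lt(max(abs(od$C %*% od$D - diag(3))), 1e-9)
  }
  # the all-zero "white" vector resolves to the uniform brightness absorber
  wh <- build_od_matrix(lib[[3]])
  expect_equal(wh$C[1, ], rep(1 / sqrt(3), 3), tolerance = 1e-12)
})

test_that("deconvolution separates pure-stain colours and white", {
  od <- build_od_matrix(stain_combination("mg", c(0.98003, 0.144316, 0.133146)))
  # white pixel: zero density in every stain, displays at full brightness
  white <- structure(array(255, dim = c(1, 1, 3)), class = "lab_image")
  maps <- color_deconvolve(white, od)
  for (m in maps) expect_equal(as.numeric(unclass(m)), 255, tolerance = 1e-9)
  # a uniform image along the first stain's OD direction loads only stain 1
  k <- 0.8
  vals <- 256 * exp(-k * od$C[1, ]) - 1
  img <- structure(array(rep(vals, each = 4), dim = c(2, 2, 3)),
                   class = "lab_image")
  maps <- color_deconvolve(img, od)
  expect_equal(unique(as.numeric(unclass(maps[[1]]))),
               256 * exp(-k) - 1, tolerance = 1e-6)
  expect_equal(as.numeric(unclass(maps[[2]])), rep(255, 4), tolerance = 1e-6)
  expect_equal(as.numeric(unclass(maps[[3]])), rep(255, 4), tolerance = 1e-6)
})

test_that("deconvolution round-trips random Lab images within 1 unit", {
  set.seed(21)
  for (combo in load_stain_library()) {
    od <- build_od_matrix(combo)
    a <- array(runif(8 * 8 * 3, 0, 255), dim = c(8, 8, 3))
    lab <- structure(a, class = "lab_image")
    V <- rbind(as.vector(a[, , 1]), as.vector(a[, , 2]), as.vector(a[, , 3]))
    Rstar <- solve(t(od$C)) %*% (-log((V + 1) / 256))
    rec <- 256 * exp(-t(od$C) %*% Rstar) - 1
    expect_lt(max(abs(rec - V)), 1)
  }
})

test_that("stain selection picks the nearest centroid with stable ties", {
  lib <- list(stain_combination("a", c(1, 0, 0), c(100, 128, 128)),
              stain_combination("b", c(0, 1, 0), c(200, 128, 128)))
  lab <- structure(array(rep(c(100, 128, 128), each = 4), dim = c(2, 2, 3)),
                   class = "lab_image")
  fruit <- binary_mask(matrix(255, 2, 2))
  expect_equal(select_stain_combination(lab, fruit, lib)$name, "a")
  mid <- structure(array(rep(c(150, 128, 128), each = 4), dim = c(2, 2, 3)),
                   class = "lab_image")
  expect_equal(select_stain_combination(mid, fruit, lib)$name, "a")
  expect_error(select_stain_combination(lab, binary_mask(matrix(0, 2, 2)),
                                        lib), "empty fruit")
})

test_that("each generated colourway selects its own stain combination", {
  lib <- load_stain_library()
  expected <- c(yellow = "white", pale = "methyl green",
                red = "hematoxylin GL")
  for (cwn in names(expected)) {
    for (sd in 1:4) {
      fix <- generate_ear(ear_spec(rows = 4, cols = 4, colorway = cwn,
                                   seed = sd, color_jitter = 5))
      filt <- mean_shift_filter(pyr_down(fix$image, 2),
                                mean_shift_params(sp = 10, sr = 60))
      fruit <- remove_small_areas(fill_holes(segment_fruit(filt, "blue")), 20)
      combo <- select_stain_combination(rgb_to_lab(filt), fruit, lib)
      expect_equal(combo$name, unname(expected[cwn]))
    }
  }
})

test_that("grey extraction returns the first stain map with shape intact", {
  maps <- list(gray_image(matrix(1, 3, 4)), gray_image(matrix(2, 3, 4)),
               gray_image(matrix(3, 3, 4)))
  g <- extract_gray(maps)
  expect_identical(unclass(g), matrix(1, 3, 4))
})

test_that("the deconvolved grey keeps the contact line clearly darker", {
  fix <- generate_touching_pair("edge_edge", seed = 1, noise_sd = 0)
  tr <- fix$truth
  lab <- rgb_to_lab(fix$image)
  gray <- unclass(extract_gray(color_deconvolve(
    lab, build_od_matrix(load_stain_library()[[3]]))))
  mid <- round(colMeans(tr$centres))
  crown <- round(unlist(tr$centres[1, ]))
  contrast <- gray[crown[1], crown[2]] - gray[mid[1], mid[2]]
  expect_gt(contrast, 30)
})
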