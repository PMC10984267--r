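test_that("CIVE matches direct evaluation of its coefficients", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(compute_cive(px(0, 0, 0))[1, 1], 18.78754)
  expect_equal(compute_cive(px(0, 255, 0))[1, 1], -188.01746)
  expect_equal(compute_cive(px(255, 0, 0))[1, 1], 131.24254)
  # BGR input swaps the red and blue slices
  expect_equal(compute_cive(px(255, 0, 0), "BGR")[1, 1],
               compute_cive(px(0, 0, 255))[1, 1])
  expect_error(compute_cive(matrix(0, 2, 2)), "H x W x 3")
})

test_that("CIVE on an image equals per-pixel scalar evaluation", {
  set.seed(42)
  img <- array(sample(0:255, 3 * 40 * 25, replace = TRUE), dim = c(40, 25, 3))
  cive <- compute_cive(img)
  ij <- cbind(sample(40, 100, TRUE), sample(25, 100, TRUE))
  for (k in seq_len(nrow(ij))) {
    i <- ij[k, 1]; j <- ij[k, 2]
    expect_equal(cive[i, j],
                 0.441 * img[i, j, 1] - 0.811 * img[i, j, 2] +
                   0.385 * img[i, j, 3] + 18.78754)
  }
})

test_that("Otsu binarization separates a two-level map exactly", {
  cive <- matrix(c(rep(-100, 50), rep(10, 50)), 10, 10)
  vm <- binarize_vegetation(cive)
  expect_false(vm$degenerate)
  expect_identical(vm$mask, cive == -100)
  # the mask is the exact level-set of the returned threshold
  expect_identical(vm$mask, cive <= vm$otsu_threshold)
})

test_that("constant CIVE map is flagged degenerate with an all-false mask", {
  vm <- binarize_vegetation(matrix(5, 8, 8))
  expect_true(vm$degenerate)
  expect_false(any(vm$mask))
  expect_true(is.na(vm$otsu_threshold))
})

test_that("binarization equals brute-force Otsu and partitions the pixels", {
  for (s in 1:5) {
    set.seed(s)
    cive <- matrix(c(rnorm(300, -60, 12), rnorm(200, 15, 10)), 25, 20)
    vm <- binarize_vegetation(cive)
    expect_identical(vm$mask, brute_otsu_mask(cive))
    # vegetation and background partition the image
    expect_true(all(xor(vm$mask, cive > vm$otsu_threshold)))
  }
})

test_that("binarization agrees with EBImage's Otsu on well-separated classes", {
  # EBImage's histogram split differs in bin bookkeeping, but on bimodal maps
  # with a clear gap both thresholds fall inside the gap: identical masks
  for (s in 1:3) {
    set.seed(s)
    cive <- matrix(c(rnorm(500, -60, 10), rnorm(300, 15, 8)), 40, 20)
    vm <- binarize_vegetation(cive)
    rng <- range(cive)
    ref <- EBImage::otsu(EBImage::Image((cive - rng[1]) / diff(rng)),
                         range = c(0, 1), levels = 256)
    ref_cive <- rng[1] + ref * diff(rng)
    expect_identical(vm$mask, cive <= ref_cive)
  }
})

test_that("green rectangle on soil is recovered by the vegetation mask", {
  img <- array(0, dim = c(120, 160, 3))
  for (ch in 1:3) img[, , ch] <- c(120, 100, 80)[ch]
  truth <- matrix(FALSE, 120, 160)
  truth[31:90, 41:120] <- TRUE
  for (ch in 1:3) {
    pl <- img[, , ch]; pl[truth] <- c(60, 140, 60)[ch]; img[, , ch] <- pl
  }
  vm <- binarize_vegetation(compute_cive(img))
  iou <- sum(vm$mask & truth) / sum(vm$mask | truth)
  expect_gte(iou, 0.99)
})

test_that("white-pixel profiles count, smooth and conserve vegetation", {
  expect_identical(white_pixel_profile(matrix(FALSE, 30, 20))$raw_counts,
                   integer(30))
  pr <- white_pixel_profile(matrix(TRUE, 40, 500), "row")
  expect_true(all(pr$raw_counts == 500L))
  expect_true(all(pr$smoothed == 500))

  # one all-true row away from the edges: smoothed plateau conserves the sum
  m <- matrix(FALSE, 400, 50); m[200, ] <- TRUE
  sm <- white_pixel_profile(m, "row", smooth_window = 100)$smoothed
  expect_equal(sum(sm), 50)
  expect_equal(sum(sm > 0), 100)          # plateau of exactly window width
  expect_equal(sm, slow_ma(rowSums(m), 100))

  # conservation: row total = column total = vegetation pixel count
  set.seed(3)
  m2 <- matrix(runif(60 * 45) < 0.3, 60, 45)
  expect_equal(sum(white_pixel_profile(m2, "row")$raw_counts),
               sum(white_pixel_profile(m2, "column")$raw_counts))
  expect_equal(sum(white_pixel_profile(m2, "row")$raw_counts), sum(m2))
})

test_that("locate_plot equals the exhaustive-placement oracle", {
  set.seed(11)
  masks <- list(
    matrix(runif(300 * 250) < 0.4, 300, 250),
    { m <- matrix(FALSE, 280, 260); m[60:210, 40:230] <- TRUE; m },
    { m <- matrix(TRUE, 240, 240); m[100:140, ] <- FALSE; m }
  )
  for (m in masks) {
    w <- locate_plot(m, height = 150, width = 180, smooth_window = 30)
    o <- exhaustive_locate(m, 150, 180, smooth_window = 30)
    expect_identical(w$row0, as.integer(o$row0))
    expect_identical(w$col0, as.integer(o$col0))
  }
})

test_that("a vegetation band is located at full frame scale", {
  m <- matrix(FALSE, 3000, 5000)
  m[601:2100, 801:4100] <- TRUE     # band rows 600-2099, cols 800-4099 (0-based)
  w <- locate_plot(m, height = 2000, width = 3800, smooth_window = 100)
  o <- exhaustive_locate(m, 2000, 3800, smooth_window = 100)
  expect_identical(w$row0, as.integer(o$row0))
  expect_identical(w$col0, as.integer(o$col0))
  # the window contains the band center and sits within 60 px of the optimum
  expect_lte(abs(w$row0 - o$row0), 60)
  expect_true(w$row0 <= 600 + 60 && w$col0 <= 800 + 60)
})

test_that("degenerate masks tie-break to the centered placement", {
  w <- locate_plot(matrix(TRUE, 300, 400), height = 200, width = 300,
                   smooth_window = 20)
  expect_identical(c(w$row0, w$col0), c(50L, 50L))
  w0 <- locate_plot(matrix(FALSE, 300, 400), height = 200, width = 300,
                    smooth_window = 20)
  expect_identical(c(w0$row0, w0$col0), c(50L, 50L))
  expect_error(locate_plot(matrix(TRUE, 100, 100), height = 200, width = 300),
               "smaller than")
})

test_that("crop_plot returns exactly the window and round-trips", {
  set.seed(5)
  img <- array(runif(150 * 220 * 3, 0, 255), dim = c(150, 220, 3))
  full <- crop_plot(img, plot_window(0, 0, 150, 220))
  expect_identical(full, img)
  cr <- crop_plot(img, plot_window(30, 40, 100, 150))
  expect_identical(dim(cr), c(100L, 150L, 3L))
  expect_identical(cr[1, 1, ], img[31, 41, ])
  expect_error(crop_plot(img, plot_window(100, 40, 100, 150)), "bounds")
  # locating within a crop of the crop's own size has a single placement
  vm <- binarize_vegetation(compute_cive(cr))
  w2 <- locate_plot(vm, height = 100, width = 150, smooth_window = 10)
  expect_identical(c(w2$row0, w2$col0), c(0L, 0L))
})
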