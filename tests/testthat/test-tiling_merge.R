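test_that("tile grids follow the stride-then-clamp rule", {
  g <- make_tiles(2000, 1000, tile = 1000, overlap_ratio = 0)
  expect_identical(sort(unique(g$x0)), c(0L, 1000L))
  expect_identical(unique(g$y0), 0L)
  expect_identical(nrow(g), 2L)

  g2 <- make_tiles(3800, 2000, tile = 1000, overlap_ratio = 0.25)
  expect_identical(sort(unique(g2$x0)), c(0L, 750L, 1500L, 2250L, 2800L))
  expect_identical(sort(unique(g2$y0)), c(0L, 750L, 1000L))
  expect_identical(nrow(g2), 15L)

  expect_identical(nrow(make_tiles(1000, 1000, overlap_ratio = 0.5)), 1L)
  expect_error(make_tiles(800, 2000), "larger than plot")
})

test_that("tilings cover every pixel; 0.25 overlap covers each at most 4x", {
  set.seed(21)
  for (i in 1:20) {
    w <- sample(1000:3000, 1); h <- sample(1000:3000, 1)
    g <- make_tiles(w, h, tile = 1000, overlap_ratio = 0.25)
    cover <- matrix(0L, h, w)
    for (k in seq_len(nrow(g)))
      cover[(g$y0[k] + 1):(g$y0[k] + 1000), (g$x0[k] + 1):(g$x0[k] + 1000)] <-
        cover[(g$y0[k] + 1):(g$y0[k] + 1000), (g$x0[k] + 1):(g$x0[k] + 1000)] + 1L
    expect_true(all(cover >= 1L))
    # away from the clamped final-tile bands, multiplicity is at most 4
    expect_lte(max(cover[seq_len(h - 1000), seq_len(w - 1000)]), 4L)
  }
})

test_that("to_global translates, clips and round-trips", {
  tl <- data.frame(x0 = 750L, y0 = 1000L, size_x = 1000L, size_y = 1000L)
  d <- detection_set(data.frame(x_min = 10, y_min = 20, x_max = 50, y_max = 80,
                                score = 0.7), frame = "tile", source_tile = tl)
  g <- to_global(d)
  expect_equal(as.numeric(g$boxes[1, 1:4]), c(760, 1020, 800, 1080))
  expect_identical(g$frame, "plot")
  expect_error(to_global(g), "already")

  # tile at origin leaves boxes unchanged; translation is invertible
  o <- data.frame(x0 = 0L, y0 = 0L)
  d0 <- detection_set(d$boxes, frame = "tile", source_tile = o)
  expect_equal(to_global(d0)$boxes, d$boxes)
  back <- to_global(d)$boxes
  back[, c("x_min", "x_max")] <- back[, c("x_min", "x_max")] - tl$x0
  back[, c("y_min", "y_max")] <- back[, c("y_min", "y_max")] - tl$y0
  expect_equal(back, d$boxes)

  # clipping to the plot extent
  clipped <- to_global(d, plot_w = 780, plot_h = 2000)
  expect_equal(clipped$boxes$x_max, 780)
})

test_that("box IoU matches hand-computed areas", {
  b <- function(...) data.frame(matrix(c(...), 1,
         dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max"))))
  expect_equal(box_iou(b(0, 0, 10, 10), b(0, 0, 10, 10)), 1)
  expect_equal(box_iou(b(0, 0, 10, 10), b(20, 20, 30, 30)), 0)
  expect_equal(box_iou(b(0, 0, 10, 10), b(5, 0, 15, 10)), 1 / 3)
})

test_that("greedy NMS keeps the top box among duplicates and is idempotent", {
  expect_identical(nrow(nms(detection_set(frame = "plot"))$boxes), 0L)
  two <- detection_set(data.frame(x_min = c(0, 0), y_min = c(0, 0),
                                  x_max = c(10, 10), y_max = c(10, 10),
                                  score = c(0.9, 0.8)), frame = "plot")
  kept <- nms(two, 0.25)
  expect_identical(nrow(kept$boxes), 1L)
  expect_equal(kept$boxes$score, 0.9)

  set.seed(31)
  for (i in 1:25) {
    d <- detection_set(random_boxes(sample(1:50, 1)), frame = "plot")
    out <- nms(d, 0.3)
    expect_equal(canon_boxes(nms(out, 0.3)), canon_boxes(out))   # idempotent
    expect_lte(nrow(out$boxes), nrow(d$boxes))
    if (nrow(out$boxes) > 1) {
      m <- box_iou(out$boxes, out$boxes)
      expect_lte(max(m[upper.tri(m)]), 0.3)   # survivors mutually separated
    }
    expect_equal(canon_boxes(out), canon_boxes(
      detection_set(brute_nms(d$boxes, 0.3), frame = "plot")))
  }
})

test_that("merging filters, deduplicates across tiles and ignores tile order", {
  tl1 <- data.frame(x0 = 0L, y0 = 0L)
  tl2 <- data.frame(x0 = 750L, y0 = 0L)
  # the same panicle seen by both overlapping tiles
  d1 <- detection_set(data.frame(x_min = 760, y_min = 100, x_max = 800,
                                 y_max = 140, score = 0.8),
                      frame = "tile", source_tile = tl1)
  d2 <- detection_set(data.frame(x_min = 12, y_min = 102, x_max = 52,
                                 y_max = 141, score = 0.9),
                      frame = "tile", source_tile = tl2)
  merged <- merge_tile_detections(list(d1, d2))
  expect_identical(count_panicles(merged), 1L)
  expect_equal(merged$boxes$score, 0.9)

  # one tile only: equals conf-filter + NMS of that tile
  solo <- merge_tile_detections(list(d1))
  expect_equal(canon_boxes(solo), canon_boxes(nms(to_global(d1), 0.25)))

  # everything below the confidence threshold vanishes
  low <- detection_set(data.frame(x_min = 1, y_min = 1, x_max = 5, y_max = 5,
                                  score = 0.2), frame = "tile", source_tile = tl1)
  expect_identical(count_panicles(merge_tile_detections(list(low))), 0L)

  # permuting tile order never changes the merged set
  set.seed(41)
  tiles <- list(tl1, tl2, data.frame(x0 = 0L, y0 = 750L))
  sets <- lapply(tiles, function(tl)
    detection_set(random_boxes(8, extent = 900), frame = "tile",
                  source_tile = tl))
  ref <- canon_boxes(merge_tile_detections(sets))
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(canon_boxes(merge_tile_detections(sets[p])), ref)
})
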