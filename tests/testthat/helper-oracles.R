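# Independent oracles, written as plain loops so they share no code path with
# the implementation they check.

# scalar IoU by direct area arithmetic
scalar_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  inter / (area(a) + area(b) - inter)
}

# O(n^2) greedy NMS reference: repeated scans, no sorting
brute_nms <- function(boxes, thr) {
  alive <- rep(TRUE, nrow(boxes))
  kept <- integer(0)
  area <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
  while (any(alive)) {
    best <- NA_integer_
    for (i in which(alive)) {
      if (is.na(best) ||
          boxes$score[i] > boxes$score[best] ||
          (boxes$score[i] == boxes$score[best] && area[i] > area[best]))
        best <- i
    }
    kept <- c(kept, best)
    alive[best] <- FALSE
    bb <- as.numeric(boxes[best, c("x_min", "y_min", "x_max", "y_max")])
    for (i in which(alive)) {
      oi <- as.numeric(boxes[i, c("x_min", "y_min", "x_max", "y_max")])
      if (scalar_iou(bb, oi) > thr) alive[i] <- FALSE
    }
  }
  boxes[sort(kept), , drop = FALSE]
}

random_boxes <- function(n, extent = 100) {
  x0 <- runif(n, 0, extent - 10); y0 <- runif(n, 0, extent - 10)
  data.frame(x_min = x0, y_min = y0,
             x_max = x0 + runif(n, 2, 30), y_max = y0 + runif(n, 2, 30),
             score = runif(n))
}

# moving average by explicit window loop
slow_ma <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - ((w - 1) %/% 2))
    hi <- min(n, i + (w %/% 2))
    out[i] <- mean(x[lo:hi])
  }
  out
}

# exhaustive plot-placement search on smoothed profiles (median tie index)
exhaustive_locate <- function(mask, height, width, smooth_window = 100) {
  sr <- slow_ma(rowSums(mask), smooth_window)
  sc <- slow_ma(colSums(mask), smooth_window)
  pick <- function(s, ext) {
    obj <- numeric(length(s) - ext + 1)
    for (i in seq_along(obj)) obj[i] <- s[i] + s[i + ext - 1]
    tied <- which(obj == min(obj))
    tied[(length(tied) + 1) %/% 2] - 1L   # 0-based
  }
  list(row0 = pick(sr, height), col0 = pick(sc, width))
}

# brute-force 256-bin Otsu: try every split, explicit class statistics
brute_otsu_mask <- function(cive) {
  lo <- min(cive); hi <- max(cive)
  bins <- as.integer(round((cive - lo) / (hi - lo) * 255))
  best_t <- NA; best_v <- -Inf
  for (T in 0:254) {
    c0 <- bins <= T
    n0 <- sum(c0); n1 <- sum(!c0)
    if (n0 == 0 || n1 == 0) next
    v <- n0 * n1 * (mean(bins[c0]) - mean(bins[!c0]))^2
    if (v > best_v + 1e-9) { best_v <- v; best_t <- T }
  }
  out <- bins <= best_t
  dim(out) <- dim(cive)
  out
}

# 101-point AP by explicit enumeration of every (precision, recall) prefix
brute_ap <- function(tp_sorted, n_gt) {
  n <- length(tp_sorted)
  prec <- numeric(n); rec <- numeric(n)
  for (k in seq_len(n)) {
    prec[k] <- sum(tp_sorted[1:k]) / k
    rec[k] <- sum(tp_sorted[1:k]) / n_gt
  }
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    p <- 0
    for (k in seq_len(n)) if (rec[k] >= r && prec[k] > p) p <- prec[k]
    total <- total + p
  }
  total / 101
}

# IoU of two plot windows
win_iou <- function(a, b) {
  ih <- max(0, min(a$row0 + a$height, b$row0 + b$height) - max(a$row0, b$row0))
  iw <- max(0, min(a$col0 + a$width, b$col0 + b$width) - max(a$col0, b$col0))
  inter <- ih * iw
  inter / (a$height * a$width + b$height * b$width - inter)
}

# canonical form for comparing detection sets as sets
canon_boxes <- function(det) {
  b <- det$boxes
  b <- b[order(b$x_min, b$y_min, b$x_max, b$y_max, b$score), , drop = FALSE]
  rownames(b) <- NULL
  b
}

# one flat synthetic tile with given blob boxes painted on a dark background
paint_tile <- function(h, w, boxes, tone = c(220, 200, 110), bg = 60) {
  img <- array(bg, dim = c(h, w, 3))
  for (i in seq_len(nrow(boxes))) {
    rr <- (boxes$y_min[i] + 1):boxes$y_max[i]
    cc <- (boxes$x_min[i] + 1):boxes$x_max[i]
    for (ch in 1:3) img[rr, cc, ch] <- tone[ch]
  }
  img
}
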