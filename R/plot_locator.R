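#' Color index of vegetation extraction (CIVE)
#'
#' Computes the CIVE index per pixel,
#' \deqn{0.441 R - 0.811 G + 0.385 B + 18.78754,}
#' a linear combination of the red, green and blue channels whose low values
#' indicate green vegetation (the large negative green coefficient dominates
#' for foliage pixels).
#'
#' @param image numeric array of dimension H x W x 3 with intensities in
#'   `[0, 255]` (8-bit scale; fractional values are allowed).
#' @param channel_order `"RGB"` (default) or `"BGR"`; declares which slice of
#'   the third dimension holds which channel.
#' @return an H x W numeric matrix of CIVE values.
#' @examples
#' px <- array(c(0, 255, 0), dim = c(1, 1, 3))  # pure green
#' compute_cive(px)                              # -188.01746
#' @export
compute_cive <- function(image, channel_order = c("RGB", "BGR")) {
  channel_order <- match.arg(channel_order)
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be an H x W x 3 array")
  idx <- if (channel_order == "RGB") c(1L, 2L, 3L) else c(3L, 2L, 1L)
  r <- image[, , idx[1]]
  g <- image[, , idx[2]]
  b <- image[, , idx[3]]
  out <- 0.441 * r - 0.811 * g + 0.385 * b + 18.78754
  dim(out) <- dim(image)[1:2]   # keep H x W even for 1-pixel images
  out
}

# Otsu threshold on a 256-bin integer histogram. Returns the bin index T
# (0-based) maximizing between-class variance for the split {<= T} / {> T};
# ties break to the lowest T. `counts` has length 256.
otsu_bin <- function(counts) {
  n <- sum(counts)
  bins <- 0:255
  w0 <- cumsum(counts)                      # pixels in class {<= T}
  mu_t <- cumsum(counts * bins)             # running intensity mass
  mu <- mu_t[256] / n
  w0f <- w0 / n
  # between-class variance; undefined where a class is empty
  num <- (mu * w0f - mu_t / n)^2
  den <- w0f * (1 - w0f)
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  sigma_b <- sigma_b[1:255]                 # T = 255 leaves class 2 empty
  if (all(!is.finite(sigma_b))) return(NA_integer_)
  which.max(sigma_b) - 1L
}

#' Binarize a CIVE map into a vegetation mask
#'
#' Applies Otsu's method to the CIVE values. The map is affinely rescaled so
#' its minimum maps to bin 0 and its maximum to bin 255, the optimal 256-bin
#' Otsu split is found, and the threshold is mapped back to CIVE units.
#' Vegetation is the low side: pixels with CIVE less than or equal to the
#' threshold (greener pixels have lower CIVE).
#'
#' A constant-valued map has no separable classes; the result is then an
#' all-`FALSE` mask with `degenerate = TRUE` and an `NA` threshold.
#'
#' @param cive numeric matrix of finite CIVE values.
#' @return an object of class `vegetation_mask`: a list with `mask` (logical
#'   matrix, `TRUE` = vegetation), `otsu_threshold` (CIVE units) and
#'   `degenerate` flag.
#' @export
binarize_vegetation <- function(cive) {
  if (!is.matrix(cive)) stop("`cive` must be a matrix")
  if (any(!is.finite(cive))) stop("`cive` must be finite everywhere")
  lo <- min(cive)
  hi <- max(cive)
  if (hi <= lo) {
    res <- list(mask = matrix(FALSE, nrow(cive), ncol(cive)),
                otsu_threshold = NA_real_, degenerate = TRUE)
    class(res) <- "vegetation_mask"
    return(res)
  }
  bins <- as.integer(round((cive - lo) / (hi - lo) * 255))
  counts <- tabulate(bins + 1L, nbins = 256L)
  t_bin <- otsu_bin(counts)
  # threshold = upper edge of the chosen bin, so the mask below is the exact
  # level-set {CIVE <= otsu_threshold}
  thr <- lo + (t_bin + 0.5) / 255 * (hi - lo)
  res <- list(mask = cive <= thr, otsu_threshold = thr, degenerate = FALSE)
  class(res) <- "vegetation_mask"
  res
}

#' @export
print.vegetation_mask <- function(x, ...) {
  cat(sprintf("vegetation_mask: %d x %d, %.1f%% vegetation, threshold %s%s\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask),
              format(x$otsu_threshold),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# Centered moving average with window `w`, edge windows truncated to the
# valid index range. For even w the window at i is [i - (w/2 - 1), i + w/2].
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(as.numeric(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - ((w - 1L) %/% 2L))
  hi <- pmin(n, i + (w %/% 2L))
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' White-pixel profile of a vegetation mask
#'
#' Counts vegetation pixels per row (or per column) and smooths the counts
#' with a centered moving average (window 100 by default, truncated at the
#' edges). These profiles drive the minimum-boundary plot search: plot gaps
#' show up as dips.
#'
#' @param mask a `vegetation_mask` or a logical matrix.
#' @param axis `"row"` or `"column"`.
#' @param smooth_window moving-average window in pixels.
#' @return a list of class `pixel_profile` with `axis`, `raw_counts`,
#'   `smoothed` and `smooth_window`.
#' @export
white_pixel_profile <- function(mask, axis = c("row", "column"),
                                smooth_window = 100) {
  axis <- match.arg(axis)
  m <- if (inherits(mask, "vegetation_mask")) mask$mask else mask
  if (!is.matrix(m) || length(m) == 0L) stop("`mask` must be a non-empty matrix")
  raw <- if (axis == "row") rowSums(m) else colSums(m)
  structure(list(axis = axis,
                 raw_counts = as.integer(raw),
                 smoothed = moving_average(raw, as.integer(smooth_window)),
                 smooth_window = as.integer(smooth_window)),
            class = "pixel_profile")
}

# argmin with ties broken to the median element of the tied set
argmin_median_tie <- function(x, tol = 0) {
  m <- min(x)
  tied <- which(x <= m + tol)
  tied[(length(tied) + 1L) %/% 2L]
}

#' Plot window
#'
#' Axis-aligned crop rectangle identifying the central plot. Coordinates are
#' 0-based and half-open: the window covers rows `[row0, row0 + height)` and
#' columns `[col0, col0 + width)` of the image.
#'
#' @param row0,col0 0-based origin.
#' @param height,width window extent in pixels; the defaults are the expected
#'   plot size (in pixels) of a 2 x 1.1 m plot at the reference flight
#'   altitude and zoom.
#' @export
plot_window <- function(row0, col0, height = 2000, width = 3800) {
  w <- list(row0 = as.integer(row0), col0 = as.integer(col0),
            height = as.integer(height), width = as.integer(width))
  if (w$row0 < 0L || w$col0 < 0L || w$height <= 0L || w$width <= 0L)
    stop("invalid plot window")
  class(w) <- "plot_window"
  w
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("plot_window: origin (row %d, col %d), %d x %d px\n",
              x$row0, x$col0, x$height, x$width))
  invisible(x)
}

#' Locate the central plot by minimum-boundary search
#'
#' Finds the placement of a fixed-size window whose two boundary rows (and,
#' independently, boundary columns) contain the fewest vegetation pixels:
#' plot boundaries fall in the low-vegetation gaps between plots. For every
#' candidate origin `i` the objective is
#' `smoothed[i] + smoothed[i + height - 1]` on the smoothed row profile
#' (likewise for columns with `width`), and the argmin is taken. Tied minima
#' return the median index of the tied set, so a frame full of ties yields
#' the centered placement (frames are acquired centered on a plot).
#'
#' @param mask a `vegetation_mask` or logical matrix.
#' @param height,width window size in pixels (defaults 2000 x 3800).
#' @param smooth_window moving-average window for the profiles.
#' @return a [plot_window()].
#' @seealso [crop_plot()], [white_pixel_profile()]
#' @export
locate_plot <- function(mask, height = 2000, width = 3800,
                        smooth_window = 100) {
  m <- if (inherits(mask, "vegetation_mask")) mask$mask else mask
  height <- as.integer(height); width <- as.integer(width)
  if (nrow(m) < height || ncol(m) < width)
    stop(sprintf("image (%d x %d) smaller than plot window (%d x %d)",
                 nrow(m), ncol(m), height, width))
  sr <- white_pixel_profile(m, "row", smooth_window)$smoothed
  sc <- white_pixel_profile(m, "column", smooth_window)$smoothed
  # all placements, evaluated exhaustively (vectorized)
  ri <- seq_len(nrow(m) - height + 1L)
  ci <- seq_len(ncol(m) - width + 1L)
  row_obj <- sr[ri] + sr[ri + height - 1L]
  col_obj <- sc[ci] + sc[ci + width - 1L]
  plot_window(row0 = argmin_median_tie(row_obj) - 1L,
              col0 = argmin_median_tie(col_obj) - 1L,
              height = height, width = width)
}

#' Crop a plot window out of an image
#'
#' @param image H x W x 3 array (or H x W matrix).
#' @param window a [plot_window()] lying fully inside the image.
#' @return the cropped array, exactly `height x width` pixels.
#' @export
crop_plot <- function(image, window) {
  d <- dim(image)
  if (window$row0 < 0L || window$col0 < 0L ||
      window$row0 + window$height > d[1] || window$col0 + window$width > d[2])
    stop("plot window out of image bounds")
  rows <- (window$row0 + 1L):(window$row0 + window$height)
  cols <- (window$col0 + 1L):(window$col0 + window$width)
  if (length(d) == 3L) image[rows, cols, , drop = FALSE]
  else image[rows, cols, drop = FALSE]
}
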