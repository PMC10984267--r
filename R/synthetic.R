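#' Generate a synthetic field scene with known ground truth
#'
#' Renders an aerial frame a scene the locator and detector can be scored
#' against exactly: a soil-toned background, vegetation everywhere except
#' low-vegetation gap bands, and panicle-toned elliptical blobs at recorded
#' positions. The true plot window is placed at a seeded random offset; the
#' gap bands are *centered on the window boundary* (vegetation stops half a
#' gap inside the window and resumes half a gap outside, where the
#' neighbouring plots begin), which is exactly the geometry the locator's
#' minimum-boundary objective models: both boundary rows of the correct
#' placement sit in profile minima simultaneously.
#'
#' Panicle blobs are rendered in a bright tone band distinct from foliage so
#' the reference blob detector is a clean oracle; photorealism is explicitly
#' not the goal. Blobs keep `min_spacing` pixels of clearance from each other
#' and from the plot border.
#'
#' @param seed integer seed; scenes are pure functions of (seed, parameters).
#' @param image_h,image_w frame size in pixels.
#' @param plot_h,plot_w true plot window size in pixels.
#' @param gap gap-band width in pixels (>= 40 recommended).
#' @param n_panicles number of panicle blobs to place.
#' @param blob_range min/max blob axis length in pixels.
#' @param min_spacing minimum clearance between blob boxes and from the plot
#'   border, in pixels.
#' @param noise_sd per-pixel Gaussian color noise (8-bit units).
#' @return list of class `field_scene`: `image` (H x W x 3, 0-255),
#'   `true_plot` ([plot_window()]), `true_panicles` (plot-frame box
#'   data.frame), `seed`, and the layout parameters.
#' @export
generate_field_scene <- function(seed, image_h = 600, image_w = 800,
                                 plot_h = 300, plot_w = 420, gap = 40,
                                 n_panicles = 25, blob_range = c(8, 16),
                                 min_spacing = 20, noise_sd = 5) {
  half <- gap %/% 2L
  if (plot_h + 2L * gap > image_h || plot_w + 2L * gap > image_w)
    stop("plot does not fit in image with margins >= gap width")
  lo <- blob_range[1]; hi <- blob_range[2]
  margin <- half + min_spacing
  if (n_panicles > 0 &&
      (plot_w - 2L * margin - hi < margin || plot_h - 2L * margin - hi < margin))
    stop("plot too small for the requested blob size and spacing")
  pick <- function(v) v[sample.int(length(v), 1L)]   # size-1-safe sample
  set.seed(as.integer(seed))
  # random plot offset, keeping a full gap inside the frame on every side
  row0 <- pick(gap:(image_h - plot_h - gap))
  col0 <- pick(gap:(image_w - plot_w - gap))

  soil <- c(120, 100, 80)
  leaf <- c(60, 140, 60)
  panicle <- c(220, 200, 110)

  img <- array(0, dim = c(image_h, image_w, 3))
  for (ch in 1:3) img[, , ch] <- soil[ch]

  # vegetation: whole frame except gap bands centered on the plot boundary
  veg <- matrix(TRUE, image_h, image_w)
  band <- function(center, n) pmax(1L, center - half + 1L):pmin(n, center + half)
  veg[band(row0, image_h), ] <- FALSE                # top boundary (row row0)
  veg[band(row0 + plot_h, image_h), ] <- FALSE       # bottom boundary
  veg[, band(col0, image_w)] <- FALSE
  veg[, band(col0 + plot_w, image_w)] <- FALSE
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[veg] <- leaf[ch]
    img[, , ch] <- plane
  }

  # non-overlapping elliptical panicle blobs inside the vegetated plot core
  boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0))
  tries <- 0L
  while (nrow(boxes) < n_panicles) {
    if ((tries <- tries + 1L) > 200L * max(1L, n_panicles))
      stop("infeasible layout: cannot place ", n_panicles,
           " non-overlapping panicles")
    ax <- pick(lo:hi); ay <- pick(lo:hi)
    # plot-frame box, >= margin from the window border
    x0 <- pick(margin:(plot_w - margin - ax))
    y0 <- pick(margin:(plot_h - margin - ay))
    cand <- data.frame(x_min = x0, y_min = y0, x_max = x0 + ax, y_max = y0 + ay)
    if (nrow(boxes) > 0L) {
      grown <- data.frame(x_min = boxes$x_min - min_spacing,
                          y_min = boxes$y_min - min_spacing,
                          x_max = boxes$x_max + min_spacing,
                          y_max = boxes$y_max + min_spacing)
      sep <- all(box_iou(cand, grown) == 0)
      if (!sep) next
    }
    boxes <- rbind(boxes, cand)
    # render the ellipse inscribed in the box (image coordinates)
    cy <- row0 + y0 + ay / 2; cx <- col0 + x0 + ax / 2
    rr <- (row0 + y0 + 1L):(row0 + y0 + ay)
    cc <- (col0 + x0 + 1L):(col0 + x0 + ax)
    d2 <- outer(((rr - 0.5) - cy) / (ay / 2), ((cc - 0.5) - cx) / (ax / 2),
                function(u, v) u^2 + v^2)
    inside <- d2 <= 1
    for (ch in 1:3) {
      patch <- img[rr, cc, ch]
      patch[inside] <- panicle[ch]
      img[rr, cc, ch] <- patch
    }
  }

  if (noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 255)   # img first: pmin/pmax keep its dim

  structure(list(image = img,
                 true_plot = plot_window(row0, col0, plot_h, plot_w),
                 true_panicles = boxes,
                 seed = as.integer(seed),
                 params = list(image_h = image_h, image_w = image_w,
                               plot_h = plot_h, plot_w = plot_w, gap = gap,
                               n_panicles = n_panicles,
                               blob_range = blob_range,
                               min_spacing = min_spacing,
                               noise_sd = noise_sd)),
            class = "field_scene")
}

#' Generate a logistic panicle-count series with analytic trait truth
#'
#' Simulates one plot's panicle-count time series as a logistic growth curve
#' \deqn{c(t) = K / (1 + e^{-r (t - t_0)})}
#' observed daily at t = 0, ..., `n_dates` - 1 with additive Gaussian noise,
#' rounded to non-negative integer counts. The analytic heading date for a
#' fraction f is the logistic quantile crossing
#' \deqn{t_f = t_0 + \log(f / (1 - f)) / r,}
#' clipped to the sampled range; the analytic heading stage is
#' `t_0.8 - t_0.1 = log(36) / r`, independent of K and t0.
#'
#' Defaults emulate one season's acquisition campaign: 42 daily flights, a
#' plot reaching about 120 panicles, and a heading stage of about ten days
#' (r = 0.35).
#'
#' @param seed integer seed.
#' @param K carrying capacity (maximum expected count), > 0.
#' @param r logistic steepness per day, > 0.
#' @param t0 inflection day (50% crossing).
#' @param n_dates number of daily observations.
#' @param sigma count noise standard deviation (absolute; the trait-recovery
#'   regime of interest is sigma <= 0.03 K).
#' @param plot_id identifier given to the curve.
#' @return list of class `simulated_series`: `curve` ([growth_curve()]),
#'   `true_traits` (analytic `hd10/30/50/80`, `heading_stage`, `K`), the
#'   parameters and the seed.
#' @export
generate_series <- function(seed, K = 120, r = 0.35, t0 = 20, n_dates = 42,
                            sigma = 0, plot_id = "sim") {
  if (K <= 0 || r <= 0) stop("logistic parameters require K > 0 and r > 0")
  set.seed(as.integer(seed))
  t <- 0:(n_dates - 1L)
  mu <- K / (1 + exp(-r * (t - t0)))
  eps <- if (sigma > 0) stats::rnorm(n_dates, 0, sigma) else 0
  counts <- round(pmax(0, mu + eps))
  clip <- function(x) min(max(x, 0), n_dates - 1L)
  hd_f <- function(f) clip(t0 + log(f / (1 - f)) / r)
  truth <- list(hd10 = hd_f(0.1), hd30 = hd_f(0.3), hd50 = hd_f(0.5),
                hd80 = hd_f(0.8), K = K)
  truth$heading_stage <- truth$hd80 - truth$hd10
  structure(list(curve = growth_curve(plot_id, t, counts),
                 true_traits = truth,
                 params = list(K = K, r = r, t0 = t0, n_dates = n_dates,
                               sigma = sigma),
                 seed = as.integer(seed)),
            class = "simulated_series")
}
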