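#' Tile grid over a plot image
#'
#' Generates the tile origins of a sliding-window tiling. The stride is
#' `round(tile * (1 - overlap_ratio))`; offsets run 0, stride, 2*stride, ...
#' and the final offset is clamped to `extent - tile` so the last tile aligns
#' with the image edge (duplicates removed). Every pixel is covered.
#'
#' With the defaults used for prediction (tile 1000, overlap 0.25) a
#' 3800 x 2000 plot yields x offsets {0, 750, 1500, 2250, 2800} and y offsets
#' {0, 750, 1000}: 15 tiles. Annotation-style tiling is the `overlap_ratio =
#' 0` special case (stride = tile, last tile clamped).
#'
#' @param plot_w,plot_h plot image extent in pixels; must be >= `tile`.
#' @param tile square tile side in pixels.
#' @param overlap_ratio fraction of the tile shared by neighbours, in `[0, 1)`.
#' @return data.frame of class `tile_grid` with 0-based columns `x0`, `y0` and
#'   `size_x`, `size_y`.
#' @export
make_tiles <- function(plot_w, plot_h, tile = 1000, overlap_ratio = 0.25) {
  if (plot_w < tile || plot_h < tile)
    stop(sprintf("tile (%d) larger than plot (%d x %d)", tile, plot_w, plot_h))
  if (overlap_ratio < 0 || overlap_ratio >= 1)
    stop("`overlap_ratio` must be in [0, 1)")
  stride <- max(1L, as.integer(round(tile * (1 - overlap_ratio))))
  offs <- function(extent) {
    last <- as.integer(extent - tile)
    o <- seq.int(0L, last, by = stride)
    unique(c(o, last))
  }
  g <- expand.grid(x0 = offs(plot_w), y0 = offs(plot_h),
                   KEEP.OUT.ATTRS = FALSE)
  g$size_x <- as.integer(tile)
  g$size_y <- as.integer(tile)
  class(g) <- c("tile_grid", "data.frame")
  g
}

#' Scored bounding boxes and detection sets
#'
#' A detection set is a data.frame of axis-aligned boxes (`x_min`, `y_min`,
#' `x_max`, `y_max` in pixels, 0-based half-open, with `x_min < x_max`) and a
#' confidence `score` in `[0, 1]`, tagged with the coordinate `frame` it lives
#' in: `"tile"` (local to one sub-image, with the source tile attached) or
#' `"plot"` (the cropped plot image). The single object class is "panicle".
#'
#' @param boxes data.frame with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `score` (zero-row input allowed).
#' @param frame `"tile"` or `"plot"`.
#' @param source_tile for tile-frame sets, one row of a [make_tiles()] grid
#'   (or a list with `x0`, `y0`).
#' @return object of class `detection_set`.
#' @export
detection_set <- function(boxes = NULL, frame = c("plot", "tile"),
                          source_tile = NULL) {
  frame <- match.arg(frame)
  cols <- c("x_min", "y_min", "x_max", "y_max", "score")
  if (is.null(boxes) || nrow(boxes) == 0L) {
    boxes <- as.data.frame(setNames(rep(list(numeric(0)), 5L), cols))
  } else {
    if (!all(cols %in% names(boxes)))
      stop("boxes need columns ", paste(cols, collapse = ", "))
    boxes <- as.data.frame(boxes)[cols]
    if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max))
      stop("degenerate box: x_min < x_max and y_min < y_max required")
    if (any(boxes$score < 0 | boxes$score > 1))
      stop("scores must lie in [0, 1]")
  }
  rownames(boxes) <- NULL
  structure(list(boxes = boxes, frame = frame, source_tile = source_tile),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("detection_set: %d box(es), frame = %s\n",
              nrow(x$boxes), x$frame))
  invisible(x)
}

#' Number of panicles in a merged detection set
#'
#' @param dets a plot-frame `detection_set` (normally the output of
#'   [merge_tile_detections()]).
#' @return integer count.
#' @export
count_panicles <- function(dets) {
  stopifnot(inherits(dets, "detection_set"))
  if (dets$frame != "plot") stop("counting requires a plot-frame detection set")
  nrow(dets$boxes)
}

#' Lift tile-frame detections to plot coordinates
#'
#' Translates every box by the tile origin and clips to the plot extent when
#' it is known.
#'
#' @param det tile-frame `detection_set`.
#' @param tile the source tile (row of a [make_tiles()] grid); defaults to the
#'   set's `source_tile`.
#' @param plot_w,plot_h optional plot extent for clipping.
#' @return plot-frame `detection_set`.
#' @export
to_global <- function(det, tile = det$source_tile,
                      plot_w = NULL, plot_h = NULL) {
  stopifnot(inherits(det, "detection_set"))
  if (det$frame != "tile")
    stop("`det` is already in the plot frame")
  if (is.null(tile)) stop("no source tile attached or supplied")
  b <- det$boxes
  b$x_min <- b$x_min + tile$x0; b$x_max <- b$x_max + tile$x0
  b$y_min <- b$y_min + tile$y0; b$y_max <- b$y_max + tile$y0
  if (!is.null(plot_w)) { b$x_min <- pmax(0, pmin(b$x_min, plot_w))
                          b$x_max <- pmax(0, pmin(b$x_max, plot_w)) }
  if (!is.null(plot_h)) { b$y_min <- pmax(0, pmin(b$y_min, plot_h))
                          b$y_max <- pmax(0, pmin(b$y_max, plot_h)) }
  keep <- b$x_min < b$x_max & b$y_min < b$y_max
  detection_set(b[keep, , drop = FALSE], frame = "plot")
}

#' Intersection-over-union of axis-aligned boxes
#'
#' IoU = area of overlap / area of union, on half-open pixel boxes. With two
#' data.frames of boxes the full pairwise matrix is returned.
#'
#' @param a,b data.frames (or single rows) with `x_min`, `y_min`, `x_max`,
#'   `y_max`.
#' @return numeric matrix `nrow(a)` x `nrow(b)` (a scalar for 1 x 1).
#' @examples
#' box_iou(data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10),
#'         data.frame(x_min = 5, y_min = 0, x_max = 15, y_max = 10))  # 1/3
#' @export
box_iou <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  ix <- pmax(0, outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax))
  iy <- pmax(0, outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  un <- outer(area_a, area_b, `+`) - inter
  out <- ifelse(un > 0, inter / un, 0)
  if (length(out) == 1L) out[1] else out
}

#' Greedy non-maximum suppression
#'
#' Sorts boxes by descending score, repeatedly keeps the top box and discards
#' every remaining box whose IoU with it exceeds `iou_threshold`. Survivors
#' are an unmodified subset of the input. Score ties break to the larger box
#' area, then input order, making the output deterministic.
#'
#' @param dets plot-frame `detection_set`.
#' @param iou_threshold suppression threshold (merge stage default 0.25).
#' @return `detection_set` of the kept boxes.
#' @export
nms <- function(dets, iou_threshold = 0.25) {
  stopifnot(inherits(dets, "detection_set"))
  if (dets$frame != "plot") stop("nms operates on plot-frame detections")
  b <- dets$boxes
  n <- nrow(b)
  if (n == 0L) return(dets)
  area <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  ord <- order(-b$score, -area, seq_len(n))
  alive <- rep(TRUE, n)
  keep <- logical(n)
  iou_m <- matrix(box_iou(b, b), n, n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive <- alive & (iou_m[i, ] <= iou_threshold)
    alive[i] <- FALSE
  }
  detection_set(b[keep, , drop = FALSE], frame = "plot")
}

#' Merge per-tile detections into one plot-level set
#'
#' Lifts each tile's detections to plot coordinates, drops boxes below the
#' confidence threshold, and removes cross-tile duplicates with greedy NMS.
#' This is the merge stage of sliced inference; the detector's own internal
#' NMS (deduplication within a tile) is the backend's responsibility.
#'
#' @param per_tile list of tile-frame `detection_set`s, each carrying its
#'   source tile.
#' @param conf_threshold minimum score kept (prediction default 0.3).
#' @param merge_iou NMS threshold for cross-tile duplicates (default 0.25).
#' @param plot_w,plot_h optional plot extent for clipping lifted boxes.
#' @return plot-frame `detection_set`.
#' @export
merge_tile_detections <- function(per_tile, conf_threshold = 0.3,
                                  merge_iou = 0.25,
                                  plot_w = NULL, plot_h = NULL) {
  if (length(per_tile) == 0L) return(detection_set(frame = "plot"))
  lifted <- lapply(per_tile, function(d) {
    if (!inherits(d, "detection_set") || d$frame != "tile")
      stop("merge_tile_detections expects tile-frame detection sets")
    to_global(d, plot_w = plot_w, plot_h = plot_h)$boxes
  })
  all_boxes <- do.call(rbind, lifted)
  all_boxes <- all_boxes[all_boxes$score >= conf_threshold, , drop = FALSE]
  # canonical order before NMS: the merged set is then independent of tile
  # order even when scores tie
  ord <- order(-all_boxes$score, all_boxes$x_min, all_boxes$y_min,
               all_boxes$x_max, all_boxes$y_max)
  nms(detection_set(all_boxes[ord, , drop = FALSE], frame = "plot"), merge_iou)
}
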