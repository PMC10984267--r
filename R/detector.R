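#' Reference blob detector configuration
#'
#' The reference detector finds panicles in synthetic tiles by brightness
#' thresholding and connected components. Synthetic panicles are rendered
#' bright (mean intensity well above foliage and soil), so a single channel
#' threshold separates them cleanly; each connected component whose area lies
#' in `[min_area, max_area]` becomes one box with a fixed confidence.
#'
#' `drop_border` discards components whose bounding box touches the tile
#' edge: a panicle cut by a tile boundary appears whole in a neighbouring
#' tile whenever the tiling overlap exceeds the panicle size, and keeping the
#' truncated fragment would seed duplicate (low-IoU) boxes that merge NMS
#' cannot collapse.
#'
#' @param brightness_min minimum mean RGB intensity (0-255) of panicle pixels.
#' @param min_area,max_area component area bounds in px^2.
#' @param fixed_score confidence attached to every emitted box.
#' @param drop_border drop components touching the tile edge (default TRUE).
#' @return a list of class `blob_detector_config`.
#' @export
blob_detector_config <- function(brightness_min = 140, min_area = 10,
                                 max_area = 5000, fixed_score = 0.9,
                                 drop_border = TRUE) {
  stopifnot(min_area > 0, min_area < max_area,
            fixed_score >= 0, fixed_score <= 1)
  structure(list(brightness_min = brightness_min, min_area = min_area,
                 max_area = max_area, fixed_score = fixed_score,
                 drop_border = drop_border),
            class = "blob_detector_config")
}

#' Detect bright blobs in one tile
#'
#' Deterministic reference detector: thresholds the tile's mean-RGB
#' brightness, labels connected components (via [EBImage::bwlabel()]) and
#' emits one tile-frame box per component within the configured area range.
#' Identical tiles always yield identical detection sets.
#'
#' @param tile H x W x 3 array, intensities 0-255.
#' @param cfg a [blob_detector_config()].
#' @param source_tile optional tile descriptor attached to the output.
#' @return tile-frame `detection_set`.
#' @export
reference_blob_detect <- function(tile, cfg = blob_detector_config(),
                                  source_tile = NULL) {
  stopifnot(length(dim(tile)) == 3L)
  bright <- (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
  fg <- bright >= cfg$brightness_min
  if (!any(fg))
    return(detection_set(frame = "tile", source_tile = source_tile))
  lab <- EBImage::bwlabel(fg * 1)
  n_lab <- max(lab)
  rows <- row(lab)[lab > 0]; cols <- col(lab)[lab > 0]; ids <- lab[lab > 0]
  area <- tabulate(ids, nbins = n_lab)
  # half-open 0-based boxes: [min-1, max) in each axis
  x_min <- tapply(cols, ids, min) - 1L
  x_max <- tapply(cols, ids, max)
  y_min <- tapply(rows, ids, min) - 1L
  y_max <- tapply(rows, ids, max)
  keep <- area >= cfg$min_area & area <= cfg$max_area
  if (cfg$drop_border) {
    h <- dim(tile)[1]; w <- dim(tile)[2]
    keep <- keep & x_min > 0 & y_min > 0 & x_max < w & y_max < h
  }
  boxes <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                      x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                      score = cfg$fixed_score)[keep, , drop = FALSE]
  detection_set(boxes, frame = "tile", source_tile = source_tile)
}

#' Detector backends
#'
#' A detector backend is the contract the prediction workflow runs against: a
#' list with a `detect(tile, source_tile)` function returning a tile-frame
#' [detection_set()], a `name`, and the model-internal confidence and NMS IoU
#' thresholds (the trained networks of the original study deduplicate within
#' a tile at IoU 0.5 before the cross-tile merge; the reference blob detector
#' emits disjoint components, so its internal stage is a no-op).
#'
#' `detector_backend("blob")` wraps [reference_blob_detect()];
#' `detector_backend("file", detections = ...)` serves pre-computed per-tile
#' detections loaded with [load_external_detections()], keyed by tile id
#' `"x0_y0"`, so outputs of any trained detector can be plugged in.
#'
#' @param name `"blob"` or `"file"`.
#' @param cfg blob backend: a [blob_detector_config()].
#' @param detections file backend: named list of tile-frame detection sets.
#' @param internal_conf,internal_nms_iou model-internal thresholds recorded in
#'   the contract metadata.
#' @return a list of class `detector_backend`.
#' @export
detector_backend <- function(name = c("blob", "file"),
                             cfg = blob_detector_config(),
                             detections = NULL,
                             internal_conf = 0.3, internal_nms_iou = 0.5) {
  name <- match.arg(name)
  detect <- switch(name,
    blob = function(tile, source_tile = NULL)
      reference_blob_detect(tile, cfg, source_tile),
    file = {
      if (is.null(detections)) stop("file backend needs `detections`")
      function(tile, source_tile = NULL) {
        key <- sprintf("%d_%d", source_tile$x0, source_tile$y0)
        d <- detections[[key]]
        if (is.null(d))
          detection_set(frame = "tile", source_tile = source_tile)
        else detection_set(d$boxes, frame = "tile", source_tile = source_tile)
      }
    })
  structure(list(name = name, detect = detect,
                 internal_conf = internal_conf,
                 internal_nms_iou = internal_nms_iou),
            class = "detector_backend")
}

#' Load externally computed detections
#'
#' Reads per-tile (or per-image) detections from a COCO-JSON results file or
#' a directory of YOLO-format `.txt` files and groups them by tile/image
#' identifier as tile-frame detection sets.
#'
#' @param path a `.json` COCO detections file, or a directory containing one
#'   `<tile_id>.txt` YOLO file per tile.
#' @param tile_w,tile_h tile pixel size, required to denormalize YOLO boxes.
#' @return named list of tile-frame `detection_set`s.
#' @export
load_external_detections <- function(path, tile_w = 1000, tile_h = 1000) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    out <- lapply(files, read_yolo, width = tile_w, height = tile_h)
    names(out) <- tools::file_path_sans_ext(basename(files))
    return(out)
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  read_coco_detections(path)
}
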