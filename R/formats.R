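#' Annotation and detection file formats
#'
#' Detections and ground-truth boxes travel as COCO-JSON or YOLO text, the two
#' formats detector toolchains emit. Both converters are lossless round trips
#' for box geometry and scores (YOLO stores normalized coordinates at full
#' double precision).
#'
#' COCO boxes are `[x, y, w, h]` with a single category `"panicle"`
#' (category_id 1); YOLO rows are `class cx cy w h [score]`, center-size,
#' normalized by the image extent.
#'
#' @name formats
NULL

det_to_coco <- function(det, image_id) {
  b <- det$boxes
  if (nrow(b) == 0L) return(NULL)
  lapply(seq_len(nrow(b)), function(i) list(
    image_id = image_id,
    category_id = 1L,
    bbox = c(b$x_min[i], b$y_min[i],
             b$x_max[i] - b$x_min[i], b$y_max[i] - b$y_min[i]),
    score = b$score[i]))
}

#' Write detections as a COCO-JSON results file
#'
#' @param dets_by_image named list of `detection_set`s; names are image/tile
#'   identifiers.
#' @param path output `.json` path.
#' @export
write_coco_detections <- function(dets_by_image, path) {
  recs <- unlist(lapply(names(dets_by_image), function(id)
    det_to_coco(dets_by_image[[id]], id)), recursive = FALSE)
  if (is.null(recs)) recs <- list()
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-JSON results file
#'
#' @param path `.json` file of COCO detection records.
#' @param frame coordinate frame to tag the sets with.
#' @return named list of `detection_set`s grouped by `image_id`.
#' @export
read_coco_detections <- function(path, frame = "tile") {
  recs <- jsonlite::read_json(path)
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$bbox) || length(r$bbox) != 4L || is.null(r$image_id))
      stop(sprintf("malformed COCO record %d in %s", i, path))
    bb <- as.numeric(r$bbox)
    data.frame(image_id = as.character(r$image_id),
               x_min = bb[1], y_min = bb[2],
               x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
               score = if (is.null(r$score)) 1 else as.numeric(r$score))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(list())
  out <- lapply(split(df, df$image_id), function(d)
    detection_set(d[-1], frame = frame))
  out[unique(df$image_id)]
}

#' Write boxes in YOLO text format
#'
#' One row per box: `class cx cy w h [score]`, normalized to the image
#' extent, full precision.
#'
#' @param det a `detection_set`.
#' @param path output `.txt` path.
#' @param width,height image extent in pixels used for normalization.
#' @param scores include the score column (detections) or not (labels).
#' @export
write_yolo <- function(det, path, width, height, scores = TRUE) {
  b <- det$boxes
  lines <- character(0)
  if (nrow(b) > 0L) {
    cx <- (b$x_min + b$x_max) / 2 / width
    cy <- (b$y_min + b$y_max) / 2 / height
    w <- (b$x_max - b$x_min) / width
    h <- (b$y_max - b$y_min) / height
    fmt <- function(x) formatC(x, format = "g", digits = 17)
    lines <- if (scores)
      sprintf("0 %s %s %s %s %s", fmt(cx), fmt(cy), fmt(w), fmt(h),
              fmt(b$score))
    else sprintf("0 %s %s %s %s", fmt(cx), fmt(cy), fmt(w), fmt(h))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a YOLO text file
#'
#' @param path `.txt` file; rows `class cx cy w h [score]`.
#' @param width,height image extent in pixels.
#' @param frame coordinate frame to tag the set with.
#' @return a `detection_set`.
#' @export
read_yolo <- function(path, width, height, frame = "tile") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(detection_set(frame = frame))
  rows <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) < 5L || anyNA(f))
      stop(sprintf("malformed YOLO record at line %d of %s", i, path))
    cx <- f[2] * width; cy <- f[3] * height
    w <- f[4] * width; h <- f[5] * height
    data.frame(x_min = cx - w / 2, y_min = cy - h / 2,
               x_max = cx + w / 2, y_max = cy + h / 2,
               score = if (length(f) >= 6L) f[6] else 1)
  })
  detection_set(do.call(rbind, rows), frame = frame)
}
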