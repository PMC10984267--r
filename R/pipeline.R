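#' Read / write RGB images
#'
#' PNG is read with the png package, other formats (JPEG, TIFF) through
#' EBImage. Images are returned as H x W x 3 arrays on the 0-255 scale, the
#' representation every function in this package consumes.
#'
#' @param path image file.
#' @return H x W x 3 numeric array, intensities in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    a <- aperm(EBImage::imageData(img), c(2, 1, 3))   # EBImage is W x H x C
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' @rdname read_rgb_image
#' @param image H x W x 3 array, 0-255.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the locate-tile-detect-merge-count-traits
#' workflow. The defaults are the operating point of the reference study
#' design: a 3800 x 2000 px plot window, profile smoothing window 100,
#' 1000 x 1000 tiles with overlap ratio 0.25, prediction confidence
#' threshold 0.3, merge NMS IoU 0.25 and heading fractions
#' \{0.1, 0.3, 0.5, 0.8\}.
#'
#' @param plot_height,plot_width plot window size in pixels.
#' @param smooth_window profile moving-average window.
#' @param tile tile side in pixels.
#' @param overlap_ratio tile overlap fraction in `[0, 1)`.
#' @param conf_threshold minimum detection score kept at merge.
#' @param merge_iou cross-tile NMS IoU threshold.
#' @param fractions heading-date fractions.
#' @param backend a [detector_backend()] (or `"blob"` / `"file"` to build one
#'   with defaults).
#' @param channel_order `"RGB"` or `"BGR"`.
#' @param monotonize monotonize growth curves before trait extraction.
#' @param seed seed recorded in run logs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(plot_height = 2000, plot_width = 3800,
                            smooth_window = 100, tile = 1000,
                            overlap_ratio = 0.25, conf_threshold = 0.3,
                            merge_iou = 0.25,
                            fractions = c(0.1, 0.3, 0.5, 0.8),
                            backend = "blob",
                            channel_order = c("RGB", "BGR"),
                            monotonize = FALSE, seed = 1L) {
  channel_order <- match.arg(channel_order)
  if (is.character(backend)) backend <- detector_backend(backend)
  stopifnot(overlap_ratio >= 0, overlap_ratio < 1,
            conf_threshold >= 0, conf_threshold <= 1,
            merge_iou >= 0, merge_iou <= 1,
            all(fractions > 0), all(fractions <= 1))
  structure(list(plot_height = plot_height, plot_width = plot_width,
                 smooth_window = smooth_window, tile = tile,
                 overlap_ratio = overlap_ratio,
                 conf_threshold = conf_threshold, merge_iou = merge_iou,
                 fractions = fractions, backend = backend,
                 channel_order = channel_order, monotonize = monotonize,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Detect and count panicles in one plot image
#'
#' Tiles the plot image, runs the configured detector backend on every tile,
#' and merges the tile detections (confidence filter, then cross-tile NMS)
#' into one plot-frame detection set.
#'
#' @param plot_img H x W x 3 array (an already-cropped plot image).
#' @param config a [pipeline_config()].
#' @return plot-frame `detection_set`.
#' @export
detect_plot_image <- function(plot_img, config = pipeline_config()) {
  h <- dim(plot_img)[1]; w <- dim(plot_img)[2]
  tiles <- make_tiles(w, h, tile = config$tile,
                      overlap_ratio = config$overlap_ratio)
  per_tile <- lapply(seq_len(nrow(tiles)), function(i) {
    tl <- tiles[i, ]
    sub <- plot_img[(tl$y0 + 1L):(tl$y0 + tl$size_y),
                    (tl$x0 + 1L):(tl$x0 + tl$size_x), , drop = FALSE]
    config$backend$detect(sub, source_tile = tl)
  })
  merge_tile_detections(per_tile, conf_threshold = config$conf_threshold,
                        merge_iou = config$merge_iou,
                        plot_w = w, plot_h = h)
}

#' Build an image manifest from a directory tree
#'
#' Expects the `plot_id/date.png` layout: one sub-directory per plot, one
#' image per acquisition date, named by ISO date.
#'
#' @param dir root directory.
#' @return data.frame with `plot_id`, `date`, `path`.
#' @export
discover_images <- function(dir) {
  plots <- list.dirs(dir, recursive = FALSE)
  rows <- lapply(plots, function(p) {
    imgs <- list.files(p, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                       ignore.case = TRUE, full.names = TRUE)
    if (length(imgs) == 0L) return(NULL)
    data.frame(plot_id = basename(p),
               date = tools::file_path_sans_ext(basename(imgs)),
               path = imgs, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(plot_id = character(0),
                                    date = character(0), path = character(0))
  df[order(df$plot_id, df$date), , drop = FALSE]
}

#' Run the full phenotyping pipeline
#'
#' For every image: locate the central plot, crop it, tile, detect, merge and
#' count; the per-plot counts over dates become growth curves from which the
#' six heading-date traits are extracted. Failures are isolated per image:
#' a corrupt frame produces an error log entry and a missing count, and the
#' run continues.
#'
#' @param manifest data.frame with columns `plot_id`, `date`, and either
#'   `path` (image files) or `image` (a list column of H x W x 3 arrays).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes `counts.csv`,
#'   `traits.csv`, per-image COCO-JSON detections under `detections/`, and a
#'   JSON-lines `run_log.jsonl`.
#' @return list of class `pipeline_result`: `counts` (long data.frame),
#'   `traits` (the trait table), `detections` (named list of detection sets,
#'   key `plot_id/date`), `windows` (located plot windows), `log` (list of
#'   stage records), `errors`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL) {
  manifest <- as.data.frame(manifest)
  log <- list()
  push <- function(...) log[[length(log) + 1L]] <<- list(...)
  push(stage = "config",
       plot = c(config$plot_height, config$plot_width),
       smooth_window = config$smooth_window, tile = config$tile,
       overlap_ratio = config$overlap_ratio,
       conf_threshold = config$conf_threshold, merge_iou = config$merge_iou,
       fractions = config$fractions, backend = config$backend$name,
       seed = config$seed, version = "panicleR 0.1.0")

  counts <- data.frame(plot_id = character(0), date = character(0),
                       count = integer(0))
  detections <- list()
  windows <- list()
  errors <- list()

  for (i in seq_len(nrow(manifest))) {
    id <- as.character(manifest$plot_id[i])
    dt <- as.character(manifest$date[i])
    key <- paste(id, dt, sep = "/")
    res <- tryCatch({
      img <- if ("image" %in% names(manifest)) manifest$image[[i]]
             else read_rgb_image(manifest$path[i])
      cive <- compute_cive(img, config$channel_order)
      veg <- binarize_vegetation(cive)
      win <- locate_plot(veg, height = config$plot_height,
                         width = config$plot_width,
                         smooth_window = config$smooth_window)
      crop <- crop_plot(img, win)
      dets <- detect_plot_image(crop, config)
      list(win = win, dets = dets, n = count_panicles(dets))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
      push(stage = "image", image = key, status = "error",
           message = conditionMessage(res))
      next
    }
    counts <- rbind(counts, data.frame(plot_id = id, date = dt,
                                       count = res$n))
    detections[[key]] <- res$dets
    windows[[key]] <- res$win
    push(stage = "image", image = key, status = "ok",
         window = unlist(res$win[c("row0", "col0", "height", "width")]),
         count = res$n)
  }

  traits <- if (nrow(counts) > 0L)
    traits_table(build_growth_curves(counts), fractions = config$fractions,
                 monotonize = config$monotonize)
  else data.frame(plot_id = character(0))
  push(stage = "traits", n_plots = nrow(traits))

  out <- structure(list(counts = counts, traits = traits,
                        detections = detections, windows = windows,
                        log = log, errors = errors),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' @rdname run_pipeline
#' @param result a `pipeline_result`.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$counts, file.path(out_dir, "counts.csv"),
                   row.names = FALSE)
  utils::write.csv(result$traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE, na = "")
  det_dir <- file.path(out_dir, "detections")
  dir.create(det_dir, showWarnings = FALSE)
  for (key in names(result$detections))
    write_coco_detections(result$detections[key],
                          file.path(det_dir, paste0(gsub("/", "_", key),
                                                    ".json")))
  con <- file(file.path(out_dir, "run_log.jsonl"), "w")
  on.exit(close(con))
  for (entry in result$log)
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d image(s) processed, %d failed, %d plot(s)\n",
              nrow(x$counts), length(x$errors), nrow(x$traits)))
  invisible(x)
}
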