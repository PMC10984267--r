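#' Root mean squared counting error
#'
#' `sqrt(mean((y - y_hat)^2))` over per-image (manual, predicted) panicle
#' count pairs.
#'
#' @param y manual counts.
#' @param y_hat predicted counts, same length.
#' @return non-negative scalar.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) == 0L) stop("rmse needs at least one count pair")
  if (length(y) != length(y_hat)) stop("count vectors differ in length")
  sqrt(mean((y - y_hat)^2))
}

#' Coefficient of determination for counts
#'
#' `1 - SS_res / SS_tot`. Unlike a squared correlation this can be negative:
#' a predictor worse than the constant mean scores below zero.
#'
#' @param y manual counts (must not be all identical).
#' @param y_hat predicted counts.
#' @return scalar `<= 1`.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) < 2L) stop("r_squared needs at least two count pairs")
  if (length(y) != length(y_hat)) stop("count vectors differ in length")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("degenerate input: all manual counts identical (zero SS_tot)")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Match predictions to ground truth at an IoU threshold
#'
#' Greedy single matching: predictions are processed in descending score;
#' each is matched to the not-yet-matched ground-truth box with the highest
#' IoU, provided that IoU reaches `iou_threshold` (a true positive);
#' otherwise it is a false positive. Unmatched ground truths are false
#' negatives. Equal-IoU ties between ground truths break to the lower index.
#'
#' @param preds,gts plot-frame `detection_set`s (ground-truth scores are
#'   ignored).
#' @param iou_threshold match threshold k.
#' @return list of class `match_result`: `score` and `tp` (logical) per
#'   prediction in descending-score order, plus `n_gt`, `n_tp`, `n_fp`,
#'   `n_fn` and the threshold.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  stopifnot(inherits(preds, "detection_set"), inherits(gts, "detection_set"))
  pb <- preds$boxes
  gb <- gts$boxes
  n_gt <- nrow(gb)
  ord <- order(-pb$score, seq_len(nrow(pb)))
  tp <- logical(nrow(pb))
  gt_used <- logical(n_gt)
  if (nrow(pb) > 0L && n_gt > 0L) {
    iou_m <- matrix(box_iou(pb, gb), nrow(pb), nrow(gb))
    for (j in seq_along(ord)) {
      i <- ord[j]
      ious <- iou_m[i, ]
      ious[gt_used] <- -1
      best <- which.max(ious)          # lower index wins ties
      if (length(best) && ious[best] >= iou_threshold) {
        tp[i] <- TRUE
        gt_used[best] <- TRUE
      }
    }
  }
  structure(list(score = pb$score[ord], tp = tp[ord], n_gt = n_gt,
                 n_tp = sum(tp), n_fp = sum(!tp[seq_len(nrow(pb))]),
                 n_fn = n_gt - sum(tp), iou_threshold = iou_threshold),
            class = "match_result")
}

# Pool several per-image match results into one (common score scale assumed).
pool_matches <- function(matches) {
  score <- unlist(lapply(matches, `[[`, "score"))
  tp <- unlist(lapply(matches, `[[`, "tp"))
  ord <- order(-score, seq_along(score))
  structure(list(score = score[ord], tp = tp[ord],
                 n_gt = sum(vapply(matches, `[[`, 0, "n_gt")),
                 n_tp = sum(tp), n_fp = sum(!tp),
                 n_fn = sum(vapply(matches, `[[`, 0, "n_gt")) - sum(tp),
                 iou_threshold = matches[[1]]$iou_threshold),
            class = "match_result")
}

#' Average precision from a match result
#'
#' Area under the precision-recall curve with 101-point interpolation (the
#' COCO convention): precision at each recall point r in 0.00, 0.01, ...,
#' 1.00 is taken as the maximum precision attained at recall >= r, and the
#' 101 values are averaged.
#'
#' @param match a `match_result` with `n_gt >= 1`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(match) {
  if (match$n_gt < 1L) stop("average precision undefined for zero ground truths")
  if (length(match$tp) == 0L || !any(match$tp)) return(0)
  tp_c <- cumsum(match$tp)
  fp_c <- cumsum(!match$tp)
  precision <- tp_c / (tp_c + fp_c)
  recall <- tp_c / match$n_gt
  # max precision at recall >= r, computed right-to-left
  prec_env <- rev(cummax(rev(precision)))
  r_pts <- seq(0, 1, by = 0.01)
  idx <- findInterval(r_pts, recall, left.open = TRUE) + 1L
  p_at <- ifelse(idx <= length(prec_env), prec_env[idx], 0)
  mean(p_at)
}

#' Mean average precision over IoU 0.50 to 0.95
#'
#' Average of AP at the ten IoU thresholds 0.50, 0.55, ..., 0.95 (the
#' standard 50:5:95 convention). `denominator` overrides the divisor should a
#' different normalization be wanted; the default is the number of
#' thresholds.
#'
#' @param preds,gts plot-frame `detection_set`s, or named lists of sets
#'   (matched per image by name, then pooled).
#' @param thresholds IoU thresholds to sweep.
#' @param denominator divisor of the AP sum (default `length(thresholds)`).
#' @return list with `map` and `ap_by_threshold`.
#' @export
map_50_95 <- function(preds, gts, thresholds = seq(0.5, 0.95, by = 0.05),
                      denominator = length(thresholds)) {
  ap <- vapply(thresholds, function(k)
    average_precision(match_images(preds, gts, k)), 0)
  names(ap) <- sprintf("AP@%g", thresholds)
  list(map = sum(ap) / denominator, ap_by_threshold = ap)
}

# match a single pair or per-image named lists, pooling the latter
match_images <- function(preds, gts, iou_threshold) {
  if (inherits(preds, "detection_set"))
    return(match_detections(preds, gts, iou_threshold))
  ids <- union(names(preds), names(gts))
  empty <- detection_set(frame = "plot")
  pool_matches(lapply(ids, function(id)
    match_detections(if (is.null(preds[[id]])) empty else preds[[id]],
                     if (is.null(gts[[id]])) empty else gts[[id]],
                     iou_threshold)))
}

#' Evaluate detections against ground truth
#'
#' Produces the full evaluation summary: per-image count pairs, counting RMSE
#' and R-squared, AP at each IoU threshold and the 50:5:95 mean. Matching is
#' per image; the precision-recall curve pools all images by score.
#'
#' @param preds,gts named lists of plot-frame `detection_set`s keyed by image
#'   id (or two single sets).
#' @param thresholds IoU thresholds for the AP sweep.
#' @return list of class `eval_summary` with `rmse`, `r2`, `ap_by_threshold`,
#'   `map_50_95`, `ap_50` and `count_pairs`.
#' @export
evaluate_detections <- function(preds, gts,
                                thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (inherits(preds, "detection_set")) preds <- list(img = preds)
  if (inherits(gts, "detection_set")) gts <- list(img = gts)
  ids <- union(names(preds), names(gts))
  n_of <- function(l, id) if (is.null(l[[id]])) 0L else nrow(l[[id]]$boxes)
  pairs <- data.frame(
    image_id = ids,
    y = vapply(ids, function(i) n_of(gts, i), 0L),
    y_hat = vapply(ids, function(i) n_of(preds, i), 0L))
  m <- map_50_95(preds, gts, thresholds)
  structure(list(
    rmse = rmse(pairs$y, pairs$y_hat),
    r2 = if (length(ids) >= 2L && stats::var(pairs$y) > 0)
      r_squared(pairs$y, pairs$y_hat) else NA_real_,
    ap_by_threshold = m$ap_by_threshold,
    map_50_95 = m$map,
    ap_50 = m$ap_by_threshold[["AP@0.5"]],
    count_pairs = pairs), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("eval_summary over %d image(s)\n", nrow(x$count_pairs)))
  cat(sprintf("  counting: RMSE = %.4f, R^2 = %s\n", x$rmse, format(x$r2)))
  cat(sprintf("  detection: AP@50 = %.4f, mAP@50:5:95 = %.4f\n",
              x$ap_50, x$map_50_95))
  invisible(x)
}
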