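#' Detection evaluation
#'
#' Matching, precision/recall, average precision at a fixed IOU threshold
#' and greedy non-maximum suppression. Precision = TP/(TP+FP) measures
#' false detections, recall = TP/(TP+FN) measures missed objects, and AP
#' is the area under the precision envelope of the PR curve
#' (all-point interpolation of the integral of P over R). With a single
#' class, mAP equals AP.
#'
#' @name evaluation
NULL

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-confidence box and drops every remaining
#' box whose IOU with it is at or above the threshold.
#'
#' @param boxes data.frame with columns x1, y1, x2, y2, conf
#' @param iou_threshold suppression threshold
#' @return the kept subset of `boxes`, sorted by descending confidence
#' @export
nms <- function(boxes, iou_threshold = 0.45) {
  if (nrow(boxes) <= 1) return(boxes)
  b <- boxes[order(-boxes$conf), , drop = FALSE]
  m <- as.matrix(b[, c("x1", "y1", "x2", "y2")])
  keep <- logical(nrow(b))
  alive <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(b)) {
      rest <- which(alive & seq_len(nrow(b)) > i)
      if (length(rest)) {
        ious <- iou(m[rep(i, length(rest)), , drop = FALSE],
                    m[rest, , drop = FALSE])
        alive[rest[ious >= iou_threshold]] <- FALSE
      }
    }
  }
  b[keep, , drop = FALSE]
}

#' Match detections to ground truth
#'
#' In order of descending confidence, each prediction is matched one-to-one
#' to the not-yet-matched ground-truth box of highest IOU, provided that
#' IOU reaches the threshold. Matched predictions are true positives,
#' unmatched predictions false positives, unmatched ground truth false
#' negatives. IOU ties break toward the lower ground-truth index.
#'
#' @param preds data.frame with x1, y1, x2, y2, conf
#' @param gt matrix or data.frame with columns x1, y1, x2, y2
#' @param iou_threshold matching threshold (default 0.5)
#' @return list with `tp`, `fp`, `fn` counts and `match` — a logical flag
#'   per prediction (in descending-confidence order, with `order` giving
#'   the original row indices)
#' @export
match_detections <- function(preds, gt, iou_threshold = 0.5) {
  gt <- if (is.null(gt) || NROW(gt) == 0) {
    matrix(numeric(0), 0, 4)
  } else {
    as.matrix(as.data.frame(gt)[, 1:4, drop = FALSE])
  }
  ord <- order(-preds$conf)
  np <- nrow(preds)
  matched_gt <- logical(nrow(gt))
  flags <- logical(np)
  if (np && nrow(gt)) {
    pm <- as.matrix(preds[ord, c("x1", "y1", "x2", "y2"), drop = FALSE])
    for (i in seq_len(np)) {
      ious <- iou(pm[rep(i, nrow(gt)), , drop = FALSE], gt)
      ious[matched_gt] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] >= iou_threshold) {
        matched_gt[j] <- TRUE
        flags[i] <- TRUE
      }
    }
  }
  list(tp = sum(flags), fp = np - sum(flags),
       fn = nrow(gt) - sum(matched_gt), match = flags, order = ord)
}

#' Average precision over a dataset
#'
#' Pools every prediction across images, sweeps them in descending
#' confidence, matches greedily per image at the IOU threshold, and
#' integrates the area under the precision envelope (all-point
#' interpolation).
#'
#' @param preds data.frame with columns image, x1, y1, x2, y2, conf
#' @param gt list of per-image ground-truth box matrices (columns
#'   x1, y1, x2, y2), indexed by image id
#' @param iou_threshold matching threshold (default 0.5)
#' @return an object of class `detection_metrics`: counts `tp`, `fp`,
#'   `fn`, final `precision` and `recall`, the `pr_curve` data.frame and
#'   `ap` (= mAP for the single class)
#' @export
average_precision <- function(preds, gt, iou_threshold = 0.5) {
  n_gt <- sum(vapply(gt, NROW, 0L))
  if (n_gt == 0) stop("average precision is undefined with zero ground-truth boxes")
  # per-image greedy matching produces a TP flag per prediction; the flags
  # must be assigned sweeping confidences globally, so match per image in
  # global confidence order
  matched <- lapply(gt, function(g) logical(NROW(g)))
  ord <- order(-preds$conf)
  flags <- logical(nrow(preds))
  for (i in ord) {
    im <- preds$image[i]
    g <- gt[[im]]
    if (is.null(g) || NROW(g) == 0) next
    g <- as.matrix(as.data.frame(g)[, 1:4, drop = FALSE])
    pm <- as.matrix(preds[i, c("x1", "y1", "x2", "y2"), drop = FALSE])
    ious <- iou(pm[rep(1, nrow(g)), , drop = FALSE], g)
    ious[matched[[im]]] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_threshold) {
      matched[[im]][j] <- TRUE
      flags[i] <- TRUE
    }
  }
  fl <- flags[ord]
  tp_cum <- cumsum(fl)
  fp_cum <- cumsum(!fl)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  ap <- ap_from_pr(recall, precision)
  tp <- sum(fl); fp <- sum(!fl)
  structure(list(tp = tp, fp = fp, fn = n_gt - tp,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = tp / n_gt,
                 pr_curve = data.frame(recall = recall, precision = precision),
                 ap = ap, map = ap),
            class = "detection_metrics")
}

# all-point interpolation: area under the running-max (from the right)
# precision envelope
ap_from_pr <- function(recall, precision) {
  if (!length(recall)) return(0)
  r <- c(0, recall)
  p <- c(1, precision)
  env <- rev(cummax(rev(p)))
  sum(diff(r) * env[-1])
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat("Detection metrics (single class)\n")
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  AP@0.5 %.4f\n",
              x$precision, x$recall, x$ap))
  invisible(x)
}

#' Evaluate a model on an annotated dataset
#'
#' Runs inference image by image (decode + NMS), matches against the
#' annotations and aggregates into [average_precision()] metrics.
#'
#' @param model a [detector()]
#' @param images list of (3, H, W) arrays or a single (N, 3, H, W) array,
#'   pixel values in \[0, 1\]
#' @param gt list of per-image ground-truth box matrices
#' @param conf_threshold decoding confidence threshold
#' @param nms_threshold NMS IOU threshold
#' @param iou_threshold matching IOU threshold
#' @return a `detection_metrics` object
#' @export
evaluate <- function(model, images, gt, conf_threshold = 0.05,
                     nms_threshold = 0.45, iou_threshold = 0.5) {
  if (is.array(images) && length(dim(images)) == 4) {
    images <- lapply(seq_len(dim(images)[1]), function(i) {
      images[i, , , , drop = FALSE]
    })
  } else {
    images <- lapply(images, function(im) {
      if (length(dim(im)) == 3) array(im, c(1, dim(im))) else im
    })
  }
  if (!length(images)) stop("empty dataset")
  stopifnot(length(images) == length(gt))
  dets <- list()
  for (i in seq_along(images)) {
    d <- detect(model, images[[i]], conf_threshold, nms_threshold)
    if (nrow(d)) {
      d$image <- i
      dets[[length(dets) + 1]] <- d
    }
  }
  preds <- if (length(dets)) {
    do.call(rbind, dets)
  } else {
    data.frame(image = integer(), x1 = numeric(), y1 = numeric(),
               x2 = numeric(), y2 = numeric(), conf = numeric())
  }
  average_precision(preds, gt, iou_threshold)
}

#' Write a metrics report
#'
#' @param metrics a `detection_metrics` object
#' @param json_path path for the JSON summary (counts, precision, recall,
#'   AP); `NULL` to skip
#' @param pr_csv_path path for the PR-curve table; `NULL` to skip
#' @return invisibly, the metrics
#' @export
write_metrics <- function(metrics, json_path = NULL, pr_csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(metrics[c("tp", "fp", "fn", "precision", "recall",
                                   "ap")],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(pr_csv_path)) {
    utils::write.csv(metrics$pr_curve, pr_csv_path, row.names = FALSE)
  }
  invisible(metrics)
}
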