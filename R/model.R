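#' Build the wheat-ear detector
#'
#' Assembles the ASB backbone, the PANet-style neck and the three YOLO
#' heads into a single trainable model.
#'
#' @param spec backbone specification ([default_backbone_spec()]); use
#'   `default_backbone_spec(width_mult = )` for width-reduced models
#' @param neck_widths per-level channel counts after fusion (default the
#'   backbone tap widths)
#' @param anchors 9 x 2 anchor matrix ([default_anchors()] or
#'   [fit_anchors()])
#' @param input_size square input side in pixels (must be divisible by 32)
#' @param num_classes number of object classes (1: wheat ear)
#' @param seed integer seed for weight initialization
#' @return a detector model for [model_forward()], [detect()], [train()]
#'   and [evaluate()]
#' @export
detector <- function(spec = default_backbone_spec(), neck_widths = NULL,
                     anchors = default_anchors(), input_size = 1024,
                     num_classes = 1, seed = 0) {
  stopifnot(input_size %% 32 == 0, nrow(anchors) == 9)
  set.seed(seed)
  tap_ch <- vapply(spec$taps, function(i) spec$stages[[i]]$out_channels, 0L)
  if (is.null(neck_widths)) neck_widths <- tap_ch
  bb <- layer_backbone(spec)
  nk <- layer_neck(tap_ch, neck_widths)
  hd <- layer_heads(neck_widths, num_classes)
  new_module("earnet_detector", children = list(bb, nk, hd),
             backbone = bb, neck = nk, heads = hd,
             anchors = anchors, input_size = as.integer(input_size),
             num_classes = as.integer(num_classes), spec = spec,
             neck_widths = neck_widths, seed = seed)
}

#' @export
nn_forward.earnet_detector <- function(m, x, training = FALSE) {
  taps <- nn_forward(m$backbone, x, training)
  fused <- nn_forward(m$neck, taps, training)
  nn_forward(m$heads, fused, training)
}

#' @export
nn_backward.earnet_detector <- function(m, dy) {
  d <- nn_backward(m$heads, dy)
  d <- nn_backward(m$neck, d)
  nn_backward(m$backbone, d)
}

#' Raw multi-level predictions for an image batch
#'
#' @param model a [detector()]
#' @param x (N, 3, H, W) array, pixel values scaled to \[0, 1\]
#' @param training use batch statistics in normalization layers?
#' @return list of three (N, C, H, W) raw prediction arrays (P3, P4, P5)
#' @export
model_forward <- function(model, x, training = FALSE) {
  lapply(nn_forward(model, fm_from_array(x), training), fm_to_array)
}

#' Detect objects in images
#'
#' Runs the model, decodes the raw predictions and applies greedy NMS
#' per image.
#'
#' @param model a [detector()]
#' @param x (N, 3, H, W) array in \[0, 1\]
#' @param conf_threshold minimum confidence
#' @param nms_threshold IOU threshold for suppression
#' @return a data.frame of boxes (`image, x1, y1, x2, y2, conf, class`)
#' @export
detect <- function(model, x, conf_threshold = 0.25, nms_threshold = 0.45) {
  preds <- model_forward(model, x)
  boxes <- decode(preds, model$anchors, model$input_size, conf_threshold)
  parts <- lapply(split(boxes, boxes$image), nms, iou_threshold = nms_threshold)
  out <- do.call(rbind, parts)
  if (is.null(out)) boxes else out
}

## ---- target assignment ----

#' Assign ground-truth boxes to anchors and grid cells
#'
#' Each ground-truth box is matched by shape IOU (boxes centred on each
#' other) against the 9 anchors; the best anchor is always positive, and
#' any other anchor with shape IOU at or above `iou_threshold` is an
#' additional positive. A positive lands in the grid cell of the box
#' center on the anchor's pyramid level. When two boxes contend for the
#' same (cell, anchor) slot the higher shape IOU wins.
#'
#' @param gt list (one element per image) of box matrices with columns
#'   x1, y1, x2, y2 (may have zero rows)
#' @param anchors 9 x 2 anchor matrix
#' @param input_size input image side in pixels
#' @param iou_threshold shape-IOU threshold for extra positives
#'   (default 0.5)
#' @return a data.frame of positives: `image, level, anchor, ci, cj`
#'   (1-based cell row/col), raw-offset targets `tx, ty, tw, th` and the
#'   ground-truth geometry `gx1, gy1, gx2, gy2`
#' @export
assign_targets <- function(gt, anchors, input_size, iou_threshold = 0.5) {
  strides <- c(8, 16, 32)
  rows <- list()
  for (im in seq_along(gt)) {
    g <- gt[[im]]
    if (is.null(g) || nrow(g) == 0) next
    g <- as_box_matrix(g)
    wh <- cbind(g[, 3] - g[, 1], g[, 4] - g[, 2])
    si <- shape_iou(wh, anchors) # nGT x 9
    for (bi in seq_len(nrow(g))) {
      pos_anchors <- union(which.max(si[bi, ]),
                           which(si[bi, ] >= iou_threshold))
      for (aa in pos_anchors) {
        lvl <- (aa - 1) %/% 3 + 1
        slot <- (aa - 1) %% 3 + 1
        s <- strides[lvl]
        cx <- (g[bi, 1] + g[bi, 3]) / 2
        cy <- (g[bi, 2] + g[bi, 4]) / 2
        cj <- min(max(floor(cx / s), 0), input_size / s - 1) # 0-based col
        ci <- min(max(floor(cy / s), 0), input_size / s - 1) # 0-based row
        rows[[length(rows) + 1]] <- data.frame(
          image = im, level = lvl, anchor = slot, ci = ci + 1, cj = cj + 1,
          tx = cx / s - cj, ty = cy / s - ci,
          tw = log(wh[bi, 1] / anchors[aa, 1]),
          th = log(wh[bi, 2] / anchors[aa, 2]),
          gx1 = g[bi, 1], gy1 = g[bi, 2], gx2 = g[bi, 3], gy2 = g[bi, 4],
          shape_iou = si[bi, aa])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(image = integer(), level = integer(), anchor = integer(),
                      ci = integer(), cj = integer(), tx = numeric(),
                      ty = numeric(), tw = numeric(), th = numeric(),
                      gx1 = numeric(), gy1 = numeric(), gx2 = numeric(),
                      gy2 = numeric(), shape_iou = numeric()))
  }
  tgts <- do.call(rbind, rows)
  # resolve slot contention: keep the best shape IOU per (image, level,
  # anchor, cell)
  key <- paste(tgts$image, tgts$level, tgts$anchor, tgts$ci, tgts$cj)
  ord <- order(key, -tgts$shape_iou)
  tgts <- tgts[ord, ]
  tgts[!duplicated(key[ord]), , drop = FALSE]
}

#' Loss weights
#'
#' @param box weight of the CIOU box-regression term
#' @param objectness weight of the objectness binary cross-entropy
#' @param class weight of the classification binary cross-entropy
#' @return a named list
#' @export
loss_weights <- function(box = 0.05, objectness = 1, class = 0.5) {
  stopifnot(box >= 0, objectness >= 0, class >= 0)
  list(box = box, objectness = objectness, class = class)
}

# Composite detection loss over raw predictions (internal fm matrices).
# preds: list of fm matrices (rows h*w*n, cols 3*(5+nc));
# targets: data.frame from assign_targets().
# Returns list(total, components, dpreds).
detection_loss_fm <- function(preds, targets, anchors, input_size,
                              weights = loss_weights(), num_classes = 1) {
  strides <- c(8, 16, 32)
  per <- 5 + num_classes
  dpreds <- lapply(preds, function(p) fm_like(p * 0, p))
  n_obj <- 0
  obj_loss <- 0
  box_loss <- 0
  cls_loss <- 0
  npos <- nrow(targets)

  bce <- function(z, t) ifelse(z > 0, z - z * t + log1p(exp(-z)),
                               -z * t + log1p(exp(z)))

  for (l in seq_along(preds)) {
    p <- preds[[l]]
    h <- fm_h(p); w <- fm_w(p); nimg <- fm_n(p)
    s <- strides[l]
    obj_cols <- (0:2) * per + 5
    zobj <- p[, obj_cols, drop = FALSE]
    tobj <- zobj * 0
    tl <- targets[targets$level == l, , drop = FALSE]
    rows <- integer(0)
    if (nrow(tl)) {
      # fm row index for (ci, cj, image): h_idx + H*(w_idx + W*(n-1))
      rows <- tl$ci + h * (tl$cj - 1) + h * w * (tl$image - 1)
      acols <- (tl$anchor - 1) * per
      for (kk in seq_len(nrow(tl))) {
        r <- rows[kk]; a0 <- acols[kk]
        anc <- anchors[(l - 1) * 3 + tl$anchor[kk], ]
        tx <- p[r, a0 + 1]; ty <- p[r, a0 + 2]
        tw <- p[r, a0 + 3]; th <- p[r, a0 + 4]
        sx <- sigmoid(tx); sy <- sigmoid(ty)
        cx <- (tl$cj[kk] - 1 + sx) * s
        cy <- (tl$ci[kk] - 1 + sy) * s
        bw <- anc[1] * exp(min(tw, 10))
        bh <- anc[2] * exp(min(th, 10))
        gt <- matrix(c(tl$gx1[kk], tl$gy1[kk], tl$gx2[kk], tl$gy2[kk]), 1)
        pred_box <- c(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
        box_loss <- box_loss + ciou_loss(pred_box, gt)
        gr <- ciou_grad_cxcywh(cx, cy, bw, bh, gt)[1, ] / max(npos, 1)
        # chain to raw offsets
        dpreds[[l]][r, a0 + 1] <- dpreds[[l]][r, a0 + 1] +
          weights$box * gr[1] * s * sx * (1 - sx)
        dpreds[[l]][r, a0 + 2] <- dpreds[[l]][r, a0 + 2] +
          weights$box * gr[2] * s * sy * (1 - sy)
        dpreds[[l]][r, a0 + 3] <- dpreds[[l]][r, a0 + 3] +
          weights$box * gr[3] * bw
        dpreds[[l]][r, a0 + 4] <- dpreds[[l]][r, a0 + 4] +
          weights$box * gr[4] * bh
        # objectness target 1 at the positive slot
        tobj[r, tl$anchor[kk]] <- 1
        # class loss (single class: target 1)
        for (cc in seq_len(num_classes)) {
          tcls <- if (cc == 1) 1 else 0
          zc <- p[r, a0 + 5 + cc]
          cls_loss <- cls_loss + bce(zc, tcls)
          dpreds[[l]][r, a0 + 5 + cc] <- dpreds[[l]][r, a0 + 5 + cc] +
            weights$class * (sigmoid(zc) - tcls) / max(npos, 1)
        }
      }
    }
    obj_loss <- obj_loss + sum(bce(zobj, tobj))
    dobj <- (sigmoid(zobj) - tobj)
    n_obj <- n_obj + length(zobj)
    dpreds[[l]][, obj_cols] <- dpreds[[l]][, obj_cols] + dobj # scaled later
  }
  obj_loss <- obj_loss / n_obj
  for (l in seq_along(dpreds)) {
    obj_cols <- (0:2) * per + 5
    dpreds[[l]][, obj_cols] <- dpreds[[l]][, obj_cols] *
      (weights$objectness / n_obj) +
      0 # box/class grads already include their weights
  }
  box_mean <- if (npos > 0) box_loss / npos else 0
  cls_mean <- if (npos > 0) cls_loss / npos else 0
  total <- weights$box * box_mean + weights$objectness * obj_loss +
    weights$class * cls_mean
  list(total = total,
       components = c(box = box_mean, objectness = obj_loss,
                      class = cls_mean),
       dpreds = dpreds)
}

#' Composite detection loss
#'
#' Box term: mean CIOU loss over the positive (assigned) anchors; objectness
#' term: binary cross-entropy over every anchor slot of every cell;
#' class term: binary cross-entropy at the positives. The total is the
#' weighted sum. With no positives the box and class terms are 0 and the
#' total is still defined.
#'
#' @param preds list of three raw (N, C, H, W) prediction arrays
#' @param targets data.frame from [assign_targets()]
#' @param anchors 9 x 2 anchor matrix
#' @param input_size input side in pixels
#' @param weights a [loss_weights()]
#' @param num_classes number of classes
#' @return list with `total` (scalar) and `components`
#'   (box, objectness, class)
#' @export
detection_loss <- function(preds, targets, anchors, input_size,
                           weights = loss_weights(), num_classes = 1) {
  fms <- lapply(preds, fm_from_array)
  r <- detection_loss_fm(fms, targets, anchors, input_size, weights,
                         num_classes)
  r[c("total", "components")]
}
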