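#' PANet-style neck and YOLO heads
#'
#' The neck fuses the backbone taps with a top-down pass (upsample the
#' deeper level, concatenate with the shallower, fuse with a 1x1
#' convolution) followed by a bottom-up pass (stride-2 3x3 convolution
#' down, concatenate, fuse), keeping each level's spatial size. The three
#' heads are single 1x1 convolutions to `3 * (5 + num_classes)` channels:
#' per anchor a box offset quadruple (tx, ty, tw, th), an objectness logit
#' and the class logits.
#'
#' @name neck_heads
NULL

layer_neck <- function(in_widths, widths, act = "tanhexp") {
  stopifnot(length(in_widths) == 3, length(widths) == 3, all(widths > 0))
  new_module("layer_neck",
             lat5 = lat5 <- conv_bn_act(in_widths[3], widths[3], k = 1, act = act),
             fuse4_td = f4t <- conv_bn_act(widths[3] + in_widths[2], widths[2], k = 1, act = act),
             fuse3_td = f3t <- conv_bn_act(widths[2] + in_widths[1], widths[1], k = 1, act = act),
             up5 = u5 <- layer_upsample2(), up4 = u4 <- layer_upsample2(),
             down3 = d3 <- conv_bn_act(widths[1], widths[1], k = 3, stride = 2, act = act),
             fuse4_bu = f4b <- conv_bn_act(widths[1] + widths[2], widths[2], k = 1, act = act),
             down4 = d4 <- conv_bn_act(widths[2], widths[2], k = 3, stride = 2, act = act),
             fuse5_bu = f5b <- conv_bn_act(widths[2] + widths[3], widths[3], k = 1, act = act),
             children = list(lat5, f4t, f3t, u5, u4, d3, f4b, d4, f5b),
             widths = widths)
}

#' @export
nn_forward.layer_neck <- function(m, x, training = FALSE) {
  p3 <- x[[1]]; p4 <- x[[2]]; p5 <- x[[3]]
  if (2 * fm_h(p5) != fm_h(p4) || 2 * fm_h(p4) != fm_h(p3)) {
    stop("neck expects a stride-8/16/32 pyramid with matched spatial sizes")
  }
  t5 <- nn_forward(m$lat5, p5, training)
  m$c4 <- fm_c(p4); m$c3 <- fm_c(p3) # concat split points for backward
  t4 <- nn_forward(m$fuse4_td,
                   fm_like(cbind(nn_forward(m$up5, t5, training), p4), p4),
                   training)
  t3 <- nn_forward(m$fuse3_td,
                   fm_like(cbind(nn_forward(m$up4, t4, training), p3), p3),
                   training)
  o3 <- t3
  o4 <- nn_forward(m$fuse4_bu,
                   fm_like(cbind(nn_forward(m$down3, o3, training), t4), t4),
                   training)
  o5 <- nn_forward(m$fuse5_bu,
                   fm_like(cbind(nn_forward(m$down4, o4, training), t5), t5),
                   training)
  list(o3, o4, o5)
}

#' @export
nn_backward.layer_neck <- function(m, dy) {
  w <- m$widths
  d5 <- nn_backward(m$fuse5_bu, dy[[3]])
  d_o4 <- nn_backward(m$down4, fm_like(d5[, seq_len(w[2]), drop = FALSE], d5))
  d_t5 <- fm_like(d5[, w[2] + seq_len(w[3]), drop = FALSE], d5)
  d4 <- nn_backward(m$fuse4_bu, fm_like(dy[[2]] + d_o4, d_o4))
  d_o3 <- nn_backward(m$down3, fm_like(d4[, seq_len(w[1]), drop = FALSE], d4))
  d_t4 <- fm_like(d4[, w[1] + seq_len(w[2]), drop = FALSE], d4)
  d_t3 <- fm_like(dy[[1]] + d_o3, d_o3)

  d3 <- nn_backward(m$fuse3_td, d_t3)
  d_up4 <- fm_like(d3[, seq_len(w[2]), drop = FALSE], d3)
  d_p3 <- fm_like(d3[, w[2] + seq_len(m$c3), drop = FALSE], d3)
  d_t4 <- fm_like(d_t4 + nn_backward(m$up4, d_up4), d_t4)

  d4td <- nn_backward(m$fuse4_td, d_t4)
  d_up5 <- fm_like(d4td[, seq_len(w[3]), drop = FALSE], d4td)
  d_p4 <- fm_like(d4td[, w[3] + seq_len(m$c4), drop = FALSE], d4td)
  d_t5 <- fm_like(d_t5 + nn_backward(m$up5, d_up5), d_t5)

  d_p5 <- nn_backward(m$lat5, d_t5)
  list(d_p3, d_p4, d_p5)
}

layer_heads <- function(widths, num_classes = 1, anchors_per_level = 3) {
  per <- anchors_per_level * (5 + num_classes)
  hs <- lapply(widths, function(w) layer_conv1x1(w, per, bias = TRUE))
  new_module("layer_heads", children = hs, heads = hs, per = per,
             num_classes = num_classes, na = anchors_per_level)
}

#' @export
nn_forward.layer_heads <- function(m, x, training = FALSE) {
  lapply(seq_along(x), function(i) nn_forward(m$heads[[i]], x[[i]], training))
}

#' @export
nn_backward.layer_heads <- function(m, dy) {
  lapply(seq_along(dy), function(i) nn_backward(m$heads[[i]], dy[[i]]))
}

## ---- anchors ----

#' Default anchor set
#'
#' Nine square-ish prior box sizes spanning 16 to 256 px, three per pyramid
#' level (smallest to P3, largest to P5), used when no training boxes are
#' available to fit anchors from.
#'
#' @return a 9 x 2 matrix of (width, height) pairs sorted by area
#' @export
default_anchors <- function() {
  s <- c(16, 24, 32, 48, 64, 96, 128, 192, 256)
  cbind(w = s, h = s * 0.9)
}

# IOU of two (w, h) shapes centred on each other
shape_iou <- function(wh, anchors) {
  iw <- outer(wh[, 1], anchors[, 1], pmin)
  ih <- outer(wh[, 2], anchors[, 2], pmin)
  inter <- iw * ih
  inter / (outer(wh[, 1] * wh[, 2], anchors[, 1] * anchors[, 2], "+") - inter)
}

#' Fit anchors to training box sizes
#'
#' K-means clustering of (width, height) pairs under the IOU distance
#' (1 - IOU of the shapes centred on each other), the standard way to pick
#' anchor priors for a YOLO-style detector. Deterministic under `seed`.
#'
#' @param wh a matrix with columns (width, height) of training boxes
#' @param k number of anchors (default 9)
#' @param seed integer seed for the initialization
#' @param iters maximum Lloyd iterations
#' @return a k x 2 anchor matrix sorted by area
#' @export
fit_anchors <- function(wh, k = 9, seed = 1, iters = 100) {
  wh <- as.matrix(wh)[, 1:2, drop = FALSE]
  if (nrow(wh) < k) stop("need at least k = ", k, " boxes, got ", nrow(wh))
  set.seed(seed)
  centers <- wh[sample.int(nrow(wh), k), , drop = FALSE]
  assign_old <- rep(0L, nrow(wh))
  for (it in seq_len(iters)) {
    d <- 1 - shape_iou(wh, centers)
    assign_new <- max.col(-d, ties.method = "first")
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      rows <- assign_new == j
      if (any(rows)) centers[j, ] <- colMeans(wh[rows, , drop = FALSE])
    }
  }
  centers <- centers[order(centers[, 1] * centers[, 2]), , drop = FALSE]
  colnames(centers) <- c("w", "h")
  centers
}

## ---- decoding raw predictions to boxes ----

# raw head channel layout per anchor a (0-based block a*(5+nc)):
# tx, ty, tw, th, obj, class logits...

#' Decode raw head predictions into boxes
#'
#' Applies the YOLO decode: sigmoid cell offsets for the center, anchors
#' scaled by `exp(tw, th)` for the size, confidence =
#' sigmoid(objectness) * sigmoid(class logit). Boxes below the confidence
#' threshold are dropped and the rest are clipped to the image bounds.
#'
#' @param preds list of three (N, C, H, W) raw prediction arrays
#' @param anchors a 9 x 2 anchor matrix (smallest three used on P3)
#' @param input_size input image side length in pixels
#' @param conf_threshold minimum confidence to keep a box
#' @return a data.frame with columns
#'   `image, x1, y1, x2, y2, conf, class` (image = batch index)
#' @export
decode <- function(preds, anchors, input_size, conf_threshold = 0.25) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1)
  out <- list()
  for (l in seq_along(preds)) {
    a <- preds[[l]]
    d <- dim(a) # N C H W
    n <- d[1]; gh <- d[3]; gw <- d[4]
    stride <- input_size / gh
    nc <- d[2] / 3 - 5
    for (ai in 1:3) {
      off <- (ai - 1) * (5 + nc)
      anc <- anchors[(l - 1) * 3 + ai, ]
      tx <- a[, off + 1, , , drop = FALSE]
      ty <- a[, off + 2, , , drop = FALSE]
      tw <- a[, off + 3, , , drop = FALSE]
      th <- a[, off + 4, , , drop = FALSE]
      obj <- sigmoid(a[, off + 5, , , drop = FALSE])
      cls <- sigmoid(a[, off + 6, , , drop = FALSE])
      conf <- as.vector(obj * cls)
      keep <- which(conf >= conf_threshold & conf > 0)
      if (!length(keep)) next
      # index arithmetic: arrays are (N, 1, H, W) -> vector index k maps to
      # n + N*( (h-1) + H*(w-1) )
      k0 <- keep - 1
      nn <- k0 %% n
      hh <- (k0 %/% n) %% gh
      ww <- k0 %/% (n * gh)
      cx <- (ww + sigmoid(as.vector(tx)[keep])) * stride
      cy <- (hh + sigmoid(as.vector(ty)[keep])) * stride
      bw <- anc[1] * exp(pmin(as.vector(tw)[keep], 10))
      bh <- anc[2] * exp(pmin(as.vector(th)[keep], 10))
      x1 <- pmax(0, cx - bw / 2); x2 <- pmin(input_size, cx + bw / 2)
      y1 <- pmax(0, cy - bh / 2); y2 <- pmin(input_size, cy + bh / 2)
      ok <- x2 > x1 & y2 > y1
      if (!any(ok)) next
      out[[length(out) + 1]] <- data.frame(
        image = nn[ok] + 1L, x1 = x1[ok], y1 = y1[ok], x2 = x2[ok],
        y2 = y2[ok], conf = conf[keep][ok], class = 0L)
    }
  }
  if (!length(out)) {
    return(data.frame(image = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), conf = numeric(),
                      class = integer()))
  }
  do.call(rbind, out)
}
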