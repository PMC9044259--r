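#' Bounding-box geometry and regression losses
#'
#' Boxes are axis-aligned rectangles in continuous, half-open, 0-based image
#' coordinates (x right, y down), represented as numeric vectors or matrices
#' with columns `x1, y1, x2, y2` and positive width/height. `iou()` is the
#' intersection-over-union overlap; `iou_loss()`, `giou_loss()` and
#' `ciou_loss()` are the corresponding regression losses. GIOU adds the
#' smallest-enclosing-rectangle penalty, so it stays informative for
#' disjoint boxes; CIOU additionally penalizes the normalized squared
#' distance between box centers (relative to the enclosing box diagonal)
#' and the aspect-ratio mismatch
#' `v = (4/pi^2) (atan(w_gt/h_gt) - atan(w/h))^2` weighted by
#' `alpha = v / ((1 - IOU) + v)`.
#'
#' @param a,b boxes: numeric vectors `c(x1, y1, x2, y2)` or matrices with
#'   those four columns (recycled row-wise)
#' @return numeric vector of values, one per box pair
#' @name box_losses
NULL

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = TRUE)
  b <- as.matrix(b)[, 1:4, drop = FALSE]
  if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2])) {
    stop("degenerate box: need x2 > x1 and y2 > y1")
  }
  b
}

recycle_boxes <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- max(nrow(a), nrow(b))
  list(a = a[rep_len(seq_len(nrow(a)), n), , drop = FALSE],
       b = b[rep_len(seq_len(nrow(b)), n), , drop = FALSE])
}

iou_parts <- function(a, b) {
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  union <- area_a + area_b - inter
  list(inter = inter, union = union, iou = inter / union)
}

#' @rdname box_losses
#' @export
iou <- function(a, b) {
  p <- recycle_boxes(a, b)
  iou_parts(p$a, p$b)$iou
}

#' @rdname box_losses
#' @export
iou_loss <- function(a, b) 1 - iou(a, b)

#' @rdname box_losses
#' @export
giou_loss <- function(a, b) {
  p <- recycle_boxes(a, b)
  o <- iou_parts(p$a, p$b)
  cw <- pmax(p$a[, 3], p$b[, 3]) - pmin(p$a[, 1], p$b[, 1])
  ch <- pmax(p$a[, 4], p$b[, 4]) - pmin(p$a[, 2], p$b[, 2])
  carea <- cw * ch
  1 - o$iou + (carea - o$union) / carea
}

#' @rdname box_losses
#' @export
ciou_loss <- function(a, b) {
  p <- recycle_boxes(a, b)
  o <- iou_parts(p$a, p$b)
  cw <- pmax(p$a[, 3], p$b[, 3]) - pmin(p$a[, 1], p$b[, 1])
  ch <- pmax(p$a[, 4], p$b[, 4]) - pmin(p$a[, 2], p$b[, 2])
  r1sq <- cw^2 + ch^2
  acx <- (p$a[, 1] + p$a[, 3]) / 2; acy <- (p$a[, 2] + p$a[, 4]) / 2
  bcx <- (p$b[, 1] + p$b[, 3]) / 2; bcy <- (p$b[, 2] + p$b[, 4]) / 2
  r2sq <- (acx - bcx)^2 + (acy - bcy)^2
  aw <- p$a[, 3] - p$a[, 1]; ah <- p$a[, 4] - p$a[, 2]
  bw <- p$b[, 3] - p$b[, 1]; bh <- p$b[, 4] - p$b[, 2]
  v <- (4 / pi^2) * (atan(bw / bh) - atan(aw / ah))^2
  alpha <- ifelse(v > 0, v / ((1 - o$iou) + v), 0)
  1 - o$iou + r2sq / r1sq + alpha * v
}

# Gradient of the CIOU loss of the predicted box (cx, cy, w, h) against a
# fixed ground-truth box (matrix gt with columns x1,y1,x2,y2). alpha is
# treated as a constant within the step. Returns an n x 4 matrix
# d(loss)/d(cx, cy, w, h).
ciou_grad_cxcywh <- function(cx, cy, w, h, gt) {
  x1 <- cx - w / 2; x2 <- cx + w / 2
  y1 <- cy - h / 2; y2 <- cy + h / 2
  gx1 <- gt[, 1]; gy1 <- gt[, 2]; gx2 <- gt[, 3]; gy2 <- gt[, 4]
  gw <- gx2 - gx1; gh <- gy2 - gy1
  gcx <- (gx1 + gx2) / 2; gcy <- (gy1 + gy2) / 2

  iw <- pmax(0, pmin(x2, gx2) - pmax(x1, gx1))
  ih <- pmax(0, pmin(y2, gy2) - pmax(y1, gy1))
  inter <- iw * ih
  union <- w * h + gw * gh - inter
  iouv <- inter / union

  # d(inter)/d corners (piecewise, zero when the respective side is not binding)
  act <- inter > 0
  dI_dx1 <- ifelse(act & x1 > gx1, -ih, 0)
  dI_dx2 <- ifelse(act & x2 < gx2, ih, 0)
  dI_dy1 <- ifelse(act & y1 > gy1, -iw, 0)
  dI_dy2 <- ifelse(act & y2 < gy2, iw, 0)
  dA_dx1 <- -h; dA_dx2 <- h; dA_dy1 <- -w; dA_dy2 <- w
  # d(iou) = (dI * union - inter * (dA - dI)) / union^2
  diou_c <- function(dI, dA) (dI * union - inter * (dA - dI)) / union^2
  diou_dx1 <- diou_c(dI_dx1, dA_dx1); diou_dx2 <- diou_c(dI_dx2, dA_dx2)
  diou_dy1 <- diou_c(dI_dy1, dA_dy1); diou_dy2 <- diou_c(dI_dy2, dA_dy2)

  cw <- pmax(x2, gx2) - pmin(x1, gx1)
  chh <- pmax(y2, gy2) - pmin(y1, gy1)
  r1sq <- cw^2 + chh^2
  r2sq <- (cx - gcx)^2 + (cy - gcy)^2
  # d(r2sq/r1sq)
  dcw_dx1 <- ifelse(x1 < gx1, -1, 0); dcw_dx2 <- ifelse(x2 > gx2, 1, 0)
  dch_dy1 <- ifelse(y1 < gy1, -1, 0); dch_dy2 <- ifelse(y2 > gy2, 1, 0)
  dr1_dx1 <- 2 * cw * dcw_dx1; dr1_dx2 <- 2 * cw * dcw_dx2
  dr1_dy1 <- 2 * chh * dch_dy1; dr1_dy2 <- 2 * chh * dch_dy2
  drho_corner <- function(dr1) -r2sq / r1sq^2 * dr1
  drho_dx1 <- drho_corner(dr1_dx1); drho_dx2 <- drho_corner(dr1_dx2)
  drho_dy1 <- drho_corner(dr1_dy1); drho_dy2 <- drho_corner(dr1_dy2)
  drho_dcx <- 2 * (cx - gcx) / r1sq
  drho_dcy <- 2 * (cy - gcy) / r1sq

  # aspect term (alpha constant)
  dv_fac <- (4 / pi^2) * 2 * (atan(gw / gh) - atan(w / h))
  # d atan(w/h)/dw = h/(w^2+h^2); /dh = -w/(w^2+h^2)
  denom <- w^2 + h^2
  dv_dw <- dv_fac * (-h / denom)
  dv_dh <- dv_fac * (w / denom)
  v <- (4 / pi^2) * (atan(gw / gh) - atan(w / h))^2
  alpha <- ifelse(v > 0, v / ((1 - iouv) + v), 0)

  # corner derivatives w.r.t. (cx, cy, w, h): x1 = cx - w/2, x2 = cx + w/2 ...
  # loss = 1 - iou + rho + alpha * v
  dl_dx1 <- -diou_dx1 + drho_dx1
  dl_dx2 <- -diou_dx2 + drho_dx2
  dl_dy1 <- -diou_dy1 + drho_dy1
  dl_dy2 <- -diou_dy2 + drho_dy2
  cbind(cx = dl_dx1 + dl_dx2 + drho_dcx,
        cy = dl_dy1 + dl_dy2 + drho_dcy,
        w = (dl_dx2 - dl_dx1) / 2 + alpha * dv_dw,
        h = (dl_dy2 - dl_dy1) / 2 + alpha * dv_dh)
}

#' Pixel-rasterization IOU oracle
#'
#' Approximates IOU by counting pixel centers on a regular grid laid over
#' the union extent of the two boxes. Independent of the analytic
#' [iou()] path; used to validate the loss family.
#'
#' @param a,b boxes `c(x1, y1, x2, y2)`
#' @param resolution grid points per axis
#' @return approximate IOU in \[0, 1\]
#' @export
iou_rasterized <- function(a, b, resolution = 1000) {
  lo <- c(min(a[1], b[1]), min(a[2], b[2]))
  hi <- c(max(a[3], b[3]), max(a[4], b[4]))
  xs <- seq(lo[1], hi[1], length.out = resolution + 1)
  xs <- (xs[-1] + xs[-length(xs)]) / 2
  ys <- seq(lo[2], hi[2], length.out = resolution + 1)
  ys <- (ys[-1] + ys[-length(ys)]) / 2
  in_a_x <- xs >= a[1] & xs < a[3]; in_a_y <- ys >= a[2] & ys < a[4]
  in_b_x <- xs >= b[1] & xs < b[3]; in_b_y <- ys >= b[2] & ys < b[4]
  n_a <- sum(in_a_x) * sum(in_a_y)
  n_b <- sum(in_b_x) * sum(in_b_y)
  n_i <- sum(in_a_x & in_b_x) * sum(in_a_y & in_b_y)
  n_i / (n_a + n_b - n_i)
}
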