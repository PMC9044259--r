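test_that("iou handles the canonical cases", {
  expect_identical(iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0) # disjoint -> exactly 0
  expect_identical(iou(c(1, 1, 4, 5), c(1, 1, 4, 5)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_true(abs(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) -
                    iou(c(1, 1, 3, 3), c(0, 0, 2, 2))) == 0) # symmetric
  expect_error(iou(c(0, 0, 0, 2), c(1, 1, 3, 3)), "degenerate")
})

test_that("iou_loss and giou_loss match their closed forms", {
  expect_identical(iou_loss(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_identical(iou_loss(c(0, 0, 2, 2), c(5, 5, 7, 7)), 1)
  expect_equal(iou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3)), 6 / 7)
  expect_identical(giou_loss(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  # enclosing box 3x3 = 9, union 7 -> 1 - 1/7 + 2/9
  expect_equal(giou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3)), 68 / 63)
  # far-apart boxes: the enclosing-box penalty pushes past 1
  expect_gt(giou_loss(c(0, 0, 1, 1), c(9, 9, 10, 10)), 1)
})

test_that("ciou_loss adds center-distance and aspect penalties", {
  expect_identical(ciou_loss(c(1, 1, 3, 4), c(1, 1, 3, 4)), 0)
  # concentric, same aspect: only the IOU term remains
  expect_equal(ciou_loss(c(0, 0, 4, 4), c(1, 1, 3, 3)), 1 - 4 / 16)
  # disjoint boxes still produce a center-distance signal: moving the
  # prediction closer strictly reduces the loss where iou_loss is flat
  far <- ciou_loss(c(8, 0, 9, 1), c(0, 0, 1, 1))
  near <- ciou_loss(c(4, 0, 5, 1), c(0, 0, 1, 1))
  expect_lt(near, far)
  expect_identical(iou_loss(c(8, 0, 9, 1), c(0, 0, 1, 1)),
                   iou_loss(c(4, 0, 5, 1), c(0, 0, 1, 1)))
})

test_that("loss family agrees with the pixel-rasterization oracle", {
  set.seed(31)
  dev <- vapply(1:200, function(i) {
    a <- runif(2, 0, 80)
    b <- runif(2, 0, 80)
    boxa <- c(a[1], a[2], a[1] + runif(1, 5, 40), a[2] + runif(1, 5, 40))
    boxb <- c(b[1], b[2], b[1] + runif(1, 5, 40), b[2] + runif(1, 5, 40))
    abs(iou(boxa, boxb) - iou_rasterized(boxa, boxb, resolution = 1000))
  }, 0)
  expect_lte(max(dev), 2e-3) # absolute band around the pixel count
})

test_that("loss ordering and identity properties hold on random pairs", {
  set.seed(32)
  n <- 300
  a <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  a <- cbind(a, a[, 1] + runif(n, 2, 30), a[, 2] + runif(n, 2, 30))
  b <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  b <- cbind(b, b[, 1] + runif(n, 2, 30), b[, 2] + runif(n, 2, 30))
  il <- iou_loss(a, b); gl <- giou_loss(a, b); cl <- ciou_loss(a, b)
  expect_true(all(iou(a, b) >= 0 & iou(a, b) <= 1))
  expect_true(all(gl >= il - 1e-12))
  expect_true(all(cl >= il - 1e-12)) # the subtracted penalty is >= 0
  # zero iff identical
  expect_true(all(cl[rowSums(abs(a - b)) > 1e-9] > 0))
  expect_true(all(giou_loss(a, a) == 0))
  # translation invariance
  shift <- cbind(5, -3, 5, -3)[rep(1, n), ]
  expect_equal(il, iou_loss(a + shift, b + shift), tolerance = 1e-12)
  expect_equal(gl, giou_loss(a + shift, b + shift), tolerance = 1e-12)
  expect_equal(cl, ciou_loss(a + shift, b + shift), tolerance = 1e-10)
})

test_that("ciou gradient matches central differences", {
  set.seed(33)
  for (i in 1:20) {
    gt <- c(10, 10, 10 + runif(1, 4, 20), 10 + runif(1, 4, 20))
    cx <- runif(1, 5, 30); cy <- runif(1, 5, 30)
    w <- runif(1, 3, 15); h <- runif(1, 3, 15)
    g <- earnet:::ciou_grad_cxcywh(cx, cy, w, h, matrix(gt, 1))
    # alpha is treated as a constant within a step, so the reference loss
    # freezes it at the evaluation point before differencing
    gw <- gt[3] - gt[1]; gh <- gt[4] - gt[2]
    v0 <- (4 / pi^2) * (atan(gw / gh) - atan(w / h))^2
    iou0 <- iou(c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2), gt)
    alpha0 <- if (v0 > 0) v0 / ((1 - iou0) + v0) else 0
    lossf <- function(p) {
      bx <- c(p[1] - p[3] / 2, p[2] - p[4] / 2,
              p[1] + p[3] / 2, p[2] + p[4] / 2)
      cw <- max(bx[3], gt[3]) - min(bx[1], gt[1])
      ch <- max(bx[4], gt[4]) - min(bx[2], gt[2])
      r2sq <- (p[1] - (gt[1] + gt[3]) / 2)^2 + (p[2] - (gt[2] + gt[4]) / 2)^2
      v <- (4 / pi^2) * (atan(gw / gh) - atan(p[3] / p[4]))^2
      1 - iou(bx, gt) + r2sq / (cw^2 + ch^2) + alpha0 * v
    }
    eps <- 1e-6
    for (k in 1:4) {
      p <- c(cx, cy, w, h)
      pp <- p; pp[k] <- pp[k] + eps
      pm <- p; pm[k] <- pm[k] - eps
      gnum <- (lossf(pp) - lossf(pm)) / (2 * eps)
      expect_lt(abs(unname(g[1, k]) - gnum), 1e-6 + 1e-5 * abs(gnum))
    }
  }
})

test_that("gradient of ciou_loss w.r.t. the center is nonzero for disjoint boxes", {
  g <- earnet:::ciou_grad_cxcywh(20, 20, 4, 4, matrix(c(0, 0, 4, 4), 1))
  expect_gt(abs(g[1, "cx"]) + abs(g[1, "cy"]), 0)
})

test_that("target assignment places boxes at their center cells", {
  anchors <- default_anchors()
  # a box exactly equal to anchor 1 (16 x 14.4) centered at (20, 20):
  # level 1 (stride 8), cell (3, 3)
  gt <- list(matrix(c(20 - 8, 20 - 7.2, 20 + 8, 20 + 7.2), 1))
  tg <- assign_targets(gt, anchors, 256)
  best <- tg[which.max(tg$shape_iou), ]
  expect_identical(best$level, 1)
  expect_identical(best$anchor, 1)
  expect_identical(c(best$ci, best$cj), c(3, 3))
  expect_equal(max(tg$shape_iou), 1)
  # empty ground truth -> no positives
  expect_identical(nrow(assign_targets(list(NULL), anchors, 256)), 0L)
})

test_that("two boxes in distinct cells give disjoint positive sets", {
  anchors <- default_anchors()
  gt <- list(matrix(c(10, 10, 26, 26, 100, 100, 116, 116), 2, 4,
                    byrow = TRUE))
  tg <- assign_targets(gt, anchors, 256)
  cells <- unique(tg[, c("level", "anchor", "ci", "cj")])
  expect_identical(nrow(cells), nrow(tg)) # no contested slots survive
  # the two boxes occupy different cells on every level they land on
  key <- paste(tg$level, tg$ci, tg$cj)
  expect_identical(anyDuplicated(key[tg$anchor == tg$anchor[1]]), 0L)
})

test_that("detection loss is zero for perfect predictions and defined without positives", {
  anchors <- default_anchors()
  gt <- list(matrix(c(60, 60, 100, 100), 1))
  tg <- assign_targets(gt, anchors, 256)
  # build raw predictions that decode exactly to the ground truth
  shapes <- list(c(1, 18, 32, 32), c(1, 18, 16, 16), c(1, 18, 8, 8))
  preds <- lapply(shapes, function(d) array(-20, d)) # all logits strongly off
  for (r in seq_len(nrow(tg))) {
    t1 <- tg[r, ]
    per <- 6
    a0 <- (t1$anchor - 1) * per
    logit <- function(p) log(p / (1 - p))
    preds[[t1$level]][1, a0 + 1, t1$ci, t1$cj] <- logit(min(max(t1$tx, 1e-6),
                                                            1 - 1e-6))
    preds[[t1$level]][1, a0 + 2, t1$ci, t1$cj] <- logit(min(max(t1$ty, 1e-6),
                                                            1 - 1e-6))
    preds[[t1$level]][1, a0 + 3, t1$ci, t1$cj] <- t1$tw
    preds[[t1$level]][1, a0 + 4, t1$ci, t1$cj] <- t1$th
    preds[[t1$level]][1, a0 + 5, t1$ci, t1$cj] <- 20 # objectness ~ 1
    preds[[t1$level]][1, a0 + 6, t1$ci, t1$cj] <- 20 # class ~ 1
  }
  l <- detection_loss(preds, tg, anchors, 256)
  expect_lt(l$total, 1e-4)
  # no ground truth at all: box term 0, total still finite
  l0 <- detection_loss(lapply(shapes, function(d) array(-20, d)),
                       assign_targets(list(NULL), anchors, 256), anchors, 256)
  expect_identical(unname(l0$components["box"]), 0)
  expect_true(is.finite(l0$total))
})
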