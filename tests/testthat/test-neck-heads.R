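make_small_model <- function(input_size = 64, seed = 3, anchors = NULL) {
  if (is.null(anchors)) anchors <- default_anchors()
  detector(default_backbone_spec(width_mult = 0.25), anchors = anchors,
           input_size = input_size, seed = seed)
}

test_that("end-to-end shape audit: grids at strides 8/16/32, 18 channels", {
  m <- make_small_model(64)
  x <- array(runif(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  preds <- model_forward(m, x)
  expect_identical(lapply(preds, dim),
                   list(c(2L, 18L, 8L, 8L), c(2L, 18L, 4L, 4L),
                        c(2L, 18L, 2L, 2L)))
})

test_that("neck keeps per-level spatial sizes and configured widths", {
  set.seed(4)
  nk <- earnet:::layer_neck(c(8, 12, 16), c(8, 12, 16))
  taps <- list(
    earnet:::fm_from_array(array(rnorm(8 * 8 * 8), c(1, 8, 8, 8))),
    earnet:::fm_from_array(array(rnorm(12 * 4 * 4), c(1, 12, 4, 4))),
    earnet:::fm_from_array(array(rnorm(16 * 2 * 2), c(1, 16, 2, 2))))
  out <- earnet:::nn_forward(nk, taps)
  expect_identical(vapply(out, earnet:::fm_h, 0), c(8, 4, 2))
  expect_identical(vapply(out, ncol, 0L), c(8L, 12L, 16L))
  bad <- taps
  bad[[3]] <- earnet:::fm_from_array(array(0, c(1, 16, 3, 3)))
  expect_error(earnet:::nn_forward(nk, bad), "pyramid")
})

test_that("neck output is batch-permutation stable (per-sample independence)", {
  m <- make_small_model(64, seed = 9)
  set.seed(10)
  x <- array(runif(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  p12 <- model_forward(m, x)
  p21 <- model_forward(m, x[2:1, , , , drop = FALSE])
  for (l in 1:3) {
    expect_equal(p12[[l]][1, , , ], p21[[l]][2, , , ], tolerance = 1e-10)
    expect_equal(p12[[l]][2, , , ], p21[[l]][1, , , ], tolerance = 1e-10)
  }
})

test_that("decode maps zero offsets to anchor boxes at cell centers", {
  anchors <- default_anchors()
  shapes <- list(c(1, 18, 8, 8), c(1, 18, 4, 4), c(1, 18, 2, 2))
  preds <- lapply(shapes, function(d) array(-1e9, d))
  # anchor 2 of level 1 at cell (3, 4) (row, col; 1-based): tx=ty=tw=th=0,
  # objectness and class strongly positive
  a0 <- 6
  preds[[1]][1, a0 + 1:4, 3, 4] <- 0
  preds[[1]][1, a0 + 5:6, 3, 4] <- 50
  out <- decode(preds, anchors, 64, conf_threshold = 0.5)
  expect_identical(nrow(out), 1L)
  cx <- (out$x1 + out$x2) / 2; cy <- (out$y1 + out$y2) / 2
  expect_equal(cx, (4 - 1 + 0.5) * 8) # column -> x
  expect_equal(cy, (3 - 1 + 0.5) * 8) # row -> y
  expect_equal(out$x2 - out$x1, unname(anchors[2, 1]))
  expect_equal(out$y2 - out$y1, unname(anchors[2, 2]))
  # all objectness at -inf-like logits: nothing decodes
  none <- decode(lapply(shapes, function(d) array(-1e9, d)), anchors, 64, 0)
  expect_identical(nrow(none), 0L)
})

test_that("decoded boxes always lie inside the image", {
  set.seed(11)
  anchors <- default_anchors()
  shapes <- list(c(1, 18, 8, 8), c(1, 18, 4, 4), c(1, 18, 2, 2))
  preds <- lapply(shapes, function(d) array(rnorm(prod(d), 0, 3), d))
  out <- decode(preds, anchors, 64, conf_threshold = 0)
  expect_true(all(out$x1 >= 0 & out$y1 >= 0 & out$x2 <= 64 & out$y2 <= 64))
  expect_true(all(out$x2 > out$x1 & out$y2 > out$y1))
})

test_that("assignment-encoded targets decode back to the ground truth", {
  anchors <- default_anchors()
  set.seed(12)
  input <- 256
  gt <- matrix(0, 5, 4)
  for (i in 1:5) {
    w <- runif(1, 20, 120); h <- runif(1, 20, 120)
    cx <- runif(1, w / 2 + 1, input - w / 2 - 1)
    cy <- runif(1, h / 2 + 1, input - h / 2 - 1)
    gt[i, ] <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  }
  tg <- assign_targets(list(gt), anchors, input)
  shapes <- list(c(1, 18, 32, 32), c(1, 18, 16, 16), c(1, 18, 8, 8))
  preds <- lapply(shapes, function(d) array(-1e9, d))
  logit <- function(p) log(p / (1 - p))
  for (r in seq_len(nrow(tg))) {
    t1 <- tg[r, ]
    a0 <- (t1$anchor - 1) * 6
    preds[[t1$level]][1, a0 + 1, t1$ci, t1$cj] <-
      logit(min(max(t1$tx, 1e-9), 1 - 1e-9))
    preds[[t1$level]][1, a0 + 2, t1$ci, t1$cj] <-
      logit(min(max(t1$ty, 1e-9), 1 - 1e-9))
    preds[[t1$level]][1, a0 + 3, t1$ci, t1$cj] <- t1$tw
    preds[[t1$level]][1, a0 + 4, t1$ci, t1$cj] <- t1$th
    preds[[t1$level]][1, a0 + 5:6, t1$ci, t1$cj] <- 50
  }
  out <- decode(preds, anchors, input, conf_threshold = 0.5)
  # every ground-truth box is recovered by at least one decoded box
  for (i in 1:5) {
    ious <- iou(as.matrix(out[, c("x1", "y1", "x2", "y2")]),
                matrix(gt[i, ], 1))
    expect_gt(max(ious), 1 - 1e-4)
  }
})

test_that("anchor fitting recovers degenerate and separated clusters", {
  all_same <- matrix(rep(c(30, 40), each = 20), 20)
  a <- fit_anchors(all_same, k = 3, seed = 7)
  expect_true(all(abs(a[, 1] - 30) < 1e-9) && all(abs(a[, 2] - 40) < 1e-9))
  set.seed(8)
  small <- cbind(runif(10, 9, 11), runif(10, 9, 11))
  large <- cbind(runif(10, 99, 101), runif(10, 99, 101))
  a2 <- fit_anchors(rbind(small, large), k = 2, seed = 1)
  expect_equal(a2[1, ], colMeans(small), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(a2[2, ], colMeans(large), tolerance = 1e-9,
               ignore_attr = TRUE)
  # determinism under equal seeds
  expect_identical(fit_anchors(rbind(small, large), k = 2, seed = 5),
                   fit_anchors(rbind(small, large), k = 2, seed = 5))
  expect_error(fit_anchors(small, k = 99), "at least")
})
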