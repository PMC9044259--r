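# Loop-level transcriptions of the polarized attention branches, written
# with explicit scalar loops and no batched matrix operations, as an
# independent oracle for the vectorized implementation. x is a (C, H, W)
# array for a single sample.

oracle_channel_branch <- function(x, Wq, Wv, Wz) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]
  ci <- ncol(Wv)
  hw <- H * W
  # flatten spatial positions in (h, w) order
  pos <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H))
  # W_v projection: V[p, j] = sum_c x[c, p] * Wv[c, j]
  V <- matrix(0, hw, ci)
  q <- numeric(hw)
  for (p in seq_len(hw)) {
    for (j in seq_len(ci)) {
      acc <- 0
      for (cc in seq_len(C)) acc <- acc + x[cc, pos[p, 1], pos[p, 2]] * Wv[cc, j]
      V[p, j] <- acc
    }
    accq <- 0
    for (cc in seq_len(C)) accq <- accq + x[cc, pos[p, 1], pos[p, 2]] * Wq[cc, 1]
    q[p] <- accq
  }
  # softmax over the H*W positions
  eq <- exp(q - max(q))
  sm <- eq / sum(eq)
  # matrix dot product sigma1(Wv X) x F_SM(sigma2(Wq X))
  z <- numeric(ci)
  for (j in seq_len(ci)) {
    for (p in seq_len(hw)) z[j] <- z[j] + V[p, j] * sm[p]
  }
  # W_z back to C channels, sigmoid gate
  a <- numeric(C)
  for (cc in seq_len(C)) {
    acc <- 0
    for (j in seq_len(ci)) acc <- acc + z[j] * Wz[j, cc]
    a[cc] <- 1 / (1 + exp(-acc))
  }
  y <- x
  for (cc in seq_len(C)) y[cc, , ] <- x[cc, , ] * a[cc]
  y
}

oracle_spatial_branch <- function(x, Wq, Wv) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]
  ci <- ncol(Wq)
  # W_q projection then global average pool to a ci-vector
  g <- numeric(ci)
  for (j in seq_len(ci)) {
    acc <- 0
    for (h in seq_len(H)) for (w in seq_len(W)) {
      for (cc in seq_len(C)) acc <- acc + x[cc, h, w] * Wq[cc, j]
    }
    g[j] <- acc / (H * W)
  }
  eg <- exp(g - max(g))
  sm <- eg / sum(eg)
  # attention logit per position: dot of softmax with W_v projection
  amap <- matrix(0, H, W)
  for (h in seq_len(H)) for (w in seq_len(W)) {
    acc <- 0
    for (j in seq_len(ci)) {
      vj <- 0
      for (cc in seq_len(C)) vj <- vj + x[cc, h, w] * Wv[cc, j]
      acc <- acc + sm[j] * vj
    }
    amap[h, w] <- 1 / (1 + exp(-acc))
  }
  y <- x
  for (cc in seq_len(C)) y[cc, , ] <- x[cc, , ] * amap
  y
}

# brute-force average precision: integrate the exact precision envelope by
# enumerating every distinct confidence threshold
oracle_average_precision <- function(tp_flags_by_conf_desc, n_gt) {
  n <- length(tp_flags_by_conf_desc)
  recalls <- numeric(n)
  precisions <- numeric(n)
  tp <- 0
  for (i in seq_len(n)) {
    tp <- tp + tp_flags_by_conf_desc[i]
    recalls[i] <- tp / n_gt
    precisions[i] <- tp / i
  }
  ap <- 0
  prev_r <- 0
  for (i in seq_len(n)) {
    env <- max(precisions[i:n]) # best precision at recall >= recalls[i]
    ap <- ap + (recalls[i] - prev_r) * env
    prev_r <- recalls[i]
  }
  ap
}

# exhaustive one-to-one matching that maximizes the number of matches with
# IOU >= threshold (optimal assignment by enumeration; feasible for <= 5)
oracle_optimal_matches <- function(preds, gt, iou_threshold) {
  np <- nrow(preds); ng <- NROW(gt)
  if (np == 0 || ng == 0) return(0)
  pm <- as.matrix(preds[, c("x1", "y1", "x2", "y2")])
  gm <- as.matrix(as.data.frame(gt)[, 1:4])
  feasible <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    feasible[i, j] <- iou(pm[i, ], gm[j, ]) >= iou_threshold
  }
  best <- 0
  recurse <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1, used, count) # leave pred i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && feasible[i, j]) {
        used[j] <- TRUE
        recurse(i + 1, used, count + 1)
        used[j] <- FALSE
      }
    }
  }
  recurse(1, logical(ng), 0)
  best
}
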