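#' Shuffle Polarized Self-Attention (SPSA)
#'
#' SPSA splits the channels of a feature tensor into `groups` sub-features;
#' inside each group the channels are halved, one half passing through a
#' channel-only polarized attention branch (a per-channel weight vector
#' computed by collapsing the spatial axes through a softmax-weighted value
#' projection) and the other through a spatial-only branch (an H x W
#' attention map computed by collapsing the channel axis). The reweighted
#' halves are concatenated, the groups are concatenated, and a channel
#' shuffle mixes information across groups.
#'
#' All 1x1 projections are bias-free, so an all-zero input yields an all-zero
#' output. The gate is a logistic sigmoid, so every attention weight lies
#' strictly inside (0, 1). The block preserves the input shape exactly.
#'
#' @name spsa
NULL

shuffle_perm <- function(ch, groups) {
  if (ch %% groups != 0) {
    stop("channel count ", ch, " is not divisible by groups = ", groups)
  }
  as.vector(matrix(seq_len(ch), nrow = groups, byrow = TRUE))
}

#' Channel shuffle
#'
#' Reorders channels by viewing the channel axis of length C as a
#' (groups, C/groups) matrix, transposing and flattening: a pure permutation
#' that lets later grouped operations see channels from every group.
#'
#' @param x a 4-axis (N, C, H, W) array
#' @param groups number of groups; must divide the channel count
#' @return an array of the same shape with channels permuted
#' @examples
#' x <- array(seq_len(4), c(1, 4, 1, 1))
#' drop(channel_shuffle(x, 2)) # channels reordered 1,3,2,4
#' @export
channel_shuffle <- function(x, groups) {
  stopifnot(is.array(x), length(dim(x)) == 4)
  x[, shuffle_perm(dim(x)[2], groups), , , drop = FALSE]
}

## ---- single-branch forward/backward on internal fm matrices ----
# weights: channel branch Wq (c x 1), Wv (c x ci), Wz (ci x c)
#          spatial branch Wq (c x ci), Wv (c x ci)

ch_branch_fwd <- function(x, Wq, Wv, Wz) {
  h <- fm_h(x); w <- fm_w(x); n <- fm_n(x)
  hw <- h * w
  y <- x
  cache <- vector("list", n)
  for (s in seq_len(n)) {
    rows <- ((s - 1) * hw + 1):(s * hw)
    xs <- x[rows, , drop = FALSE]
    V <- xs %*% Wv                      # (HW, ci)   value projection
    sm <- softmax_vec(as.vector(xs %*% Wq)) # (HW)   query softmax over space
    z <- as.vector(crossprod(V, sm))    # (ci)       sigma1(Wv X) x F_SM(...)
    u <- as.vector(z %*% Wz)            # (c)        W_z back to c channels
    a <- sigmoid(u)                     # F_SG gate  -> per-channel weights
    y[rows, ] <- xs * rep(a, each = hw) # Z^ch = A^ch (x)ch X
    cache[[s]] <- list(xs = xs, V = V, sm = sm, z = z, a = a, rows = rows)
  }
  list(y = fm_like(y, x), cache = cache)
}

ch_branch_bwd <- function(dy, cache, Wq, Wv, Wz) {
  dx <- dy
  dWq <- Wq * 0; dWv <- Wv * 0; dWz <- Wz * 0
  for (cc in cache) {
    rows <- cc$rows
    hw <- length(cc$sm)
    dys <- dy[rows, , drop = FALSE]
    da <- colSums(dys * cc$xs)
    du <- da * cc$a * (1 - cc$a)
    dWz <- dWz + outer(cc$z, du)
    dz <- as.vector(Wz %*% du)
    dV <- outer(cc$sm, dz)
    ds <- as.vector(cc$V %*% dz)
    dq <- cc$sm * (ds - sum(ds * cc$sm))
    dxs <- dys * rep(cc$a, each = hw) +
      dq %*% t(Wq) + dV %*% t(Wv)
    dWq <- dWq + crossprod(cc$xs, dq)
    dWv <- dWv + crossprod(cc$xs, dV)
    dx[rows, ] <- dxs
  }
  list(dx = fm_like(dx, dy), dWq = dWq, dWv = dWv, dWz = dWz)
}

sp_branch_fwd <- function(x, Wq, Wv) {
  h <- fm_h(x); w <- fm_w(x); n <- fm_n(x)
  hw <- h * w
  y <- x
  cache <- vector("list", n)
  for (s in seq_len(n)) {
    rows <- ((s - 1) * hw + 1):(s * hw)
    xs <- x[rows, , drop = FALSE]
    Q <- xs %*% Wq                      # (HW, ci)
    g <- colMeans(Q)                    # F_GP global average pool -> (ci)
    sm <- softmax_vec(g)                # F_SM over the pooled channels
    V <- xs %*% Wv                      # (HW, ci)
    u <- as.vector(V %*% sm)            # (HW)  sigma3(...) spatial logits
    a <- sigmoid(u)                     # F_SG  -> H x W attention map
    y[rows, ] <- xs * a                 # Z^sp = A^sp (x)sp X
    cache[[s]] <- list(xs = xs, V = V, sm = sm, a = a, rows = rows, hw = hw)
  }
  list(y = fm_like(y, x), cache = cache)
}

sp_branch_bwd <- function(dy, cache, Wq, Wv) {
  dx <- dy
  dWq <- Wq * 0; dWv <- Wv * 0
  for (cc in cache) {
    rows <- cc$rows
    dys <- dy[rows, , drop = FALSE]
    da <- rowSums(dys * cc$xs)
    du <- da * cc$a * (1 - cc$a)
    dV <- outer(du, cc$sm)
    ds <- as.vector(crossprod(cc$V, du))
    dg <- cc$sm * (ds - sum(ds * cc$sm))
    dQ <- matrix(dg / cc$hw, cc$hw, length(dg), byrow = TRUE)
    dxs <- dys * cc$a + dQ %*% t(Wq) + dV %*% t(Wv)
    dWq <- dWq + crossprod(cc$xs, dQ)
    dWv <- dWv + crossprod(cc$xs, dV)
    dx[rows, ] <- dxs
  }
  list(dx = fm_like(dx, dy), dWq = dWq, dWv = dWv)
}

#' Channel-only polarized attention branch
#'
#' Computes a per-channel attention vector: a bias-free 1x1 value projection
#' to `c * internal_ratio` channels, a 1x1 query projection to a single
#' channel whose flattened map is softmax-normalized over the H*W positions,
#' their matrix dot-product, a 1x1 projection back to c channels, and a
#' sigmoid gate; the input is then reweighted channel-wise.
#'
#' @param x a 4-axis (N, C, H, W) array slice
#' @param weights list with entries `Wq` (C x 1), `Wv` (C x Ci), `Wz` (Ci x C)
#' @return an array of the same shape as `x`
#' @export
spsa_channel_branch <- function(x, weights) {
  f <- fm_from_array(x)
  fm_to_array(ch_branch_fwd(f, weights$Wq, weights$Wv, weights$Wz)$y)
}

#' Spatial-only polarized attention branch
#'
#' Computes an H x W attention map: a 1x1 query projection whose global
#' average pool is softmax-normalized, a 1x1 value projection reshaped to
#' (Ci, H*W), their dot-product reshaped to the spatial grid and gated by a
#' sigmoid; every channel of the input is multiplied by the map.
#'
#' @param x a 4-axis (N, C, H, W) array slice
#' @param weights list with entries `Wq` (C x Ci), `Wv` (C x Ci)
#' @return an array of the same shape as `x`
#' @export
spsa_spatial_branch <- function(x, weights) {
  f <- fm_from_array(x)
  fm_to_array(sp_branch_fwd(f, weights$Wq, weights$Wv)$y)
}

## ---- the full block as a trainable layer ----

# channels: number of input channels; groups: sub-feature groups G.
# Each group of c = channels/G channels splits into two halves of c/2, so
# channels must be divisible by 2*G and each half must have >= 2 channels.
layer_spsa <- function(channels, groups = 2, internal_ratio = 1 / 2) {
  if (channels %% (2 * groups) != 0) {
    stop("SPSA needs the channel count (", channels,
         ") divisible by 2*groups (", 2 * groups, ")")
  }
  half <- channels %/% (2 * groups)
  if (half < 2) stop("SPSA branch width must be >= 2 channels, got ", half)
  ci <- max(1L, as.integer(round(half * internal_ratio)))
  params <- list()
  for (g in seq_len(groups)) {
    params[[paste0("g", g, ".cWq")]] <-
      matrix(kaiming_uniform(half, half), half, 1)
    params[[paste0("g", g, ".cWv")]] <-
      matrix(kaiming_uniform(half * ci, half), half, ci)
    params[[paste0("g", g, ".cWz")]] <-
      matrix(kaiming_uniform(ci * half, ci), ci, half)
    params[[paste0("g", g, ".sWq")]] <-
      matrix(kaiming_uniform(half * ci, half), half, ci)
    params[[paste0("g", g, ".sWv")]] <-
      matrix(kaiming_uniform(half * ci, half), half, ci)
  }
  new_module("layer_spsa", params = params, channels = channels,
             groups = groups, half = half, ci = ci,
             perm = shuffle_perm(channels, groups))
}

#' @export
nn_forward.layer_spsa <- function(m, x, training = FALSE) {
  if (ncol(x) != m$channels) {
    stop("SPSA built for ", m$channels, " channels, got ", ncol(x))
  }
  y <- x
  caches <- vector("list", m$groups)
  for (g in seq_len(m$groups)) {
    base <- (g - 1) * 2 * m$half
    idx_c <- base + seq_len(m$half)
    idx_s <- base + m$half + seq_len(m$half)
    p <- m$params
    rc <- ch_branch_fwd(fm_like(x[, idx_c, drop = FALSE], x),
                        p[[paste0("g", g, ".cWq")]],
                        p[[paste0("g", g, ".cWv")]],
                        p[[paste0("g", g, ".cWz")]])
    rs <- sp_branch_fwd(fm_like(x[, idx_s, drop = FALSE], x),
                        p[[paste0("g", g, ".sWq")]],
                        p[[paste0("g", g, ".sWv")]])
    y[, idx_c] <- rc$y
    y[, idx_s] <- rs$y
    caches[[g]] <- list(ch = rc$cache, sp = rs$cache,
                        idx_c = idx_c, idx_s = idx_s)
  }
  m$cache <- caches
  fm_like(y[, m$perm, drop = FALSE], x)
}

#' @export
nn_backward.layer_spsa <- function(m, dy) {
  inv <- order(m$perm)
  d <- dy[, inv, drop = FALSE]
  dx <- d
  for (g in seq_len(m$groups)) {
    cc <- m$cache[[g]]
    p <- m$params
    rc <- ch_branch_bwd(fm_like(d[, cc$idx_c, drop = FALSE], dy), cc$ch,
                        p[[paste0("g", g, ".cWq")]],
                        p[[paste0("g", g, ".cWv")]],
                        p[[paste0("g", g, ".cWz")]])
    rs <- sp_branch_bwd(fm_like(d[, cc$idx_s, drop = FALSE], dy), cc$sp,
                        p[[paste0("g", g, ".sWq")]],
                        p[[paste0("g", g, ".sWv")]])
    dx[, cc$idx_c] <- rc$dx
    dx[, cc$idx_s] <- rs$dx
    m$grads[[paste0("g", g, ".cWq")]] <- m$grads[[paste0("g", g, ".cWq")]] + rc$dWq
    m$grads[[paste0("g", g, ".cWv")]] <- m$grads[[paste0("g", g, ".cWv")]] + rc$dWv
    m$grads[[paste0("g", g, ".cWz")]] <- m$grads[[paste0("g", g, ".cWz")]] + rc$dWz
    m$grads[[paste0("g", g, ".sWq")]] <- m$grads[[paste0("g", g, ".sWq")]] + rs$dWq
    m$grads[[paste0("g", g, ".sWv")]] <- m$grads[[paste0("g", g, ".sWv")]] + rs$dWv
  }
  fm_like(dx, dy)
}

#' Build an SPSA block
#'
#' @param channels input channel count; must be divisible by `2 * groups`
#'   with at least 2 channels per branch half
#' @param groups number of sub-feature groups G (default 2)
#' @param internal_ratio fraction of branch channels used inside the
#'   polarized projections (default 1/2)
#' @param seed optional integer seed for the projection weights
#' @return an SPSA block usable with [spsa_forward()]
#' @export
spsa_block <- function(channels, groups = 2, internal_ratio = 1 / 2,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layer_spsa(channels, groups, internal_ratio)
}

#' Apply an SPSA block to a feature tensor
#'
#' @param block an SPSA block from [spsa_block()]
#' @param x a 4-axis (N, C, H, W) array
#' @return an array of the same shape as `x`
#' @examples
#' blk <- spsa_block(8, groups = 2, seed = 1)
#' x <- array(rnorm(8 * 25), c(1, 8, 5, 5))
#' y <- spsa_forward(blk, x)
#' stopifnot(identical(dim(y), dim(x)))
#' @export
spsa_forward <- function(block, x) {
  fm_to_array(nn_forward(block, fm_from_array(x)))
}
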