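# Minimal neural-network engine: layers are environments carrying parameters,
# gradients and a forward cache; every layer implements nn_forward() and
# nn_backward() (explicit reverse-mode differentiation). Composite modules
# list their sub-layers in $children so the optimizer can walk the tree.

new_module <- function(cls, ...) {
  self <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = self)
  if (is.null(self$params)) self$params <- list()
  if (is.null(self$children)) self$children <- list()
  self$grads <- lapply(self$params, function(p) {
    z <- p; z[] <- 0; z
  })
  class(self) <- c(cls, "earnet_module")
  self
}

nn_forward <- function(m, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(m, dy) UseMethod("nn_backward")

# depth-first list of every module in the tree (self included)
nn_modules <- function(m) {
  out <- list(m)
  for (ch in m$children) out <- c(out, nn_modules(ch))
  out
}

nn_zero_grads <- function(m) {
  for (mod in nn_modules(m)) {
    mod$grads <- lapply(mod$params, function(p) {
      z <- p; z[] <- 0; z
    })
  }
  invisible(m)
}

# total number of trainable scalars
nn_count_params <- function(m) {
  sum(vapply(nn_modules(m), function(mod) {
    sum(vapply(mod$params, length, 0L))
  }, 0))
}

# flat named list of all parameter arrays (copy), for checkpointing
nn_state <- function(m) {
  mods <- nn_modules(m)
  st <- list()
  for (i in seq_along(mods)) {
    mod <- mods[[i]]
    for (nm in names(mod$params)) st[[paste0("m", i, ".", nm)]] <- mod$params[[nm]]
    for (nm in names(mod$buffers)) st[[paste0("m", i, ".buf.", nm)]] <- mod$buffers[[nm]]
  }
  st
}

nn_load_state <- function(m, st) {
  mods <- nn_modules(m)
  for (i in seq_along(mods)) {
    mod <- mods[[i]]
    for (nm in names(mod$params)) {
      key <- paste0("m", i, ".", nm)
      if (is.null(st[[key]])) stop("checkpoint is missing parameter ", key)
      mod$params[[nm]] <- st[[key]]
    }
    for (nm in names(mod$buffers)) {
      key <- paste0("m", i, ".buf.", nm)
      if (!is.null(st[[key]])) mod$buffers[[nm]] <- st[[key]]
    }
  }
  invisible(m)
}

kaiming_uniform <- function(n, fan_in) {
  bound <- sqrt(6 / max(fan_in, 1))
  stats::runif(n, -bound, bound)
}

## ---- 1x1 (pointwise) convolution: a plain matrix multiply ----

layer_conv1x1 <- function(in_ch, out_ch, bias = FALSE) {
  W <- matrix(kaiming_uniform(in_ch * out_ch, in_ch), in_ch, out_ch)
  params <- list(W = W)
  if (bias) params$b <- numeric(out_ch)
  new_module("layer_conv1x1", params = params, in_ch = in_ch, out_ch = out_ch,
             has_bias = bias)
}

#' @export
nn_forward.layer_conv1x1 <- function(m, x, training = FALSE) {
  m$cache_x <- x
  y <- x %*% m$params$W
  if (m$has_bias) y <- y + rep(m$params$b, each = nrow(y))
  fm_like(y, x)
}

#' @export
nn_backward.layer_conv1x1 <- function(m, dy) {
  m$grads$W <- m$grads$W + crossprod(m$cache_x, dy)
  if (m$has_bias) m$grads$b <- m$grads$b + colSums(dy)
  fm_like(dy %*% t(m$params$W), m$cache_x)
}

## ---- k x k convolution (optionally grouped / depthwise), Rcpp kernels ----

layer_conv2d <- function(in_ch, out_ch, k, stride = 1, groups = 1) {
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  cpg <- in_ch %/% groups
  W <- array(kaiming_uniform(k * k * cpg * out_ch, k * k * cpg),
             c(k, k, cpg, out_ch))
  new_module("layer_conv2d", params = list(W = W), in_ch = in_ch,
             out_ch = out_ch, k = k, stride = stride, groups = groups,
             cpg = cpg)
}

#' @export
nn_forward.layer_conv2d <- function(m, x, training = FALSE) {
  h <- fm_h(x); w <- fm_w(x); n <- fm_n(x)
  m$cache_x <- x
  y <- conv2d_fwd_cpp(x, h, w, n, as.vector(m$params$W), m$k, m$cpg,
                      m$out_ch, m$stride, m$groups)
  ho <- (h + 2 * (m$k %/% 2) - m$k) %/% m$stride + 1
  wo <- (w + 2 * (m$k %/% 2) - m$k) %/% m$stride + 1
  new_fm(y, ho, wo)
}

#' @export
nn_backward.layer_conv2d <- function(m, dy) {
  x <- m$cache_x
  h <- fm_h(x); w <- fm_w(x); n <- fm_n(x)
  dW <- conv2d_bwd_weight_cpp(x, dy, h, w, n, m$k, m$cpg, m$stride, m$groups)
  dim(dW) <- dim(m$params$W)
  m$grads$W <- m$grads$W + dW
  dx <- conv2d_bwd_input_cpp(dy, h, w, n, as.vector(m$params$W), m$k, m$cpg,
                             m$in_ch, m$stride, m$groups)
  new_fm(dx, h, w)
}

## ---- batch normalization ----

layer_batchnorm <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_module("layer_batchnorm",
             params = list(gamma = rep(1, ch), beta = rep(0, ch)),
             buffers = list(run_mean = rep(0, ch), run_var = rep(1, ch)),
             eps = eps, momentum = momentum, ch = ch)
}

#' @export
nn_forward.layer_batchnorm <- function(m, x, training = FALSE) {
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = nrow(x))
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + m$eps)
    xhat <- col_scale(xc, invstd)
    m$buffers$run_mean <- (1 - m$momentum) * m$buffers$run_mean + m$momentum * mu
    m$buffers$run_var <- (1 - m$momentum) * m$buffers$run_var + m$momentum * v
    m$cache_xhat <- xhat
    m$cache_invstd <- invstd
    m$train_mode <- TRUE
    fm_like(col_scale_add_cpp(xhat, m$params$gamma, m$params$beta), x)
  } else {
    invstd <- 1 / sqrt(m$buffers$run_var + m$eps)
    m$cache_invstd <- invstd
    m$train_mode <- FALSE
    fm_like(col_scale_add_cpp(x, m$params$gamma * invstd,
                              m$params$beta -
                                m$params$gamma * invstd * m$buffers$run_mean),
            x)
  }
}

#' @export
nn_backward.layer_batchnorm <- function(m, dy) {
  if (isTRUE(m$train_mode)) {
    r <- bn_bwd_cpp(dy, m$cache_xhat, m$params$gamma, m$cache_invstd)
    m$grads$gamma <- m$grads$gamma + r$dgamma
    m$grads$beta <- m$grads$beta + r$dbeta
    dx <- r$dx
  } else {
    m$grads$beta <- m$grads$beta + colSums(dy)
    dx <- col_scale(dy, m$params$gamma * m$cache_invstd)
  }
  fm_like(dx, dy)
}

## ---- activations as layers ----

layer_tanhexp <- function() new_module("layer_tanhexp")

#' @export
nn_forward.layer_tanhexp <- function(m, x, training = FALSE) {
  m$cache_x <- x
  fm_like(tanhexp(x), x)
}

#' @export
nn_backward.layer_tanhexp <- function(m, dy) {
  fm_like(dy * tanhexp_grad(m$cache_x), dy)
}

layer_identity <- function() new_module("layer_identity")

#' @export
nn_forward.layer_identity <- function(m, x, training = FALSE) x

#' @export
nn_backward.layer_identity <- function(m, dy) dy

activation_layer <- function(name = c("tanhexp", "identity")) {
  switch(match.arg(name), tanhexp = layer_tanhexp(), identity = layer_identity())
}

## ---- sequential container ----

layer_seq <- function(...) {
  new_module("layer_seq", children = list(...))
}

#' @export
nn_forward.layer_seq <- function(m, x, training = FALSE) {
  for (ch in m$children) x <- nn_forward(ch, x, training)
  x
}

#' @export
nn_backward.layer_seq <- function(m, dy) {
  for (ch in rev(m$children)) dy <- nn_backward(ch, dy)
  dy
}

# conv -> BN -> activation, the standard stack used throughout the network
conv_bn_act <- function(in_ch, out_ch, k = 1, stride = 1, groups = 1,
                        act = "tanhexp") {
  conv <- if (k == 1 && groups == 1 && stride == 1) {
    layer_conv1x1(in_ch, out_ch)
  } else {
    layer_conv2d(in_ch, out_ch, k, stride, groups)
  }
  layer_seq(conv, layer_batchnorm(out_ch), activation_layer(act))
}

## ---- nearest-neighbour x2 upsampling ----

layer_upsample2 <- function() new_module("layer_upsample2")

#' @export
nn_forward.layer_upsample2 <- function(m, x, training = FALSE) {
  h <- fm_h(x); w <- fm_w(x); n <- fm_n(x)
  m$in_hw <- c(h, w)
  m$in_n <- n
  new_fm(upsample2_fwd_cpp(x, h, w, n), 2 * h, 2 * w)
}

#' @export
nn_backward.layer_upsample2 <- function(m, dy) {
  new_fm(upsample2_bwd_cpp(dy, m$in_hw[1], m$in_hw[2], m$in_n),
         m$in_hw[1], m$in_hw[2])
}
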