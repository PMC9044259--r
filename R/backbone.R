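#' Asymmetric-bottleneck (ASB) backbone
#'
#' The backbone is a stack of 15 AsymmBottleneck blocks behind a stride-2
#' stem convolution. An ASB block is an inverted bottleneck in which part of
#' the pointwise expansion is replaced by directly carried input channels:
#' the 1x1 expansion only produces `exp_size - in_channels` new channels,
#' which are concatenated with the untouched input to form the `exp_size`
#' channels fed to the depthwise convolution. A pointwise linear projection
#' reduces to `out_channels`, with a residual connection when the stride is
#' 1 and the channel counts match. TanhExp follows the expansion and
#' depthwise stages; an SPSA block can sit between the depthwise convolution
#' and the projection. Three taps expose the multi-scale features P3/P4/P5
#' at strides 8/16/32.
#'
#' @name backbone
NULL

#' ASB stage configuration
#'
#' @param kernel depthwise kernel size, 3 or 5
#' @param exp_size expansion channel count (>= the stage's input channels)
#' @param out_channels output channel count
#' @param use_spsa attach an SPSA block after the depthwise convolution?
#' @param stride 1 or 2
#' @return a list of class `asb_config`
#' @export
asb_config <- function(kernel, exp_size, out_channels, use_spsa = FALSE,
                       stride = 1) {
  stopifnot(kernel %in% c(3, 5), stride %in% c(1, 2),
            exp_size >= out_channels, exp_size >= 1, out_channels >= 1)
  structure(list(kernel = as.integer(kernel), exp_size = as.integer(exp_size),
                 out_channels = as.integer(out_channels),
                 use_spsa = isTRUE(use_spsa), stride = as.integer(stride)),
            class = "asb_config")
}

#' Default backbone specification
#'
#' The 15-stage stage list of the wheat-ear backbone: a 3->16 stride-2 stem,
#' then ASB stages with the kernel/expansion/output/SPSA/stride pattern of
#' the lightweight asymmetric backbone, and taps at stages 6, 12 and 15
#' whose outputs (40, 112 and 160 channels at strides 8, 16 and 32) become
#' P3, P4 and P5.
#'
#' @param width_mult multiply all channel counts (stem, expansions, outputs)
#'   by this factor, rounding to multiples of 4 with a floor of 8; 1 keeps
#'   the reference architecture. Used to build width-reduced models for
#'   CPU-scale experiments.
#' @return a list of class `backbone_spec` with elements `stem_channels`,
#'   `stages` (list of 15 [asb_config()]) and `taps` (integer vector of 3)
#' @examples
#' spec <- default_backbone_spec()
#' length(spec$stages) # 15
#' sum(vapply(spec$stages, function(s) s$use_spsa, TRUE)) # 8
#' @export
default_backbone_spec <- function(width_mult = 1) {
  rows <- list(
    # kernel, exp, out, spsa, stride
    list(3, 16, 16, FALSE, 1),
    list(3, 64, 24, FALSE, 2),
    list(3, 72, 24, FALSE, 1),
    list(5, 72, 40, TRUE, 2),
    list(5, 120, 40, TRUE, 1),
    list(5, 120, 40, TRUE, 1), # P3
    list(3, 240, 80, FALSE, 2),
    list(3, 200, 80, FALSE, 1),
    list(3, 184, 80, FALSE, 1),
    list(3, 184, 80, FALSE, 1),
    list(3, 480, 112, TRUE, 1),
    list(3, 672, 112, TRUE, 1), # P4
    list(5, 672, 160, TRUE, 2),
    list(5, 960, 160, TRUE, 1),
    list(5, 960, 160, TRUE, 1) # P5
  )
  scale_ch <- function(c) {
    if (width_mult == 1) return(as.integer(c))
    max(8L, as.integer(round(c * width_mult / 4) * 4))
  }
  stem <- scale_ch(16)
  prev <- stem
  stages <- lapply(rows, function(r) {
    exp_c <- max(scale_ch(r[[2]]), prev)
    out_c <- scale_ch(r[[3]])
    prev <<- out_c
    asb_config(r[[1]], exp_c, out_c, r[[4]], r[[5]])
  })
  structure(list(stem_channels = stem, stages = stages, taps = c(6L, 12L, 15L)),
            class = "backbone_spec")
}

#' Build one ASB block
#'
#' @param cfg an [asb_config()]
#' @param in_channels channels entering the block
#' @param spsa_groups group count for the SPSA block, if enabled
#' @return a trainable block module
#' @export
build_asb_block <- function(cfg, in_channels, spsa_groups = 2) {
  stopifnot(inherits(cfg, "asb_config"), in_channels >= 1)
  if (cfg$exp_size < in_channels) {
    stop("exp_size (", cfg$exp_size, ") must be >= in_channels (",
         in_channels, ")")
  }
  new_ch <- cfg$exp_size - in_channels
  expand <- if (new_ch > 0) conv_bn_act(in_channels, new_ch, k = 1) else NULL
  dw <- conv_bn_act(cfg$exp_size, cfg$exp_size, k = cfg$kernel,
                    stride = cfg$stride, groups = cfg$exp_size)
  spsa <- if (cfg$use_spsa) layer_spsa(cfg$exp_size, spsa_groups) else NULL
  proj <- layer_seq(layer_conv1x1(cfg$exp_size, cfg$out_channels),
                    layer_batchnorm(cfg$out_channels))
  children <- Filter(Negate(is.null), list(expand = expand, dw = dw,
                                           spsa = spsa, proj = proj))
  new_module("layer_asb", children = children,
             expand = expand, dw = dw, spsa = spsa, proj = proj,
             residual = cfg$stride == 1 && in_channels == cfg$out_channels,
             in_ch = in_channels, cfg = cfg)
}

#' @export
nn_forward.layer_asb <- function(m, x, training = FALSE) {
  z <- if (is.null(m$expand)) {
    x
  } else {
    e <- nn_forward(m$expand, x, training)
    fm_like(cbind(x, e), x) # carried input channels first, learned expansion after
  }
  z <- nn_forward(m$dw, z, training)
  if (!is.null(m$spsa)) z <- nn_forward(m$spsa, z, training)
  y <- nn_forward(m$proj, z, training)
  if (m$residual) y <- fm_like(y + x, y)
  y
}

#' @export
nn_backward.layer_asb <- function(m, dy) {
  dres <- if (m$residual) dy else NULL
  d <- nn_backward(m$proj, dy)
  if (!is.null(m$spsa)) d <- nn_backward(m$spsa, d)
  d <- nn_backward(m$dw, d)
  dx <- if (is.null(m$expand)) {
    d
  } else {
    din <- d[, seq_len(m$in_ch), drop = FALSE]
    de <- d[, -seq_len(m$in_ch), drop = FALSE]
    fm_like(din + nn_backward(m$expand, fm_like(de, d)), d)
  }
  if (!is.null(dres)) dx <- fm_like(dx + dres, dx)
  dx
}

## ---- the full backbone ----

layer_backbone <- function(spec, spsa_groups = 2) {
  stopifnot(inherits(spec, "backbone_spec"), length(spec$stages) == 15,
            length(spec$taps) == 3, !is.unsorted(spec$taps, strictly = TRUE))
  stem <- conv_bn_act(3, spec$stem_channels, k = 3, stride = 2)
  blocks <- list()
  in_ch <- spec$stem_channels
  for (i in seq_along(spec$stages)) {
    blocks[[i]] <- build_asb_block(spec$stages[[i]], in_ch, spsa_groups)
    in_ch <- spec$stages[[i]]$out_channels
  }
  new_module("layer_backbone", children = c(list(stem), blocks),
             stem = stem, blocks = blocks, spec = spec)
}

#' @export
nn_forward.layer_backbone <- function(m, x, training = FALSE) {
  h <- fm_h(x); w <- fm_w(x)
  if (h %% 32 != 0 || w %% 32 != 0) {
    stop("input height and width must be divisible by 32, got ", h, "x", w)
  }
  z <- nn_forward(m$stem, x, training)
  taps <- list()
  for (i in seq_along(m$blocks)) {
    z <- nn_forward(m$blocks[[i]], z, training)
    if (i %in% m$spec$taps) taps[[length(taps) + 1]] <- z
  }
  names(taps) <- c("p3", "p4", "p5")
  taps
}

# dy: list of gradients for p3/p4/p5 (any may be NULL)
#' @export
nn_backward.layer_backbone <- function(m, dy) {
  d <- NULL
  tap_of <- match(seq_along(m$blocks), m$spec$taps) # block -> tap index
  for (i in rev(seq_along(m$blocks))) {
    if (!is.na(tap_of[i]) && !is.null(dy[[tap_of[i]]])) {
      g <- dy[[tap_of[i]]]
      d <- if (is.null(d)) g else fm_like(d + g, d)
    }
    d <- nn_backward(m$blocks[[i]], d)
  }
  nn_backward(m$stem, d)
}

#' Build a backbone network
#'
#' @param spec a [default_backbone_spec()]-style specification
#' @param seed optional integer seed for weight initialization
#' @param spsa_groups SPSA group count for the stages that carry attention
#' @return a backbone module for [backbone_forward()]
#' @export
build_backbone <- function(spec = default_backbone_spec(), seed = NULL,
                           spsa_groups = 2) {
  if (!is.null(seed)) set.seed(seed)
  layer_backbone(spec, spsa_groups)
}

#' Run the backbone on an image batch
#'
#' @param backbone a module from [build_backbone()]
#' @param x a 4-axis (N, 3, H, W) array with H and W divisible by 32
#' @param training use batch statistics in the normalization layers?
#' @return a list with (N, C, H, W) arrays `p3`, `p4`, `p5` at strides
#'   8, 16 and 32
#' @export
backbone_forward <- function(backbone, x, training = FALSE) {
  taps <- nn_forward(backbone, fm_from_array(x), training)
  lapply(taps, fm_to_array)
}

#' Closed-form parameter count of one ASB block
#'
#' Sums the weight shapes of the block's convolutions, normalization layers
#' and (optionally) its SPSA projections; used to audit the built blocks.
#'
#' @inheritParams build_asb_block
#' @return integer parameter count
#' @export
asb_param_count <- function(cfg, in_channels, spsa_groups = 2) {
  new_ch <- cfg$exp_size - in_channels
  n <- 0
  if (new_ch > 0) n <- n + in_channels * new_ch + 2 * new_ch # PW + BN
  n <- n + cfg$kernel^2 * cfg$exp_size + 2 * cfg$exp_size # DW + BN
  if (cfg$use_spsa) {
    half <- cfg$exp_size %/% (2 * spsa_groups)
    ci <- max(1L, as.integer(round(half / 2)))
    n <- n + spsa_groups * (half * 1 + 3 * half * ci + ci * half)
  }
  n + cfg$exp_size * cfg$out_channels + 2 * cfg$out_channels # proj + BN
}

#' Serialize a backbone specification to YAML
#'
#' @param spec a `backbone_spec`
#' @param path YAML file path
#' @export
save_backbone_spec <- function(spec, path) {
  yaml::write_yaml(list(stem_channels = spec$stem_channels,
                        taps = as.integer(spec$taps),
                        stages = lapply(spec$stages, unclass)), path)
  invisible(path)
}

#' @rdname save_backbone_spec
#' @return `load_backbone_spec()`: the restored `backbone_spec`
#' @export
load_backbone_spec <- function(path) {
  v <- yaml::read_yaml(path)
  structure(list(stem_channels = as.integer(v$stem_channels),
                 stages = lapply(v$stages, function(s) {
                   asb_config(s$kernel, s$exp_size, s$out_channels,
                              s$use_spsa, s$stride)
                 }),
                 taps = as.integer(v$taps)),
            class = "backbone_spec")
}
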