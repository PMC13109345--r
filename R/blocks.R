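## Composite network blocks.
##
## Each block is an environment holding its child layers plus the forward
## cache needed by its hand-derived adjoint.  Blocks preserve the channel-
## first C x H x W x B layout throughout.

new_module <- function(class, children, fields = list()) {
  e <- new_layer(c(class, "module"), fields)
  e$children <- children
  e
}

# Recursively collect primitive layers with hierarchical names, in forward
# order, for audits, optimisation and (re-)initialisation.
module_layers <- function(m, prefix = "") {
  if (inherits(m, "module")) {
    out <- list()
    for (nm in names(m$children)) {
      out <- c(out, module_layers(m$children[[nm]],
                                  paste0(prefix, nm, ".")))
    }
    out
  } else {
    stats::setNames(list(m), sub("\\.$", "", paste0(prefix, m$name)))
  }
}

ch_concat <- function(parts) {
  d1 <- dim(parts[[1L]])
  cs <- vapply(parts, function(p) dim(p)[1L], integer(1))
  out <- array(0, c(sum(cs), d1[2L], d1[3L], d1[4L]))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[1L]
    out[at + seq_len(cp), , , ] <- p
    at <- at + cp
  }
  out
}

ch_split <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(cp) {
    sl <- x[at + seq_len(cp), , , , drop = FALSE]
    at <<- at + cp
    sl
  })
}

## ---- sequential container ---------------------------------------------------

seq_module <- function(children, name = "seq") {
  new_module("seq_module", children, list(name = name))
}

#' @export
ly_forward.seq_module <- function(l, x, training = FALSE, keep = FALSE) {
  for (ch in l$children) x <- ly_forward(ch, x, training, keep)
  x
}

#' @export
ly_backward.seq_module <- function(l, dy) {
  for (ch in rev(l$children)) dy <- ly_backward(ch, dy)
  dy
}

## ---- ERF: 1x1 then two 3x3 convolutions -------------------------------------

#' Receptive-field expansion submodule
#'
#' A `1x1` convolution that re-mixes channels followed by two `3x3`
#' convolutions that deepen the extraction and widen the receptive field.
#' The submodule appears in several places of the network with different
#' shape contracts, so stride and padding of the two `3x3` convolutions are
#' set per call site: stride 1 with `same` padding inside the residual
#' blocks (spatial dims preserved), a final stride-2 convolution inside the
#' stem and the reduction stages (spatial dims roughly halved).
#'
#' @param in_c input channels.
#' @param widths three output widths, one per convolution.
#' @param strides three strides.
#' @param paddings three padding modes (`"valid"`/`"same"`).
#' @param name module name.
#' @return An ERF module.
#' @export
erf_module <- function(in_c, widths, strides = c(1L, 1L, 1L),
                       paddings = c("same", "same", "same"), name = "erf") {
  stopifnot(length(widths) == 3L)
  new_module("seq_module", list(
    conv1 = conv_layer(in_c, widths[1L], 1L, 1L, strides[1L], paddings[1L],
                       name = "conv1x1"),
    conv2 = conv_layer(widths[1L], widths[2L], 3L, 3L, strides[2L],
                       paddings[2L], name = "conv3x3_1"),
    conv3 = conv_layer(widths[2L], widths[3L], 3L, 3L, strides[3L],
                       paddings[3L], name = "conv3x3_2")
  ), list(name = name))
}

#' Apply an ERF module to a feature map
#'
#' @param erf module from [erf_module()].
#' @param x `C x H x W` array or `C x H x W x B` batch.
#' @param training use batch statistics in the normalisation layers.
#' @return Output feature map.
#' @export
erf_forward <- function(erf, x, training = FALSE) {
  ly_forward(erf, x, training = training)
}

## ---- stem -------------------------------------------------------------------

#' Stem: entry block of the network
#'
#' Three stacked `3x3` convolutions, a `3x3` max pool, then an ERF
#' submodule.  Under the reference stride schedule a `3 x 299 x 299` input
#' traces spatially 299 -> 149 -> 147 -> 147 -> 73 -> 71 -> 35 and emits
#' `256 x 35 x 35`.
#'
#' @param in_c input channels (3 for RGB).
#' @param conv_widths widths of the three leading convolutions.
#' @param erf_widths widths of the ERF convolutions; the last is the stem's
#'   output channel count.
#' @return A stem module.
#' @export
stem_module <- function(in_c = 3L, conv_widths = c(32L, 32L, 64L),
                        erf_widths = c(80L, 192L, 256L)) {
  new_module("seq_module", list(
    conv1 = conv_layer(in_c, conv_widths[1L], stride = 2L, padding = "valid",
                       name = "conv1"),
    conv2 = conv_layer(conv_widths[1L], conv_widths[2L], stride = 1L,
                       padding = "valid", name = "conv2"),
    conv3 = conv_layer(conv_widths[2L], conv_widths[3L], stride = 1L,
                       padding = "same", name = "conv3"),
    pool = max_pool_layer(3L, 2L, name = "maxpool"),
    erf = erf_module(conv_widths[3L], erf_widths, strides = c(1L, 1L, 2L),
                     paddings = c("valid", "valid", "valid"))
  ), list(name = "stem"))
}

#' Run the stem on an input image batch
#'
#' @param stem module from [stem_module()].
#' @param x `3 x S x S` array (or batch); `S` is the configured input size.
#' @param training use batch statistics.
#' @return Feature map `X1`.
#' @export
stem_forward <- function(stem, x, training = FALSE) {
  ly_forward(stem, x, training = training)
}

## ---- Inception-ResNet residual blocks ---------------------------------------

residual_block <- function(class, children, in_c, name) {
  new_module(class, children, list(name = name, in_c = as.integer(in_c)))
}

#' Inception-ResNet-A residual block
#'
#' Three parallel branches — a `1x1` convolution, a `1x1 -> 3x3` chain, and
#' an ERF submodule — concatenated and fused by a linear `1x1` convolution
#' back to the input width, added to the input, then passed through a ReLU.
#' Spatial dimensions and channel count are preserved exactly.
#'
#' @param in_c input (and output) channels.
#' @param br1 width of the `1x1` branch.
#' @param br2 two widths of the `1x1 -> 3x3` branch.
#' @param erf_widths three ERF widths.
#' @param name block name.
#' @return A block module.
#' @export
inception_resnet_a <- function(in_c = 256L, br1 = 32L, br2 = c(32L, 32L),
                               erf_widths = c(32L, 48L, 64L), name = "block_a") {
  concat_c <- br1 + br2[2L] + erf_widths[3L]
  m <- residual_block("resnet_block", list(
    b1 = conv_layer(in_c, br1, 1L, 1L, name = "b1_conv1x1"),
    b2a = conv_layer(in_c, br2[1L], 1L, 1L, name = "b2_conv1x1"),
    b2b = conv_layer(br2[1L], br2[2L], 3L, 3L, padding = "same",
                     name = "b2_conv3x3"),
    b3 = erf_module(in_c, erf_widths, name = "b3_erf"),
    fuse = conv_layer(concat_c, in_c, 1L, 1L, activation = "none",
                      name = "fuse_conv1x1")
  ), in_c, name)
  m$branch_sizes <- c(br1, br2[2L], erf_widths[3L])
  m
}

#' Inception-ResNet-B residual block
#'
#' Two parallel branches — a `1x1` convolution and a `1x1 -> 1x7 -> 7x1`
#' asymmetric chain — concatenated, fused by a linear `1x1` convolution,
#' added to the input, then ReLU.  Shape preserved.
#'
#' @param in_c input (and output) channels.
#' @param br1 width of the `1x1` branch.
#' @param br2 three widths of the asymmetric chain.
#' @param name block name.
#' @return A block module.
#' @export
inception_resnet_b <- function(in_c = 896L, br1 = 176L,
                               br2 = c(144L, 148L, 184L), name = "block_b") {
  concat_c <- br1 + br2[3L]
  m <- residual_block("resnet_block", list(
    b1 = conv_layer(in_c, br1, 1L, 1L, name = "b1_conv1x1"),
    b2a = conv_layer(in_c, br2[1L], 1L, 1L, name = "b2_conv1x1"),
    b2b = conv_layer(br2[1L], br2[2L], 1L, 7L, padding = "same",
                     name = "b2_conv1x7"),
    b2c = conv_layer(br2[2L], br2[3L], 7L, 1L, padding = "same",
                     name = "b2_conv7x1"),
    b3 = NULL,
    fuse = conv_layer(concat_c, in_c, 1L, 1L, activation = "none",
                      name = "fuse_conv1x1")
  ), in_c, name)
  m$children <- Filter(Negate(is.null), m$children)
  m$branch_sizes <- c(br1, br2[3L])
  m
}

#' @export
ly_forward.resnet_block <- function(l, x, training = FALSE, keep = FALSE) {
  x <- as_batch(x)
  ch <- l$children
  y1 <- ly_forward(ch$b1, x, training, keep)
  y2 <- ly_forward(ch$b2a, x, training, keep)
  y2 <- ly_forward(ch$b2b, y2, training, keep)
  if (!is.null(ch$b2c)) y2 <- ly_forward(ch$b2c, y2, training, keep)
  parts <- list(y1, y2)
  if (!is.null(ch$b3)) parts <- c(parts, list(ly_forward(ch$b3, x, training, keep)))
  cc <- ch_concat(parts)
  f <- ly_forward(ch$fuse, cc, training, keep)
  if (!identical(dim(f), dim(x))) {
    stop("configuration error: fusion width ", dim(f)[1L],
         " does not match input width ", dim(x)[1L])
  }
  pre <- x + f
  out <- pre
  out[out < 0] <- 0
  if (keep) l$cache <- list(mask = pre > 0)
  out
}

#' @export
ly_backward.resnet_block <- function(l, dy) {
  ch <- l$children
  dpre <- dy * l$cache$mask
  dcc <- ly_backward(ch$fuse, dpre)
  parts <- ch_split(dcc, l$branch_sizes)
  dx <- dpre + ly_backward(ch$b1, parts[[1L]])
  d2 <- parts[[2L]]
  if (!is.null(ch$b2c)) d2 <- ly_backward(ch$b2c, d2)
  d2 <- ly_backward(ch$b2b, d2)
  dx <- dx + ly_backward(ch$b2a, d2)
  if (!is.null(ch$b3)) dx <- dx + ly_backward(ch$b3, parts[[3L]])
  dx
}

## ---- reduction stages -------------------------------------------------------

#' Reduction-A downsampling stage
#'
#' Concatenates a stride-2 `3x3` convolution branch, an ERF branch whose
#' final convolution has stride 2, and a stride-2 `3x3` max-pool branch.
#' With the reference widths a `256 x 35 x 35` input becomes
#' `896 x 17 x 17` (384 + 256 + 256 channels).
#'
#' @param in_c input channels.
#' @param conv_w width of the convolution branch.
#' @param erf_widths three ERF widths (the last is that branch's output).
#' @param name module name.
#' @return A reduction module.
#' @export
reduction_a <- function(in_c = 256L, conv_w = 384L,
                        erf_widths = c(192L, 224L, 256L), name = "reduction_a") {
  m <- new_module("reduction_block", list(
    b1 = conv_layer(in_c, conv_w, 3L, 3L, stride = 2L, padding = "valid",
                    name = "b1_conv3x3"),
    b2 = erf_module(in_c, erf_widths, strides = c(1L, 1L, 2L),
                    paddings = c("valid", "same", "valid"), name = "b2_erf"),
    b3 = max_pool_layer(3L, 2L, name = "b3_maxpool")
  ), list(name = name, in_c = as.integer(in_c)))
  m$branch_sizes <- c(conv_w, erf_widths[3L], in_c)
  m$out_c <- sum(m$branch_sizes)
  m
}

#' Reduction-B downsampling stage
#'
#' Four branches: two `1x1 -> 3x3(stride 2)` convolution chains, an ERF
#' branch ending in a stride-2 convolution, and a stride-2 `3x3` max pool.
#' With the reference widths a `896 x 17 x 17` input becomes
#' `1792 x 8 x 8` (384 + 256 + 256 + 896 channels).
#'
#' @param in_c input channels.
#' @param br1,br2 two widths each (`1x1` then `3x3`) for the conv branches.
#' @param erf_widths three ERF widths.
#' @param name module name.
#' @return A reduction module.
#' @export
reduction_b <- function(in_c = 896L, br1 = c(256L, 384L), br2 = c(256L, 256L),
                        erf_widths = c(256L, 256L, 256L), name = "reduction_b") {
  m <- new_module("reduction_block", list(
    b1 = seq_module(list(
      conv1 = conv_layer(in_c, br1[1L], 1L, 1L, name = "conv1x1"),
      conv2 = conv_layer(br1[1L], br1[2L], 3L, 3L, stride = 2L,
                         padding = "valid", name = "conv3x3")
    ), name = "b1"),
    b2 = seq_module(list(
      conv1 = conv_layer(in_c, br2[1L], 1L, 1L, name = "conv1x1"),
      conv2 = conv_layer(br2[1L], br2[2L], 3L, 3L, stride = 2L,
                         padding = "valid", name = "conv3x3")
    ), name = "b2"),
    b3 = erf_module(in_c, erf_widths, strides = c(1L, 1L, 2L),
                    paddings = c("valid", "same", "valid"), name = "b3_erf"),
    b4 = max_pool_layer(3L, 2L, name = "b4_maxpool")
  ), list(name = name, in_c = as.integer(in_c)))
  m$branch_sizes <- c(br1[2L], br2[2L], erf_widths[3L], in_c)
  m$out_c <- sum(m$branch_sizes)
  m
}

#' @export
ly_forward.reduction_block <- function(l, x, training = FALSE, keep = FALSE) {
  x <- as_batch(x)
  parts <- lapply(l$children, function(ch) ly_forward(ch, x, training, keep))
  ch_concat(parts)
}

#' @export
ly_backward.reduction_block <- function(l, dy) {
  parts <- ch_split(dy, l$branch_sizes)
  dx <- 0
  for (i in seq_along(l$children)) {
    dx <- dx + ly_backward(l$children[[i]], parts[[i]])
  }
  dx
}

## ---- global attention mechanism ---------------------------------------------

#' Global attention mechanism (channel + spatial sigmoid gates)
#'
#' Channel attention permutes the `C x H x W` map to put channels last and
#' applies a two-layer perceptron across the channel axis (`c -> c/rate ->
#' c`, ReLU between) at every spatial position — algebraically identical to
#' two `1x1` convolutions — followed by a sigmoid.  Spatial attention is a
#' `7x7` convolution pair (`c -> c/rate -> c`, ReLU between, same padding)
#' followed by a sigmoid.  The gates are applied sequentially by
#' element-wise multiplication, so the output is
#' `x (*) channel_weights (*) spatial_weights`.
#'
#' @param channels input channel count `c`; must be divisible by `rate`.
#' @param rate channel compression ratio of both gates (reference: 16).
#' @param spatial_kernel spatial gate kernel size (7).
#' @return A GAM module.
#' @export
gam_module <- function(channels, rate = 16L, spatial_kernel = 7L) {
  channels <- as.integer(channels)
  rate <- as.integer(rate)
  if (rate < 1L || channels %% rate != 0L) {
    stop("configuration error: channels (", channels,
         ") must be divisible by rate (", rate, ")")
  }
  hidden <- channels %/% rate
  new_module("gam_block", list(
    ch1 = conv_layer(channels, hidden, 1L, 1L, use_bn = FALSE,
                     activation = "relu", name = "channel_fc1"),
    ch2 = conv_layer(hidden, channels, 1L, 1L, use_bn = FALSE,
                     activation = "none", name = "channel_fc2"),
    sp1 = conv_layer(channels, hidden, spatial_kernel, spatial_kernel,
                     padding = "same", use_bn = FALSE, activation = "relu",
                     name = "spatial_conv1"),
    sp2 = conv_layer(hidden, channels, spatial_kernel, spatial_kernel,
                     padding = "same", use_bn = FALSE, activation = "none",
                     name = "spatial_conv2")
  ), list(name = "gam", channels = channels, rate = rate,
          hidden = hidden, spatial_kernel = as.integer(spatial_kernel)))
}

#' Channel attention weights
#'
#' @param gam module from [gam_module()].
#' @param x feature map with `gam$channels` channels.
#' @return Array of weights, same shape as `x`, all strictly in (0, 1).
#' @export
channel_attention <- function(gam, x) {
  x <- as_batch(x)
  pre <- ly_forward(gam$children$ch2, ly_forward(gam$children$ch1, x))
  sigmoid(pre)
}

#' Spatial attention weights
#'
#' @inheritParams channel_attention
#' @return Array of weights, same shape as `x`, all strictly in (0, 1).
#' @export
spatial_attention <- function(gam, x) {
  x <- as_batch(x)
  pre <- ly_forward(gam$children$sp2, ly_forward(gam$children$sp1, x))
  sigmoid(pre)
}

#' Full attention pass: weights and gated output
#'
#' The channel gate is computed from the input; the spatial gate from the
#' channel-refined map, as the gates are applied progressively.  The output
#' equals `x * channel_weights * spatial_weights`, so its magnitude never
#' exceeds the input's.
#'
#' @inheritParams channel_attention
#' @return List with `channel_weights`, `spatial_weights`, `output`.
#' @export
gam_forward <- function(gam, x) {
  x <- as_batch(x)
  cw <- channel_attention(gam, x)
  x2 <- x * cw
  sw <- spatial_attention(gam, x2)
  list(channel_weights = cw, spatial_weights = sw, output = x2 * sw)
}

#' @export
ly_forward.gam_block <- function(l, x, training = FALSE, keep = FALSE) {
  x <- as_batch(x)
  ch <- l$children
  cw <- sigmoid(ly_forward(ch$ch2, ly_forward(ch$ch1, x, training, keep),
                           training, keep))
  x2 <- x * cw
  sw <- sigmoid(ly_forward(ch$sp2, ly_forward(ch$sp1, x2, training, keep),
                           training, keep))
  if (keep) l$cache <- list(x = x, cw = cw, x2 = x2, sw = sw)
  x2 * sw
}

#' @export
ly_backward.gam_block <- function(l, dy) {
  ch <- l$children
  cc <- l$cache
  dx2 <- dy * cc$sw
  ds_pre <- dy * cc$x2 * cc$sw * (1 - cc$sw)
  dx2 <- dx2 + ly_backward(ch$sp1, ly_backward(ch$sp2, ds_pre))
  da_pre <- dx2 * cc$x * cc$cw * (1 - cc$cw)
  dx2 * cc$cw + ly_backward(ch$ch1, ly_backward(ch$ch2, da_pre))
}
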