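## Primitive differentiable layers.
##
## Every layer is a mutable environment carrying its parameters, a forward
## cache and, after a backward pass, the parameter gradients.  The graph is
## static (assembled once from a config), so reverse-mode differentiation is
## hand-derived per layer rather than taped: ly_forward() with keep = TRUE
## stores what the adjoint needs, ly_backward() consumes it and returns the
## input gradient.

ly_forward <- function(l, x, training = FALSE, keep = FALSE) {
  UseMethod("ly_forward")
}
ly_backward <- function(l, dy) UseMethod("ly_backward")

# Names of the trainable fields of a primitive layer.
ly_param_names <- function(l) UseMethod("ly_param_names")
#' @export
ly_param_names.default <- function(l) character(0)

new_layer <- function(class, fields) {
  e <- list2env(fields, parent = emptyenv())
  e$cache <- NULL
  e$grads <- NULL
  class(e) <- c(class, "layer")
  e
}

## ---- convolution (+ optional batch norm + activation) -----------------------

#' Convolution layer with optional batch normalisation and ReLU
#'
#' Implements the network's basic operation: a cross-correlation with an
#' `M x N` kernel and stride `step`, followed (optionally) by batch
#' normalisation and a ReLU.  A bias is carried only when batch
#' normalisation is off, where its role is not already played by the
#' normalisation shift.
#'
#' @param in_c,out_c input and output channel counts.
#' @param kh,kw kernel height and width.
#' @param stride stride, shared by both axes.
#' @param padding `"valid"` or `"same"`.
#' @param use_bn apply batch normalisation after the convolution.
#' @param activation `"relu"` or `"none"`.
#' @param name layer name used in parameter audits.
#' @return A layer object; apply it with the internal forward pass or through
#'   [conv_bn_relu()].
#' @export
conv_layer <- function(in_c, out_c, kh = 3L, kw = kh, stride = 1L,
                       padding = c("valid", "same"), use_bn = TRUE,
                       activation = c("relu", "none"), name = "conv") {
  padding <- match.arg(padding)
  activation <- match.arg(activation)
  stopifnot(kh >= 1L, kw >= 1L, stride >= 1L, out_c >= 1L, in_c >= 1L)
  K <- in_c * kh * kw
  l <- new_layer("conv_layer", list(
    in_c = as.integer(in_c), out_c = as.integer(out_c),
    kh = as.integer(kh), kw = as.integer(kw), stride = as.integer(stride),
    padding = padding, use_bn = use_bn, activation = activation, name = name,
    W = matrix(0, K, out_c),
    bn_eps = 1e-5, bn_momentum = 0.1
  ))
  if (use_bn) {
    l$gamma <- rep(1, out_c)
    l$beta <- rep(0, out_c)
    l$run_mean <- rep(0, out_c)
    l$run_var <- rep(1, out_c)
  } else {
    l$b <- rep(0, out_c)
  }
  init_layer_weights(l, "he")
  l
}

#' @export
ly_param_names.conv_layer <- function(l) {
  if (l$use_bn) c("W", "gamma", "beta") else c("W", "b")
}

#' @export
ly_forward.conv_layer <- function(l, x, training = FALSE, keep = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  if (d[1L] != l$in_c) {
    stop("configuration error: layer '", l$name, "' expects ", l$in_c,
         " input channels, got ", d[1L])
  }
  H <- d[2L]; W <- d[3L]; B <- d[4L]
  oh <- conv_out_dim(H, l$kh, l$stride, l$padding)
  ow <- conv_out_dim(W, l$kw, l$stride, l$padding)
  ph <- pad_before(H, l$kh, l$stride, l$padding)
  pw <- pad_before(W, l$kw, l$stride, l$padding)
  z <- array(0, c(l$out_c, oh, ow, B))
  cols <- if (keep) vector("list", B) else NULL
  for (b in seq_len(B)) {
    cb <- im2col_chw(as.numeric(x[, , , b, drop = FALSE]), d[1L], H, W,
                     l$kh, l$kw, l$stride, ph, pw, oh, ow)
    z[, , , b] <- crossprod(l$W, cb)
    if (keep) cols[[b]] <- cb
  }
  n_pix <- oh * ow * B
  zm <- matrix(z, nrow = l$out_c)
  bn_cache <- NULL
  if (l$use_bn) {
    if (training) {
      mu <- rowMeans(zm)
      v <- rowMeans(zm * zm) - mu * mu
      v <- pmax(v, 0)
      inv_std <- 1 / sqrt(v + l$bn_eps)
      xhat <- (zm - mu) * inv_std
      l$run_mean <- (1 - l$bn_momentum) * l$run_mean + l$bn_momentum * mu
      l$run_var <- (1 - l$bn_momentum) * l$run_var + l$bn_momentum * v
    } else {
      inv_std <- 1 / sqrt(l$run_var + l$bn_eps)
      xhat <- (zm - l$run_mean) * inv_std
    }
    ym <- l$gamma * xhat + l$beta
    if (keep) bn_cache <- list(xhat = xhat, inv_std = inv_std,
                               train_stats = training)
  } else {
    ym <- zm + l$b
  }
  if (l$activation == "relu") ym[ym < 0] <- 0
  y <- array(ym, c(l$out_c, oh, ow, B))
  if (keep) {
    l$cache <- list(cols = cols, in_dim = d, oh = oh, ow = ow,
                    ph = ph, pw = pw, bn = bn_cache,
                    relu_mask = if (l$activation == "relu") ym > 0 else NULL)
  }
  y
}

#' @export
ly_backward.conv_layer <- function(l, dy) {
  cc <- l$cache
  if (is.null(cc)) stop("backward called without a cached forward pass")
  d <- cc$in_dim
  B <- d[4L]
  dym <- matrix(dy, nrow = l$out_c)
  if (!is.null(cc$relu_mask)) dym <- dym * cc$relu_mask
  grads <- list()
  if (l$use_bn) {
    bn <- cc$bn
    grads$gamma <- rowSums(dym * bn$xhat)
    grads$beta <- rowSums(dym)
    if (bn$train_stats) {
      dxhat <- dym * l$gamma
      dzm <- bn$inv_std *
        (dxhat - rowMeans(dxhat) - bn$xhat * rowMeans(dxhat * bn$xhat))
    } else {
      dzm <- dym * (l$gamma * bn$inv_std)
    }
  } else {
    grads$b <- rowSums(dym)
    dzm <- dym
  }
  dz <- array(dzm, c(l$out_c, cc$oh, cc$ow, B))
  dW <- matrix(0, nrow(l$W), ncol(l$W))
  dx <- array(0, d)
  for (b in seq_len(B)) {
    dYb <- matrix(dz[, , , b], l$out_c, cc$oh * cc$ow)
    dW <- dW + cc$cols[[b]] %*% t(dYb)
    dcols <- l$W %*% dYb
    dx[, , , b] <- col2im_chw(dcols, d[1L], d[2L], d[3L], l$kh, l$kw,
                              l$stride, cc$ph, cc$pw, cc$oh, cc$ow)
  }
  grads$W <- dW
  l$grads <- grads
  dx
}

## ---- max pooling -------------------------------------------------------------

max_pool_layer <- function(k = 3L, stride = 2L, name = "maxpool") {
  new_layer("max_pool_layer", list(k = as.integer(k),
                                   stride = as.integer(stride), name = name))
}

#' @export
ly_forward.max_pool_layer <- function(l, x, training = FALSE, keep = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  oh <- conv_out_dim(d[2L], l$k, l$stride, "valid")
  ow <- conv_out_dim(d[3L], l$k, l$stride, "valid")
  y <- array(0, c(d[1L], oh, ow, d[4L]))
  arg <- if (keep) vector("list", d[4L]) else NULL
  for (b in seq_len(d[4L])) {
    r <- maxpool_chw(as.numeric(x[, , , b, drop = FALSE]),
                     d[1L], d[2L], d[3L], l$k, l$stride)
    y[, , , b] <- r$values
    if (keep) arg[[b]] <- r$argmax
  }
  if (keep) l$cache <- list(in_dim = d, oh = oh, ow = ow, argmax = arg)
  y
}

#' @export
ly_backward.max_pool_layer <- function(l, dy) {
  cc <- l$cache
  d <- cc$in_dim
  dx <- array(0, d)
  n_in <- prod(d[1:3])
  for (b in seq_len(d[4L])) {
    dx[, , , b] <- maxpool_backward_chw(cc$argmax[[b]],
                                        as.numeric(dy[, , , b, drop = FALSE]),
                                        n_in)
  }
  dx
}

## ---- global average pool, dropout, dense ------------------------------------

gap_layer <- function(name = "gap") new_layer("gap_layer", list(name = name))

#' @export
ly_forward.gap_layer <- function(l, x, training = FALSE, keep = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  y <- apply(x, c(1L, 4L), mean)
  dim(y) <- c(d[1L], d[4L])
  if (keep) l$cache <- list(in_dim = d)
  y
}

#' @export
ly_backward.gap_layer <- function(l, dy) {
  d <- l$cache$in_dim
  scale <- 1 / (d[2L] * d[3L])
  dx <- array(0, d)
  for (b in seq_len(d[4L])) {
    dx[, , , b] <- array(rep(dy[, b] * scale, d[2L] * d[3L]), d[1:3])
  }
  dx
}

dropout_layer <- function(p = 0.2, name = "dropout") {
  new_layer("dropout_layer", list(p = p, name = name))
}

#' @export
ly_forward.dropout_layer <- function(l, x, training = FALSE, keep = FALSE) {
  if (!training || l$p <= 0) {
    if (keep) l$cache <- list(mask = NULL)
    return(x)
  }
  mask <- (runif(length(x)) >= l$p) / (1 - l$p)
  dim(mask) <- dim(x)
  if (keep) l$cache <- list(mask = mask)
  x * mask
}

#' @export
ly_backward.dropout_layer <- function(l, dy) {
  if (is.null(l$cache$mask)) dy else dy * l$cache$mask
}

dense_layer <- function(in_f, out_f, name = "fc") {
  l <- new_layer("dense_layer", list(in_f = as.integer(in_f),
                                     out_f = as.integer(out_f),
                                     name = name,
                                     W = matrix(0, in_f, out_f),
                                     b = rep(0, out_f)))
  init_layer_weights(l, "he")
  l
}

#' @export
ly_param_names.dense_layer <- function(l) c("W", "b")

#' @export
ly_forward.dense_layer <- function(l, x, training = FALSE, keep = FALSE) {
  # x: in_f x B matrix
  if (is.null(dim(x)) || length(dim(x)) != 2L) dim(x) <- c(l$in_f, length(x) / l$in_f)
  y <- crossprod(l$W, x) + l$b
  if (keep) l$cache <- list(x = x)
  y
}

#' @export
ly_backward.dense_layer <- function(l, dy) {
  x <- l$cache$x
  l$grads <- list(W = x %*% t(dy), b = rowSums(dy))
  l$W %*% dy
}

## ---- weight initialisation ---------------------------------------------------

# fan_in / fan_out follow the convolutional convention
# (channels x kernel area); He draws N(0, 2/fan_in), Xavier/Glorot
# N(0, 2/(fan_in+fan_out)), orthogonal takes the Q factor of a Gaussian
# matrix, plain normal uses sd 0.01.
init_layer_weights <- function(l, scheme = "he") {
  if (inherits(l, "conv_layer")) {
    fan_in <- l$in_c * l$kh * l$kw
    fan_out <- l$out_c * l$kh * l$kw
  } else if (inherits(l, "dense_layer")) {
    fan_in <- l$in_f
    fan_out <- l$out_f
  } else {
    return(invisible(l))
  }
  d <- dim(l$W)
  l$W <- switch(scheme,
    he = matrix(rnorm(prod(d), 0, sqrt(2 / fan_in)), d[1L], d[2L]),
    xavier = matrix(rnorm(prod(d), 0, sqrt(2 / (fan_in + fan_out))), d[1L], d[2L]),
    normal = matrix(rnorm(prod(d), 0, 0.01), d[1L], d[2L]),
    orthogonal = orthogonal_matrix(d[1L], d[2L]),
    stop("usage error: unknown initialisation scheme '", scheme, "'")
  )
  if (!is.null(l$b)) l$b[] <- 0
  if (!is.null(l$gamma)) { l$gamma[] <- 1; l$beta[] <- 0 }
  invisible(l)
}

orthogonal_matrix <- function(nr, nc) {
  big <- max(nr, nc)
  q <- qr.Q(qr(matrix(rnorm(big * big), big, big)))
  q[seq_len(nr), seq_len(nc), drop = FALSE]
}

# Zero out every trainable weight of a layer (used by ablation/identity tests).
zero_layer <- function(l) {
  for (p in ly_param_names(l)) l[[p]][] <- 0
  if (!is.null(l$gamma)) l$gamma[] <- 1  # BN scale stays at identity
  invisible(l)
}
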