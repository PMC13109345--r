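# Shared independent oracles and small fixtures.

# Direct sliding-window cross-correlation on one channel-first sample,
# independent of the im2col path.
oracle_conv <- function(x, W4, stride = 1L, pad_h = 0L, pad_w = 0L) {
  # x: C x H x W ; W4: out_c x in_c x kh x kw
  d <- dim(x); oc <- dim(W4)[1L]; kh <- dim(W4)[3L]; kw <- dim(W4)[4L]
  H <- d[2L] + 2L * pad_h; W <- d[3L] + 2L * pad_w
  xp <- array(0, c(d[1L], H, W))
  xp[, pad_h + seq_len(d[2L]), pad_w + seq_len(d[3L])] <- x
  oh <- (H - kh) %/% stride + 1L
  ow <- (W - kw) %/% stride + 1L
  y <- array(0, c(oc, oh, ow))
  for (o in seq_len(oc)) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    patch <- xp[, (i - 1L) * stride + seq_len(kh),
                (j - 1L) * stride + seq_len(kw), drop = FALSE]
    w_o <- array(W4[o, , , ], dim(patch))
    y[o, i, j] <- sum(patch * w_o)
  }
  y
}

# Conv weight matrix (K x out_c, channel-fastest rows) from a 4D kernel.
pack_kernel <- function(W4) {
  oc <- dim(W4)[1L]; ic <- dim(W4)[2L]; kh <- dim(W4)[3L]; kw <- dim(W4)[4L]
  Wm <- matrix(0, ic * kh * kw, oc)
  for (o in seq_len(oc)) {
    v <- numeric(ic * kh * kw)
    for (n in seq_len(kw)) for (m in seq_len(kh)) for (c in seq_len(ic)) {
      v[c + ic * (m - 1L) + ic * kh * (n - 1L)] <- W4[o, c, m, n]
    }
    Wm[, o] <- v
  }
  Wm
}

# Brute-force per-class metrics from raw label vectors (never touches the
# package's confusion-matrix path).
oracle_metrics <- function(true, pred, k = 6L) {
  prec <- rec <- f1 <- numeric(k)
  for (c in seq_len(k) - 1L) {
    tp <- sum(true == c & pred == c)
    fp <- sum(true != c & pred == c)
    fn <- sum(true == c & pred != c)
    prec[c + 1L] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c + 1L] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1L] <- if (prec[c + 1L] + rec[c + 1L] > 0) {
      2 * prec[c + 1L] * rec[c + 1L] / (prec[c + 1L] + rec[c + 1L])
    } else 0
  }
  list(accuracy = mean(true == pred), precision = mean(prec),
       recall = mean(rec), f1 = mean(f1))
}

# A one-channel-of-evidence toy grading model built from the package's own
# primitives: conv(relu) -> GAP -> linear head.  Exposes the "stem" stage
# for closed-form Grad-CAM checks.
toy_cam_model <- function(S = 16L, head_weight = 2) {
  conv <- conv_layer(3L, 1L, 3L, 3L, 1L, "same", use_bn = FALSE,
                     activation = "relu", name = "conv")
  fc <- dense_layer(1L, 6L, name = "fc")
  fc$W[] <- 0
  fc$W[1L, 3L] <- head_weight   # class 2 reads the channel
  fc$b[] <- 0
  m <- new.env()
  m$cfg <- list(input_size = S, n_classes = 6L)
  m$stages <- list(stem = conv,
                   pooled = maizegrader:::gap_layer(),
                   logits = fc)
  class(m) <- "irgam_model"
  m
}

easy_ear_sets <- function(n_per_level = 10L, size = 139L,
                          train_seed = 101L, test_seed = 202L) {
  list(train = generate_dataset(rep(n_per_level, 6L), "ear",
                                base_seed = train_seed, image_size = size),
       test = generate_dataset(rep(n_per_level, 6L), "ear",
                               base_seed = test_seed, image_size = size))
}

samples_to_batch <- function(samples) {
  d <- dim(samples[[1L]]$image)
  xb <- array(0, c(d, length(samples)))
  for (j in seq_along(samples)) xb[, , , j] <- samples[[j]]$image * 2 - 1
  xb
}

sample_levels <- function(samples) vapply(samples, `[[`, integer(1), "level")
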