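## Loss, optimiser, learning-rate schedule, augmentation and the training
## loop.

#' Training configuration
#'
#' Defaults follow the published training recipe: batch size 16, 300
#' epochs, Adam with cosine-annealed learning rate from `1e-4` down to
#' `1e-6` over one full cycle spanning the whole run, Adam moment decays
#' `beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-8`, He initialisation.
#'
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param lr_max,lr_min cosine schedule endpoints.
#' @param t_max schedule period in iterations; `NULL` means the total
#'   number of training iterations (no warm restarts).
#' @param beta1,beta2,epsilon Adam constants.
#' @param init initialisation scheme.
#' @param seed RNG seed making the run bit-reproducible.
#' @param augment expand the training pool with the three augmentation
#'   variants of every sample before training.
#' @param noise_sigma,brightness_factors,blur_sigma augmentation magnitudes
#'   (Gaussian pixel noise sd on the `[0,1]` scale; the two brightness
#'   factors one of which is drawn per variant; Gaussian blur sd in
#'   pixels).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16L, epochs = 300L,
                         lr_max = 1e-4, lr_min = 1e-6, t_max = NULL,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         init = "he", seed = 1L, augment = FALSE,
                         noise_sigma = 0.04,
                         brightness_factors = c(0.8, 1.2),
                         blur_sigma = 1.5) {
  stopifnot(lr_min > 0, lr_min < lr_max,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1, epsilon > 0,
            batch_size >= 1, epochs >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_max = lr_max, lr_min = lr_min, t_max = t_max,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 init = init, seed = as.integer(seed), augment = augment,
                 noise_sigma = noise_sigma,
                 brightness_factors = brightness_factors,
                 blur_sigma = blur_sigma),
            class = "train_config")
}

#' Multiclass cross-entropy loss
#'
#' `-(1/n) * sum_i log p_i[y_i]`, with probabilities clamped below at
#' `1e-12` before the logarithm.
#'
#' @param probs `B x K` matrix of predicted class probabilities (rows sum
#'   to 1).
#' @param labels integer labels in `0..K-1`, length `B`.
#' @return The mean negative log-likelihood.
#' @export
cross_entropy <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (nrow(probs) != length(labels)) {
    stop("usage error: ", nrow(probs), " probability rows but ",
         length(labels), " labels")
  }
  if (any(labels < 0L | labels >= ncol(probs))) {
    stop("usage error: labels must lie in 0..", ncol(probs) - 1L)
  }
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("usage error: probability rows must sum to 1")
  }
  p_true <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr_min + (lr_max - lr_min)/2 * (1 + cos(t * pi / t_max))`;
#' monotone non-increasing from `lr_max` at `t = 0` to `lr_min` at
#' `t = t_max` (one complete annealing cycle, no restarts).
#'
#' @param t iteration within the cycle, `0 <= t <= t_max`.
#' @param cfg a [train_config()] with `t_max` set, or a list with
#'   `lr_max`, `lr_min`, `t_max`.
#' @return The learning rate at iteration `t`.
#' @export
cosine_lr <- function(t, cfg) {
  if (is.null(cfg$t_max)) stop("usage error: cfg$t_max is not set")
  if (any(t < 0 | t > cfg$t_max)) {
    stop("usage error: t must lie in [0, ", cfg$t_max, "]")
  }
  cfg$lr_min + 0.5 * (cfg$lr_max - cfg$lr_min) * (1 + cos(t * pi / cfg$t_max))
}

## ---- Adam -------------------------------------------------------------------

#' Initialise Adam optimiser state
#'
#' @param params named list of numeric arrays (the trainable parameters).
#' @return An `adam_state` with zeroed first/second moments and `step_t = 0`.
#' @export
adam_init <- function(params) {
  structure(list(step_t = 0L,
                 m = lapply(params, function(p) { p[] <- 0; p }),
                 v = lapply(params, function(p) { p[] <- 0; p })),
            class = "adam_state")
}

# Shared update kernel for one parameter array.
adam_update <- function(theta, g, m, v, t, lr, beta1, beta2, epsilon) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  m_hat <- m / (1 - beta1^t)
  v_hat <- v / (1 - beta2^t)
  list(theta = theta - lr * m_hat / (sqrt(v_hat) + epsilon), m = m, v = v)
}

#' One Adam step over a named parameter list
#'
#' First/second moments are exponentially averaged with decay `beta1` /
#' `beta2`, bias-corrected by `1/(1 - beta^t)`, and the parameters moved by
#' `-lr * m_hat / (sqrt(v_hat) + epsilon)`.
#'
#' @param state an `adam_state`.
#' @param grads named list of gradients matching `params`.
#' @param params named list of parameter arrays.
#' @param lr learning rate for this step.
#' @param cfg a [train_config()] supplying `beta1`, `beta2`, `epsilon`.
#' @return List with updated `state` and `params`.
#' @export
adam_step <- function(state, grads, params, lr, cfg = train_config()) {
  stopifnot(identical(names(grads), names(params)))
  t <- state$step_t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (any(!is.finite(g))) {
      stop("numeric error: non-finite gradient for parameter '", nm, "'")
    }
    u <- adam_update(params[[nm]], g, state$m[[nm]], state$v[[nm]],
                     t, lr, cfg$beta1, cfg$beta2, cfg$epsilon)
    params[[nm]] <- u$theta
    state$m[[nm]] <- u$m
    state$v[[nm]] <- u$v
  }
  state$step_t <- t
  list(state = state, params = params)
}

# Flat named list of every trainable array in a model, as
# "<layer>.<field>" entries, plus helpers to read gradients and write
# updates in place.
model_param_list <- function(model) {
  layers <- model_layer_list(model)
  out <- list()
  for (nm in names(layers)) {
    for (f in ly_param_names(layers[[nm]])) {
      out[[paste0(nm, ".", f)]] <- layers[[nm]][[f]]
    }
  }
  out
}

model_grad_list <- function(model) {
  layers <- model_layer_list(model)
  out <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    for (f in ly_param_names(l)) {
      g <- l$grads[[f]]
      if (is.null(g)) { g <- l[[f]]; g[] <- 0 }
      out[[paste0(nm, ".", f)]] <- g
    }
  }
  out
}

model_set_params <- function(model, params) {
  layers <- model_layer_list(model)
  for (nm in names(layers)) {
    for (f in ly_param_names(layers[[nm]])) {
      layers[[nm]][[f]] <- params[[paste0(nm, ".", f)]]
    }
  }
  invisible(model)
}

## ---- augmentation -----------------------------------------------------------

#' Three-variant augmentation of one image sample
#'
#' Produces exactly three variants — Gaussian pixel noise, a brightness
#' rescale, and a Gaussian blur — with the label unchanged and pixels
#' clipped back to `[0, 1]`.  Deterministic under `seed`.
#'
#' @param smp an `image_sample` (list with `image` = `3 x H x W` array in
#'   `[0,1]` plus label metadata), or a bare `3 x H x W` array.
#' @param seed RNG seed.
#' @param noise_sigma sd of the additive Gaussian noise.
#' @param brightness_factors the two candidate brightness factors; one is
#'   drawn at random.
#' @param blur_sigma sd (pixels) of the Gaussian blur.
#' @return List of three augmented samples in the order noise, brightness,
#'   blur.
#' @export
augment_sample <- function(smp, seed = 1L, noise_sigma = 0.04,
                           brightness_factors = c(0.8, 1.2),
                           blur_sigma = 1.5) {
  bare <- is.array(smp)
  img <- if (bare) smp else smp$image
  stopifnot(min(img) >= 0, max(img) <= 1)
  set.seed(seed)
  noisy <- pmin(pmax(img + array(rnorm(length(img), 0, noise_sigma),
                                 dim(img)), 0), 1)
  fac <- sample(brightness_factors, 1L)
  bright <- pmin(pmax(img * fac, 0), 1)
  blurred <- if (blur_sigma > 0) {
    # EBImage works on H x W x C
    hw <- aperm(img, c(2L, 3L, 1L))
    b <- EBImage::gblur(EBImage::Image(hw, colormode = "Color"),
                        sigma = blur_sigma)
    pmin(pmax(aperm(as.array(b), c(3L, 1L, 2L)), 0), 1)
  } else {
    img
  }
  wrap <- function(x, tag) {
    if (bare) return(x)
    out <- smp
    out$image <- x
    out$id <- paste0(out$id %||% "sample", "_", tag)
    out
  }
  list(wrap(noisy, "noise"), wrap(bright, "brightness"), wrap(blurred, "blur"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- training loop ----------------------------------------------------------

#' Train a model on labelled image samples
#'
#' Minibatch gradient descent with Adam and a cosine-annealed learning rate
#' over one cycle spanning the full run.  Images arrive on the `[0, 1]`
#' scale and are mapped to `[-1, 1]` before entering the network.  The run
#' is bit-reproducible under `cfg$seed`.
#'
#' @param model an `irgam_model` (modified in place).
#' @param samples list of `image_sample`s (fields `image`, `level`).
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return List with the trained `model` and `history`, a data frame of
#'   (epoch, mean_loss, lr).
#' @export
train <- function(model, samples, cfg = train_config(), verbose = FALSE) {
  if (length(samples) == 0L) stop("usage error: empty training set")
  set.seed(cfg$seed)
  if (cfg$augment) {
    aug <- list()
    for (i in seq_along(samples)) {
      aug <- c(aug, augment_sample(samples[[i]],
                                   seed = cfg$seed + i,
                                   noise_sigma = cfg$noise_sigma,
                                   brightness_factors = cfg$brightness_factors,
                                   blur_sigma = cfg$blur_sigma))
    }
    samples <- c(samples, aug)
    set.seed(cfg$seed)  # augmentation draws must not shift the train stream
  }
  n <- length(samples)
  iters_per_epoch <- ceiling(n / cfg$batch_size)
  t_max <- cfg$t_max %||% max(cfg$epochs * iters_per_epoch, 1L)
  sched <- list(lr_max = cfg$lr_max, lr_min = cfg$lr_min, t_max = t_max)

  params <- model_param_list(model)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                        lr = numeric(0))
  iter <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    lr <- cfg$lr_max
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- array(0, c(dim(samples[[idx[1L]]]$image), length(idx)))
      yb <- integer(length(idx))
      for (j in seq_along(idx)) {
        xb[, , , j] <- samples[[idx[j]]]$image * 2 - 1
        yb[j] <- samples[[idx[j]]]$level
      }
      lr <- cosine_lr(min(iter, t_max), sched)
      logits <- model_forward(model, xb, training = TRUE, keep = TRUE)
      p <- softmax(t(logits))
      losses <- c(losses, cross_entropy(p, yb))
      dlogits <- t(p)
      dlogits[cbind(yb + 1L, seq_along(yb))] <-
        dlogits[cbind(yb + 1L, seq_along(yb))] - 1
      dlogits <- dlogits / length(yb)
      model_backward(model, dlogits)
      upd <- adam_step(state, model_grad_list(model), params, lr, cfg)
      state <- upd$state
      params <- upd$params
      model_set_params(model, params)
      iter <- iter + 1L
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         mean_loss = mean(losses), lr = lr))
    if (verbose) {
      message(sprintf("[%s] epoch %d/%d  loss %.4f  lr %.2e",
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                      epoch, cfg$epochs, mean(losses), lr))
    }
  }
  list(model = model, history = history)
}
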