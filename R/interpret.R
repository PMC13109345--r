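## Grad-CAM class-activation heatmaps and a mask-based localization score.

#' Gradient-weighted class activation map
#'
#' Backpropagates the target class logit to a chosen convolutional stage,
#' global-averages the gradient per channel to get channel weights, forms
#' `ReLU(sum_c w_c A_c)`, bilinearly upsamples to the input resolution and
#' min-max normalises to `[0, 1]`.  A raw map that is identically zero is
#' returned as an all-zero heatmap rather than NaN.
#'
#' The default stage is the attention output (the last full-resolution
#' convolutional representation); any stage tag of the model may be chosen.
#'
#' @param model an `irgam_model`.
#' @param image `3 x S x S` array on the `[0, 1]` scale.
#' @param target_class grade level 0..5 whose evidence is mapped.
#' @param layer stage tag: one of `names(model$stages)` before the pooling
#'   stage, e.g. `"stem"`, `"block_a"`, `"reduction_a"`, `"block_b"`,
#'   `"reduction_b"`, `"gam"`.
#' @return A `cam_heatmap`: list with `values` (`S x S` in `[0,1]`),
#'   `target_layer`, `target_class`.
#' @export
grad_cam <- function(model, image, target_class, layer = "gam") {
  conv_stages <- setdiff(names(model$stages), c("pooled", "dropout", "logits"))
  if (!layer %in% conv_stages) {
    stop("usage error: layer '", layer, "' not found; choose one of ",
         paste(conv_stages, collapse = ", "))
  }
  if (target_class < 0L || target_class > model$cfg$n_classes - 1L) {
    stop("usage error: target_class must lie in 0..",
         model$cfg$n_classes - 1L)
  }
  x <- image * 2 - 1
  model_forward(model, x, training = FALSE, keep = TRUE, collect = TRUE)
  dlogits <- matrix(0, model$cfg$n_classes, 1L)
  dlogits[target_class + 1L, 1L] <- 1
  model_backward(model, dlogits, collect = TRUE)
  A <- model$activations[[layer]]
  dA <- model$stage_grads[[layer]]
  C <- dim(A)[1L]
  w <- apply(dA[, , , 1L, drop = FALSE], 1L, mean)
  cam <- apply(array(A[, , , 1L] * w, dim(A)[1:3]), c(2L, 3L), sum)
  cam[cam < 0] <- 0
  s <- dim(as_batch(x))[2L]
  cam_up <- as.array(EBImage::resize(EBImage::Image(cam), w = s, h = s))
  rng <- range(cam_up)
  values <- if (rng[2] > rng[1]) {
    (cam_up - rng[1]) / (rng[2] - rng[1])
  } else if (rng[2] > 0) {
    array(1, dim(cam_up))  # constant positive map
  } else {
    array(0, dim(cam_up))
  }
  structure(list(values = values, target_layer = layer,
                 target_class = as.integer(target_class)),
            class = "cam_heatmap")
}

#' Fraction of heatmap mass inside an object mask
#'
#' `sum(heatmap * mask) / sum(heatmap)`; 0 for an all-zero heatmap.  For a
#' heatmap no better than uniform this equals the mask's area fraction, so
#' values above that fraction indicate localized attention.
#'
#' @param cam a `cam_heatmap` (or bare `H x W` array).
#' @param mask binary/logical `H x W` object mask.
#' @return Score in `[0, 1]`.
#' @export
localization_score <- function(cam, mask) {
  v <- if (inherits(cam, "cam_heatmap")) cam$values else cam
  if (!identical(dim(v), dim(mask))) {
    stop("usage error: heatmap and mask shapes differ")
  }
  tot <- sum(v)
  if (tot == 0) return(0)
  sum(v * (mask != 0)) / tot
}

#' Write a heatmap overlay PNG
#'
#' Blends the input image with a red-yellow rendering of the heatmap.
#'
#' @param image `3 x H x W` array in `[0, 1]`.
#' @param cam a `cam_heatmap` or `H x W` array in `[0, 1]`.
#' @param path output PNG path.
#' @param alpha blend weight of the heatmap.
#' @return `path`, invisibly.
#' @export
cam_overlay_png <- function(image, cam, path, alpha = 0.45) {
  v <- if (inherits(cam, "cam_heatmap")) cam$values else cam
  hw <- aperm(image, c(2L, 3L, 1L))
  heat <- array(0, dim(hw))
  heat[, , 1] <- v               # red ramp
  heat[, , 2] <- v^2 * 0.9       # yellow tip
  out <- pmin(pmax((1 - alpha) * hw + alpha * heat, 0), 1)
  EBImage::writeImage(EBImage::Image(out, colormode = "Color"), path)
  invisible(path)
}
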