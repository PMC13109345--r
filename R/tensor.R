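## Internal tensor conventions.
##
## A feature map is a numeric array with dim c(C, H, W); a batch is
## c(C, H, W, B).  Channel-first with channel fastest makes per-channel
## batch-norm statistics a matrix(x, nrow = C) away, and matches the GEMM
## layout of the im2col kernels.

#' Spatial size of a convolution or pooling output
#'
#' Standard convolution arithmetic: `valid` gives `floor((n - k)/s) + 1`,
#' `same` gives `ceiling(n / s)` (zero padding split as evenly as possible,
#' extra pixel on the trailing side).
#'
#' @param n input spatial extent.
#' @param k kernel extent.
#' @param stride stride (>= 1).
#' @param padding `"valid"` or `"same"`.
#' @return Integer output extent.
#' @export
conv_out_dim <- function(n, k, stride = 1L, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  if (padding == "valid") {
    if (n < k) {
      stop("configuration error: spatial extent ", n,
           " smaller than kernel ", k, " under valid padding")
    }
    (n - k) %/% stride + 1L
  } else {
    as.integer(ceiling(n / stride))
  }
}

# Leading (top/left) padding for one axis; trailing pad is implied by the
# output size used in im2col.
pad_before <- function(n, k, stride, padding) {
  if (padding == "valid") return(0L)
  o <- as.integer(ceiling(n / stride))
  total <- max((o - 1L) * stride + k - n, 0L)
  total %/% 2L
}

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("expected a C x H x W array or C x H x W x B batch")
  }
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

batch_size <- function(x) dim(x)[4L]

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Softmax over the rows of a logit matrix
#'
#' Numerically stabilised by subtracting the row maximum.
#'
#' @param logits numeric matrix (samples in rows) or vector.
#' @return Matrix of probabilities; each row sums to one.
#' @export
softmax <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (any(!is.finite(logits))) stop("numeric error: non-finite logits")
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
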