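## Model configuration and assembly.

#' Architecture configuration
#'
#' Collects every width, depth and attention choice of the grading network.
#' The defaults are the frozen reference configuration: stem ending at 256
#' channels, five A-blocks, Reduction-A to 896 channels (384 conv + 256 ERF
#' + 256 pool pass-through), ten B-blocks, Reduction-B to 1792 channels,
#' attention compression rate 16, dropout 0.2 before the 6-way head.  Block
#' depths and branch widths are freely stackable; the reference values are
#' chosen so that the float32 parameter audit matches the published model
#' size.
#'
#' @param input_size square input resolution (pixels).
#' @param n_classes number of grade levels (fixed at 6).
#' @param dropout dropout fraction before the classification head.
#' @param stem_conv,stem_erf stem widths.
#' @param n_blocks_a,a_br1,a_br2,a_erf A-stack depth and branch widths.
#' @param ra_conv,ra_erf Reduction-A branch widths.
#' @param n_blocks_b,b_br1,b_br2 B-stack depth and branch widths.
#' @param rb_br1,rb_br2,rb_erf Reduction-B branch widths.
#' @param gam_rate,gam_spatial_kernel attention gate parameters.
#' @return An `irgam_config` object (a validated named list).
#' @export
irgam_config <- function(input_size = 299L, n_classes = 6L, dropout = 0.2,
                         stem_conv = c(32L, 32L, 64L),
                         stem_erf = c(80L, 192L, 256L),
                         n_blocks_a = 5L, a_br1 = 32L, a_br2 = c(32L, 32L),
                         a_erf = c(32L, 48L, 64L),
                         ra_conv = 384L, ra_erf = c(192L, 224L, 256L),
                         n_blocks_b = 10L, b_br1 = 176L,
                         b_br2 = c(144L, 148L, 184L),
                         rb_br1 = c(256L, 384L), rb_br2 = c(256L, 256L),
                         rb_erf = c(256L, 256L, 256L),
                         gam_rate = 16L, gam_spatial_kernel = 7L) {
  cfg <- list(input_size = as.integer(input_size),
              n_classes = as.integer(n_classes), dropout = dropout,
              stem_conv = as.integer(stem_conv), stem_erf = as.integer(stem_erf),
              n_blocks_a = as.integer(n_blocks_a), a_br1 = as.integer(a_br1),
              a_br2 = as.integer(a_br2), a_erf = as.integer(a_erf),
              ra_conv = as.integer(ra_conv), ra_erf = as.integer(ra_erf),
              n_blocks_b = as.integer(n_blocks_b), b_br1 = as.integer(b_br1),
              b_br2 = as.integer(b_br2),
              rb_br1 = as.integer(rb_br1), rb_br2 = as.integer(rb_br2),
              rb_erf = as.integer(rb_erf),
              gam_rate = as.integer(gam_rate),
              gam_spatial_kernel = as.integer(gam_spatial_kernel))
  class(cfg) <- "irgam_config"
  validate_config(cfg)
  cfg
}

# Stage channel widths implied by a config.
config_widths <- function(cfg) {
  stem_out <- cfg$stem_erf[3L]
  ra_out <- cfg$ra_conv + cfg$ra_erf[3L] + stem_out
  rb_out <- cfg$rb_br1[2L] + cfg$rb_br2[2L] + cfg$rb_erf[3L] + ra_out
  list(stem = stem_out, reduction_a = ra_out, reduction_b = rb_out)
}

validate_config <- function(cfg) {
  w <- config_widths(cfg)
  if (cfg$n_classes != 6L) {
    stop("configuration error: the grading task has exactly 6 levels, ",
         "got n_classes = ", cfg$n_classes)
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) {
    stop("configuration error: dropout must lie in [0, 1)")
  }
  if (cfg$input_size < 32L) {
    stop("configuration error: input_size ", cfg$input_size,
         " too small for the stem's stride schedule")
  }
  if (w$reduction_b %% cfg$gam_rate != 0L) {
    stop("configuration error: attention input channels (", w$reduction_b,
         ") not divisible by gam_rate (", cfg$gam_rate, ")")
  }
  expected_ra <- cfg$ra_conv + cfg$ra_erf[3L] + w$stem
  if (expected_ra != w$reduction_a) {
    stop("configuration error: Reduction-A branch widths do not sum to ",
         "its declared output")
  }
  invisible(cfg)
}

#' Reduced-width configuration for fast experiments and tests
#'
#' Same topology as the reference network with every width cut down and a
#' single block per stack, suitable for CPU-scale training on small
#' synthetic scenes.
#'
#' @param input_size square input resolution (default 139, which the stem's
#'   stride schedule maps to a 15 x 15 feature map).
#' @param n_blocks_a,n_blocks_b stack depths.
#' @return An `irgam_config`.
#' @export
irgam_tiny_config <- function(input_size = 139L, n_blocks_a = 1L,
                              n_blocks_b = 1L) {
  irgam_config(input_size = input_size, dropout = 0.1,
               stem_conv = c(8L, 8L, 16L), stem_erf = c(16L, 24L, 32L),
               n_blocks_a = n_blocks_a, a_br1 = 8L, a_br2 = c(8L, 8L),
               a_erf = c(8L, 12L, 16L),
               ra_conv = 16L, ra_erf = c(16L, 16L, 16L),
               n_blocks_b = n_blocks_b, b_br1 = 16L, b_br2 = c(16L, 16L, 16L),
               rb_br1 = c(16L, 32L), rb_br2 = c(16L, 32L),
               rb_erf = c(16L, 16L, 32L),
               gam_rate = 4L)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return `read_config` returns an `irgam_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(irgam_config, raw)
}

#' @rdname read_config
#' @param cfg configuration to serialise.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Load the frozen reference configuration shipped with the package
#'
#' @return An `irgam_config`.
#' @export
reference_config <- function() {
  read_config(system.file("configs", "irgam_reference.yaml",
                          package = "maizegrader", mustWork = TRUE))
}

## ---- assembly ---------------------------------------------------------------

ablation_variants <- c("full", "drop_a", "drop_b",
                       "reduction_to_strided_conv", "no_gam")

#' Build the grading network
#'
#' Assembles stem -> A-block stack -> Reduction-A -> B-block stack ->
#' Reduction-B -> attention -> global average pool -> dropout -> 6-way
#' linear head, He-initialised by default.
#'
#' @param cfg an [irgam_config()].
#' @param variant ablation variant: `"full"` (the unmodified network),
#'   `"drop_a"`/`"drop_b"` (remove a block stack), `"reduction_to_strided_conv"`
#'   (replace each reduction by a single stride-2 `3x3` convolution with the
#'   same output width), `"no_gam"` (remove the attention stage).
#' @param init initialisation scheme (`"he"`, `"xavier"`, `"orthogonal"`,
#'   `"normal"`).
#' @param seed RNG seed for the initial weights; the build is bit-identical
#'   under the same seed.
#' @return An `irgam_model` object.
#' @export
build_model <- function(cfg, variant = "full", init = "he", seed = NULL) {
  validate_config(cfg)
  if (!variant %in% ablation_variants) {
    stop("usage error: unknown ablation variant '", variant, "'; choose one of ",
         paste(ablation_variants, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  w <- config_widths(cfg)
  stages <- list()
  stages$stem <- stem_module(3L, cfg$stem_conv, cfg$stem_erf)

  if (variant != "drop_a" && cfg$n_blocks_a > 0L) {
    blocks <- lapply(seq_len(cfg$n_blocks_a), function(i) {
      inception_resnet_a(w$stem, cfg$a_br1, cfg$a_br2, cfg$a_erf,
                         name = paste0("a", i))
    })
    names(blocks) <- paste0("a", seq_along(blocks))
    stages$block_a <- seq_module(blocks, name = "block_a")
  }

  stages$reduction_a <- if (variant == "reduction_to_strided_conv") {
    conv_layer(w$stem, w$reduction_a, 3L, 3L, stride = 2L, padding = "valid",
               name = "reduction_a_strided")
  } else {
    reduction_a(w$stem, cfg$ra_conv, cfg$ra_erf)
  }

  if (variant != "drop_b" && cfg$n_blocks_b > 0L) {
    blocks <- lapply(seq_len(cfg$n_blocks_b), function(i) {
      inception_resnet_b(w$reduction_a, cfg$b_br1, cfg$b_br2,
                         name = paste0("b", i))
    })
    names(blocks) <- paste0("b", seq_along(blocks))
    stages$block_b <- seq_module(blocks, name = "block_b")
  }

  stages$reduction_b <- if (variant == "reduction_to_strided_conv") {
    conv_layer(w$reduction_a, w$reduction_b, 3L, 3L, stride = 2L,
               padding = "valid", name = "reduction_b_strided")
  } else {
    reduction_b(w$reduction_a, cfg$rb_br1, cfg$rb_br2, cfg$rb_erf)
  }

  if (variant != "no_gam") {
    stages$gam <- gam_module(w$reduction_b, cfg$gam_rate,
                             cfg$gam_spatial_kernel)
  }
  stages$pooled <- gap_layer()
  stages$dropout <- dropout_layer(cfg$dropout)
  stages$logits <- dense_layer(w$reduction_b, cfg$n_classes, name = "fc")

  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$variant <- variant
  m$stages <- stages
  class(m) <- "irgam_model"
  init_params(m, init)
  m
}

#' @rdname build_model
#' @export
build_ablation_variant <- function(cfg, variant, init = "he", seed = NULL) {
  build_model(cfg, variant = variant, init = init, seed = seed)
}

#' Apply a single convolution layer (Conv + BN + ReLU)
#'
#' Functional wrapper over a [conv_layer()] for one-off use.
#'
#' @param layer a [conv_layer()].
#' @param x input feature map (`C x H x W` or batched).
#' @param training use batch statistics in the normalisation.
#' @return Output feature map.
#' @export
conv_bn_relu <- function(layer, x, training = FALSE) {
  ly_forward(layer, x, training = training)
}

model_layer_list <- function(model) {
  out <- list()
  for (nm in names(model$stages)) {
    out <- c(out, module_layers(model$stages[[nm]], paste0(nm, ".")))
  }
  out
}

#' Forward pass through the full network
#'
#' @param model an `irgam_model`.
#' @param x input batch `3 x S x S (x B)` on the `[-1, 1]` scale, where `S`
#'   is the configured input size.
#' @param training batch-statistics mode (and active dropout).
#' @param keep cache intermediates for a subsequent backward pass.
#' @param collect store per-stage activations in `model$activations`.
#' @return Logit matrix `n_classes x B`.
#' @export
model_forward <- function(model, x, training = FALSE, keep = FALSE,
                          collect = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  s <- model$cfg$input_size
  if (d[1L] != 3L || d[2L] != s || d[3L] != s) {
    stop("shape error: expected a 3 x ", s, " x ", s,
         " input, got ", paste(d[1:3], collapse = " x "))
  }
  acts <- if (collect) list(input = x) else NULL
  for (nm in names(model$stages)) {
    x <- ly_forward(model$stages[[nm]], x, training = training, keep = keep)
    if (collect) acts[[nm]] <- x
  }
  if (collect) model$activations <- acts
  x
}

#' Backward pass; optionally records per-stage activation gradients
#'
#' Must follow a `model_forward(..., keep = TRUE)` on the same model.
#'
#' @param model an `irgam_model`.
#' @param dlogits gradient of the objective w.r.t. the logits
#'   (`n_classes x B`).
#' @param collect store the gradient arriving at each stage output in
#'   `model$stage_grads`.
#' @return Gradient w.r.t. the input batch (invisibly).
#' @export
model_backward <- function(model, dlogits, collect = FALSE) {
  grads <- if (collect) list() else NULL
  dy <- dlogits
  for (nm in rev(names(model$stages))) {
    if (collect) grads[[nm]] <- dy
    dy <- ly_backward(model$stages[[nm]], dy)
  }
  if (collect) model$stage_grads <- grads
  invisible(dy)
}

#' Class probabilities and predicted grade for input images
#'
#' Softmax over the six logits.  The predicted level is the arg-max
#' probability; exact ties resolve toward the lower grade (conservative
#' grading).
#'
#' @param model an `irgam_model`.
#' @param x input `3 x S x S` array or `3 x S x S x B` batch on `[-1, 1]`.
#' @return Matrix `B x 6` of probabilities (rows sum to 1), with the
#'   predicted levels in `attr(, "level")` (integers 0-5).
#' @export
predict_proba <- function(model, x) {
  logits <- model_forward(model, x, training = FALSE)
  p <- softmax(t(logits))
  colnames(p) <- paste0("level", 0:(ncol(p) - 1L))
  attr(p, "level") <- apply(p, 1L, which.max) - 1L
  p
}

#' @rdname predict_proba
#' @return `predict_level` returns the integer grade vector only.
#' @export
predict_level <- function(model, x) {
  as.integer(attr(predict_proba(model, x), "level"))
}

#' (Re-)initialise all trainable parameters of a model
#'
#' Convolution and dense weights are drawn per the chosen scheme (He:
#' `N(0, 2/fan_in)`; Xavier: `N(0, 2/(fan_in+fan_out))`; orthogonal: Q
#' factor of a Gaussian matrix; normal: `N(0, 0.01^2)`); biases are zeroed,
#' batch-norm scale/shift reset to (1, 0) and running statistics to (0, 1).
#'
#' @param model an `irgam_model`.
#' @param scheme one of `"he"`, `"xavier"`, `"orthogonal"`, `"normal"`.
#' @param seed optional RNG seed; identical seeds give bit-identical weights.
#' @return The model, invisibly (modified in place).
#' @export
init_params <- function(model, scheme = "he", seed = NULL) {
  if (!scheme %in% c("he", "xavier", "orthogonal", "normal")) {
    stop("usage error: unknown initialisation scheme '", scheme, "'")
  }
  if (!is.null(seed)) set.seed(seed)
  for (l in model_layer_list(model)) {
    init_layer_weights(l, scheme)
    if (!is.null(l$run_mean)) { l$run_mean[] <- 0; l$run_var[] <- 1 }
  }
  invisible(model)
}

## ---- checkpointing ----------------------------------------------------------

model_state <- function(model) {
  layers <- model_layer_list(model)
  state <- lapply(layers, function(l) {
    fields <- c(ly_param_names(l),
                intersect(c("run_mean", "run_var"), ls(l)))
    stats::setNames(lapply(fields, function(f) l[[f]]), fields)
  })
  state
}

#' Save / load model weights
#'
#' The checkpoint stores the configuration, the ablation variant and every
#' trainable parameter plus batch-norm running statistics, so the model can
#' be rebuilt exactly.
#'
#' @param model an `irgam_model`.
#' @param path checkpoint file (`.rds`).
#' @return `save_model` returns `path`; `load_model` the restored model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg), variant = model$variant,
               state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_model(do.call(irgam_config, ck$cfg), variant = ck$variant)
  layers <- model_layer_list(model)
  stopifnot(identical(names(layers), names(ck$state)))
  for (nm in names(layers)) {
    for (f in names(ck$state[[nm]])) layers[[nm]][[f]] <- ck$state[[nm]][[f]]
  }
  model
}
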