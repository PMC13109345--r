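## Preprocessing and experiment orchestration.

#' Load and preprocess one image file
#'
#' Reads a PNG/JPEG, center-crops to a square, bilinearly resizes to the
#' network input size and rescales pixels from `[0, 1]` to `[-1, 1]`
#' (symmetric normalisation); fully deterministic.  An already-square,
#' already-sized image is only rescaled.
#'
#' @param path image file path.
#' @param size target square size (network input resolution).
#' @param normalize map to `[-1, 1]`; set `FALSE` to keep `[0, 1]`.
#' @return `3 x size x size` array.
#' @export
preprocess_image <- function(path, size = 299L, normalize = TRUE) {
  if (!file.exists(path)) stop("I/O error: cannot read image '", path, "'")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) {
                    stop("I/O error: cannot read image '", path, "': ",
                         conditionMessage(e))
                  })
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  w <- dim(a)[1L]; h <- dim(a)[2L]
  side <- min(w, h)
  ox <- (w - side) %/% 2L
  oy <- (h - side) %/% 2L
  a <- a[ox + seq_len(side), oy + seq_len(side), , drop = FALSE]
  if (side != size) {
    a <- as.array(EBImage::resize(EBImage::Image(a, colormode = "Color"),
                                  w = size, h = size))
  }
  x <- aperm(a, c(3L, 1L, 2L))
  x <- pmin(pmax(x, 0), 1)
  if (normalize) x * 2 - 1 else x
}

#' Predict grade levels for image files
#'
#' @param model an `irgam_model` or a checkpoint path.
#' @param paths character vector of image paths.
#' @return Data frame with one row per image: `path`, `level`, and the six
#'   class probabilities; unreadable files yield an `error` entry instead.
#' @export
predict_images <- function(model, paths) {
  if (is.character(model)) model <- load_model(model)
  size <- model$cfg$input_size
  rows <- lapply(paths, function(p) {
    x <- tryCatch(preprocess_image(p, size), error = function(e) e)
    if (inherits(x, "error")) {
      return(data.frame(path = p, level = NA_integer_,
                        t(stats::setNames(rep(NA_real_, 6),
                                          paste0("p", 0:5))),
                        error = conditionMessage(x)))
    }
    pr <- softmax(t(model_forward(model, x)))
    data.frame(path = p, level = which.max(pr[1L, ]) - 1L,
               t(stats::setNames(as.numeric(pr[1L, ]), paste0("p", 0:5))),
               error = NA_character_)
  })
  do.call(rbind, rows)
}

config_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(obj, tmp)
  unname(substr(tools::md5sum(tmp), 1L, 8L))
}

log_line <- function(..., verbose = TRUE) {
  if (verbose) {
    message(format(Sys.time(), "[%Y-%m-%dT%H:%M:%S] "), ...)
  }
}

#' Run a full experiment command
#'
#' Thin orchestration over the package's functions, mirroring the
#' command-line interface.  Each command writes its artifacts under
#' `out_dir`, with the configuration hash embedded in filenames so runs
#' are attributable to their exact settings.
#'
#' @param command one of `"synthesize"`, `"train"`, `"eval"`, `"predict"`,
#'   `"gradcam"`, `"ablate"`, `"audit"`.
#' @param arch an [irgam_config()].
#' @param train_cfg a [train_config()].
#' @param out_dir output directory.
#' @param n_per_level synthetic per-level counts (synthesize/train/eval).
#' @param organ `"ear"` or `"tassel"`.
#' @param checkpoint model checkpoint path (eval/predict/gradcam); written
#'   by train.
#' @param image_paths image files for predict/gradcam.
#' @param seed seed for data generation and splits.
#' @param verbose log progress lines.
#' @return Invisibly, a list of produced artifact paths (plus command
#'   results where natural, e.g. the metrics report for `eval`).
#' @export
run_experiment <- function(command = c("synthesize", "train", "eval",
                                       "predict", "gradcam", "ablate",
                                       "audit"),
                           arch = irgam_tiny_config(),
                           train_cfg = train_config(epochs = 3L),
                           out_dir = tempfile("run_"),
                           n_per_level = rep(10L, 6L), organ = "ear",
                           checkpoint = NULL, image_paths = NULL,
                           seed = 1L, verbose = FALSE) {
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(list(arch = unclass(arch), train = unclass(train_cfg),
                           command = command, seed = seed))
  tag <- function(stem, ext) file.path(out_dir,
                                       sprintf("%s_%s.%s", stem, hash, ext))
  art <- list(out_dir = out_dir, hash = hash)

  if (command == "synthesize") {
    ds <- generate_dataset(n_per_level, organ, base_seed = seed,
                           image_size = arch$input_size)
    art$manifest <- write_dataset(ds, out_dir)
    return(invisible(art))
  }

  if (command == "audit") {
    model <- build_model(arch, seed = seed)
    art$model_audit <- tag("audit_model", "csv")
    art$vgg_audit <- tag("audit_vgg11_bn", "csv")
    write_audit(count_parameters(model), art$model_audit)
    write_audit(audit_vgg11_bn(arch$n_classes), art$vgg_audit)
    return(invisible(art))
  }

  make_data <- function() {
    ds <- generate_dataset(n_per_level, organ, base_seed = seed,
                           image_size = arch$input_size)
    plan <- make_splits(ds$manifest, "holdout_90_10", seed = seed)
    list(ds = ds, plan = plan,
         train = ds$samples[match(plan$train, ds$manifest$id)],
         test = ds$samples[match(plan$test, ds$manifest$id)])
  }

  eval_model <- function(model, test, stem) {
    truth <- vapply(test, `[[`, integer(1), "level")
    xb <- array(0, c(3L, arch$input_size, arch$input_size, length(test)))
    for (j in seq_along(test)) xb[, , , j] <- test[[j]]$image * 2 - 1
    pred <- as.integer(attr(predict_proba(model, xb), "level"))
    cm <- build_confusion_matrix(truth, pred)
    rep <- compute_metrics(cm)
    rep$fuzzy_accuracy <- fuzzy_accuracy(truth, pred)
    write_metrics(rep, tag(paste0(stem, "_metrics"), "json"))
    utils::write.csv(cm, tag(paste0(stem, "_confusion"), "csv"))
    confusion_heatmap_png(cm, tag(paste0(stem, "_confusion"), "png"))
    rep
  }

  if (command == "train") {
    d <- make_data()
    model <- build_model(arch, init = train_cfg$init, seed = seed)
    log_line("training on ", length(d$train), " samples", verbose = verbose)
    fit <- train(model, d$train, train_cfg, verbose = verbose)
    art$checkpoint <- tag("checkpoint", "rds")
    save_model(fit$model, art$checkpoint)
    art$history <- tag("loss_history", "csv")
    utils::write.csv(fit$history, art$history, row.names = FALSE)
    return(invisible(art))
  }

  if (command == "eval") {
    if (is.null(checkpoint)) stop("usage error: eval requires a checkpoint")
    model <- load_model(checkpoint)
    d <- make_data()
    art$report <- eval_model(model, d$test, "eval")
    return(invisible(art))
  }

  if (command == "ablate") {
    d <- make_data()
    art$reports <- list()
    for (v in ablation_variants) {
      model <- build_ablation_variant(arch, v, seed = seed)
      art$reports[[v]] <- eval_model(model, d$test, paste0("ablate_", v))
    }
    return(invisible(art))
  }

  if (command == "predict") {
    if (is.null(checkpoint)) stop("usage error: predict requires a checkpoint")
    tab <- predict_images(checkpoint, image_paths)
    art$table <- tag("predictions", "csv")
    utils::write.csv(tab, art$table, row.names = FALSE)
    art$n_failed <- sum(!is.na(tab$error))
    return(invisible(art))
  }

  if (command == "gradcam") {
    if (is.null(checkpoint)) stop("usage error: gradcam requires a checkpoint")
    model <- load_model(checkpoint)
    d <- make_data()
    rows <- list()
    for (i in seq_along(d$test)) {
      smp <- d$test[[i]]
      cam <- grad_cam(model, smp$image, smp$level)
      p <- tag(paste0("cam_", smp$id), "png")
      cam_overlay_png(smp$image, cam, p)
      rows[[i]] <- data.frame(id = smp$id, level = smp$level,
                              localization = localization_score(cam, smp$mask),
                              area_fraction = mean(smp$mask), path = p)
    }
    art$localization <- tag("localization", "csv")
    utils::write.csv(do.call(rbind, rows), art$localization, row.names = FALSE)
    return(invisible(art))
  }
}
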