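## Float32 parameter accounting.
##
## Model "size" is trainable parameters x 4 bytes (single precision),
## reported in MiB (bytes / 1024^2) and rounded to 2 decimals.  Batch-norm
## scale/shift pairs count; running statistics do not (they are not
## trained).

new_param_audit <- function(per_layer) {
  total <- sum(per_layer$params)
  bytes <- 4 * total
  structure(list(per_layer = per_layer, total_params = total,
                 bytes = bytes, size_mib = round(bytes / 1024^2, 2)),
            class = "param_audit")
}

#' Audit the trainable parameters of a model
#'
#' Counts convolution and dense weights and biases plus batch-norm affine
#' pairs, layer by layer, and converts to float32 storage size.
#'
#' @param model an `irgam_model`.
#' @return A `param_audit`: per-layer table, `total_params`, `bytes`
#'   (= 4 x total), and `size_mib` (bytes / 1024^2, 2 decimals).
#' @export
count_parameters <- function(model) {
  layers <- model_layer_list(model)
  counts <- vapply(layers, function(l) {
    sum(vapply(ly_param_names(l), function(f) length(l[[f]]), numeric(1)))
  }, numeric(1))
  new_param_audit(data.frame(name = names(layers), params = as.numeric(counts),
                             row.names = NULL))
}

#' @export
print.param_audit <- function(x, ...) {
  cat("Parameter audit:", format(x$total_params, big.mark = ","),
      "trainable parameters\n")
  cat("float32 size:", x$size_mib, "MB (", x$bytes, "bytes )\n")
  invisible(x)
}

#' Write a parameter audit to CSV or JSON
#'
#' @param audit a `param_audit`.
#' @param path destination; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_layer = audit$per_layer,
                              total_params = audit$total_params,
                              bytes = audit$bytes,
                              size_mib = audit$size_mib),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(audit$per_layer, path, row.names = FALSE)
  }
  invisible(path)
}

#' Analytic parameter audit of the VGG-11 (batch-norm) reference
#'
#' The classical comparison network: eight `3x3` convolutions (widths 64,
#' 128, 256, 256, 512, 512, 512, 512), each with bias and a batch-norm
#' affine pair, and a three-layer classifier (`512*7*7 -> 4096 -> 4096 ->
#' n_classes`).  Counted layer by layer from the layer algebra alone; with
#' a 6-class head this totals 128,796,422 parameters, i.e. 491.32 MB at 4
#' bytes per parameter.
#'
#' @param n_classes classifier output width (6 for the grading task).
#' @return A `param_audit`.
#' @export
audit_vgg11_bn <- function(n_classes = 6L) {
  widths <- c(64L, 128L, 256L, 256L, 512L, 512L, 512L, 512L)
  in_c <- 3L
  rows <- list()
  for (i in seq_along(widths)) {
    out_c <- widths[i]
    rows[[length(rows) + 1L]] <-
      data.frame(name = sprintf("features.conv%d", i),
                 params = as.numeric(in_c * out_c * 9 + out_c + 2 * out_c))
    in_c <- out_c
  }
  fc <- list(c(512L * 7L * 7L, 4096L), c(4096L, 4096L),
             c(4096L, as.integer(n_classes)))
  for (i in seq_along(fc)) {
    rows[[length(rows) + 1L]] <-
      data.frame(name = sprintf("classifier.fc%d", i),
                 params = as.numeric(fc[[i]][1L] * fc[[i]][2L] + fc[[i]][2L]))
  }
  new_param_audit(do.call(rbind, rows))
}
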