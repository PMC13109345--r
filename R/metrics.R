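## Confusion matrix and classification metrics for 6-level grading.

#' Build a 6x6 confusion matrix
#'
#' Rows are true levels, columns predicted levels (0-5).
#'
#' @param true,pred integer grade vectors of equal length with values in
#'   0..5.
#' @param n_levels number of levels (6).
#' @return Integer matrix of counts with dimnames `0..5`.
#' @export
build_confusion_matrix <- function(true, pred, n_levels = 6L) {
  if (length(true) != length(pred)) {
    stop("usage error: true and pred lengths differ")
  }
  if (length(true) && (any(true < 0L | true >= n_levels) ||
                       any(pred < 0L | pred >= n_levels))) {
    stop("usage error: labels must lie in 0..", n_levels - 1L)
  }
  cm <- matrix(0L, n_levels, n_levels,
               dimnames = list(true = 0:(n_levels - 1L),
                               pred = 0:(n_levels - 1L)))
  for (i in seq_along(true)) {
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  }
  cm
}

#' Accuracy, per-class precision/recall/F1 and macro averages
#'
#' One-vs-rest per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`; accuracy is the trace over the total.  Macro values
#' are unweighted class means; `average = "weighted"` weights by class
#' support instead.  A class with a zero denominator contributes 0 (with a
#' warning) rather than propagating NaN.
#'
#' @param cm confusion matrix from [build_confusion_matrix()].
#' @param average `"macro"` or `"weighted"`.
#' @return A `metrics_report` list: `accuracy`, `per_class` data frame,
#'   `precision`, `recall`, `f1` (averaged).
#' @export
compute_metrics <- function(cm, average = c("macro", "weighted")) {
  average <- match.arg(average)
  total <- sum(cm)
  if (total == 0) stop("usage error: empty confusion matrix")
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning("zero denominator for ", what, " in class(es) ",
              paste(which(den == 0) - 1L, collapse = ", "),
              "; reporting 0", call. = FALSE)
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  wts <- if (average == "macro") rep(1 / k, k) else rowSums(cm) / total
  structure(list(
    accuracy = sum(tp) / total,
    per_class = data.frame(level = 0:(k - 1L), support = rowSums(cm),
                           precision = precision, recall = recall, f1 = f1,
                           row.names = NULL),
    precision = sum(wts * precision),
    recall = sum(wts * recall),
    f1 = sum(wts * f1),
    average = average
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | %s precision %.4f recall %.4f F1 %.4f\n",
              x$accuracy, x$average, x$precision, x$recall, x$f1))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Fuzzy adjacent-level grading accuracy
#'
#' Nonzero grades may be confused with an adjacent nonzero grade
#' (|pred - true| <= 1 with both >= 1) without counting as an error, since
#' neighbouring fertility levels are morphologically similar and their
#' boundary is partly subjective.  Level 0 (no seed set / no anther
#' emergence) is a categorically distinct phenotype: any confusion between
#' level 0 and a nonzero level remains an error.
#'
#' @param true,pred integer grade vectors in 0..5.
#' @return Fraction of fuzzy-correct predictions; always >= the strict
#'   accuracy.
#' @export
fuzzy_accuracy <- function(true, pred) {
  if (length(true) != length(pred)) {
    stop("usage error: true and pred lengths differ")
  }
  if (any(true < 0L | true > 5L | pred < 0L | pred > 5L)) {
    stop("usage error: labels must lie in 0..5")
  }
  ok <- pred == true | (abs(pred - true) <= 1L & pred >= 1L & true >= 1L)
  mean(ok)
}

#' Write a metrics report to JSON or CSV
#'
#' @param report a `metrics_report`.
#' @param path destination (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report$per_class, path, row.names = FALSE)
  }
  invisible(path)
}

#' Render a confusion matrix as a heat-map PNG
#'
#' Cell colour scales with count (light to dark); written without a
#' graphics device so it works headless.
#'
#' @param cm confusion matrix.
#' @param path output PNG path.
#' @param cell pixel size per cell.
#' @return `path`, invisibly.
#' @export
confusion_heatmap_png <- function(cm, path, cell = 32L) {
  k <- nrow(cm)
  v <- cm / max(cm, 1)
  img <- array(0, c(k * cell, k * cell, 3))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      # white -> blue ramp
      f <- v[i, j]
      col <- c(1 - 0.8 * f, 1 - 0.55 * f, 1 - 0.1 * f)
      rows <- (i - 1L) * cell + seq_len(cell)
      cols <- (j - 1L) * cell + seq_len(cell)
      for (ch in 1:3) img[rows, cols, ch] <- col[ch]
    }
  }
  EBImage::writeImage(EBImage::Image(img, colormode = "Color"), path)
  invisible(path)
}
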