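## Deterministic synthetic generator of graded ear / tassel scenes.
##
## The generator emulates the structure of single-organ photographs on a
## dark background: an ear is a central cob ellipse carrying bright kernel
## disks, a tassel is a stalk with branches carrying bright anther dots.
## The grading trait is the coverage fraction — kernel pixels over the cob
## region, or anther pixels over the branch envelope — and the emitted
## label is the band that the realized (pixel-counted) coverage falls in,
## so labels are correct by construction.

#' Coverage bands defining the six grade levels
#'
#' Level 0 is pinned to exactly zero coverage (complete absence of seed or
#' anthers, a categorically distinct phenotype); levels 1-5 partition
#' (0, 1] into half-open intervals `(b[i], b[i+1]]`.
#'
#' @param breaks increasing numeric vector of 6 break points starting at 0
#'   and ending at 1.
#' @return A `level_bands` object.
#' @export
level_bands <- function(breaks = c(0, 0.1, 0.3, 0.5, 0.7, 1)) {
  stopifnot(length(breaks) == 6L, breaks[1L] == 0, breaks[6L] == 1,
            all(diff(breaks) > 0))
  structure(list(breaks = breaks), class = "level_bands")
}

#' Grade level of a coverage fraction
#'
#' @param coverage coverage fraction(s) in `[0, 1]`.
#' @param bands a [level_bands()].
#' @return Integer level(s) 0-5; level 0 iff coverage is exactly 0.
#' @export
assign_level <- function(coverage, bands = level_bands()) {
  if (any(coverage < 0 | coverage > 1)) {
    stop("usage error: coverage must lie in [0, 1]")
  }
  vapply(coverage, function(cv) {
    if (cv == 0) 0L else sum(cv > bands$breaks[1:5])
  }, integer(1))
}

# Midpoint target coverage for a level (0 for level 0).
band_target <- function(level, bands) {
  if (level == 0L) return(0)
  lo <- bands$breaks[level]
  hi <- bands$breaks[level + 1L]
  (lo + hi) / 2
}

#' Scene specification for one synthetic organ image
#'
#' @param organ `"ear"` or `"tassel"`.
#' @param level target grade level 0-5.
#' @param image_size square output size in pixels.
#' @param background_gray mean background intensity.
#' @param density target coverage fraction; defaults to the midpoint of the
#'   level's band.
#' @param noise_sigma sd of additive Gaussian pixel noise.
#' @param bands the [level_bands()] in force.
#' @param seed RNG seed fixing the scene bit-exactly.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(organ = c("ear", "tassel"), level, image_size = 139L,
                       background_gray = 0.08, density = NULL,
                       noise_sigma = 0.02, bands = level_bands(), seed = 1L) {
  organ <- match.arg(organ)
  level <- as.integer(level)
  stopifnot(level >= 0L, level <= 5L)
  if (is.null(density)) density <- band_target(level, bands)
  if (level == 0L) {
    if (density != 0) stop("usage error: level 0 requires zero density")
  } else if (density <= bands$breaks[level] || density > bands$breaks[level + 1L]) {
    stop("usage error: density ", density, " outside the level-", level,
         " band")
  }
  structure(list(organ = organ, level = level,
                 image_size = as.integer(image_size),
                 background_gray = background_gray, density = density,
                 noise_sigma = noise_sigma, bands = bands,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

## ---- drawing primitives -----------------------------------------------------

ellipse_mask <- function(S, cy, cx, ry, rx) {
  y <- matrix(seq_len(S), S, S)
  x <- t(y)
  ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

# Paint a filled disk onto channel arrays within bounds; returns the pixel
# mask painted.
disk_pixels <- function(S, cy, cx, r) {
  ys <- max(1L, floor(cy - r)):min(S, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(S, ceiling(cx + r))
  px <- expand.grid(y = ys, x = xs)
  keep <- (px$y - cy)^2 + (px$x - cx)^2 <= r^2
  px[keep, , drop = FALSE]
}

line_pixels <- function(S, y0, x0, y1, x1) {
  n <- max(2L, ceiling(2 * sqrt((y1 - y0)^2 + (x1 - x0)^2)))
  t <- seq(0, 1, length.out = n)
  y <- pmin(pmax(round(y0 + t * (y1 - y0)), 1L), S)
  x <- pmin(pmax(round(x0 + t * (x1 - x0)), 1L), S)
  unique(data.frame(y = y, x = x))
}

# img: 3 x S x S array; paints pixels (px$y, px$x) via linear indexing.
img_set <- function(img, px, col) {
  S <- dim(img)[2L]
  base <- 3L * (px$y - 1L) + 3L * S * (px$x - 1L)
  for (ch in 1:3) img[ch + base] <- col[ch]
  img
}

## ---- generators -------------------------------------------------------------

finish_scene <- function(img, mask, organ_px, spec) {
  S <- spec$image_size
  cover_px <- sum(organ_px & mask)
  coverage <- cover_px / sum(mask)
  level <- assign_level(coverage, spec$bands)
  if (level != spec$level) {
    stop("generation error: realized coverage ", round(coverage, 4),
         " fell outside the level-", spec$level, " band")
  }
  if (spec$noise_sigma > 0) {
    img <- img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, level = level, coverage = coverage,
       organ = spec$organ, spec = spec)
}

#' Generate a synthetic ear scene
#'
#' Dark background, a central cob ellipse, and bright kernel disks placed
#' on a jittered overlapping grid inside the cob until the target coverage
#' is reached.  The object mask marks the cob region; the emitted label is
#' recomputed from the realized pixel coverage.
#'
#' @param spec a [scene_spec()] with `organ = "ear"`.
#' @return An `image_sample` list: `image` (`3 x S x S` in `[0,1]`), `mask`
#'   (`S x S` logical), `level`, `coverage`, `organ`, `spec`.
#' @export
generate_ear_image <- function(spec) {
  stopifnot(spec$organ == "ear")
  set.seed(spec$seed)
  S <- spec$image_size
  img <- array(spec$background_gray * c(1.1, 1.0, 0.9), c(3L, S, S))
  cy <- S / 2 + runif(1, -0.02, 0.02) * S
  cx <- S / 2 + runif(1, -0.02, 0.02) * S
  ry <- 0.40 * S * runif(1, 0.92, 1.0)
  rx <- 0.15 * S * runif(1, 0.9, 1.1)
  mask <- ellipse_mask(S, cy, cx, ry, rx)
  cob_col <- c(0.42, 0.28, 0.20)
  px <- which(mask, arr.ind = TRUE)
  img <- img_set(img, data.frame(y = px[, 1L], x = px[, 2L]), cob_col)

  kernel_px <- matrix(FALSE, S, S)
  if (spec$level > 0L) {
    r <- max(1L, round(S / 45))
    step <- max(1L, round(1.1 * r))
    centers <- expand.grid(y = seq(ceiling(cy - ry), floor(cy + ry), by = step),
                           x = seq(ceiling(cx - rx), floor(cx + rx), by = step))
    inside <- ((centers$y - cy) / (ry - 1))^2 +
      ((centers$x - cx) / (rx - 1))^2 <= 1
    centers <- centers[inside, , drop = FALSE]
    centers <- centers[sample.int(nrow(centers)), , drop = FALSE]
    cob_area <- sum(mask)
    target <- spec$density
    kcol_base <- c(0.85, 0.72, 0.35)
    for (i in seq_len(nrow(centers))) {
      jit <- runif(2, -0.4, 0.4) * r
      d <- disk_pixels(S, centers$y[i] + jit[1L], centers$x[i] + jit[2L], r)
      kernel_px[cbind(d$y, d$x)] <- TRUE
      img <- img_set(img, d, pmin(pmax(kcol_base + rnorm(3, 0, 0.03), 0), 1))
      if (sum(kernel_px & mask) / cob_area >= target) break
    }
    if (sum(kernel_px & mask) / cob_area < spec$bands$breaks[spec$level] ||
        all(!kernel_px)) {
      stop("generation error: infeasible density ", target,
           " for the ear geometry")
    }
  }
  finish_scene(img, mask, kernel_px, spec)
}

#' Generate a synthetic tassel scene
#'
#' A stalk with lateral branch polylines; the object mask is the dilated
#' branch envelope and anther dots are placed along the branches until the
#' target coverage of the envelope is reached.
#'
#' @param spec a [scene_spec()] with `organ = "tassel"`.
#' @return An `image_sample` list as in [generate_ear_image()].
#' @export
generate_tassel_image <- function(spec) {
  stopifnot(spec$organ == "tassel")
  set.seed(spec$seed)
  S <- spec$image_size
  img <- array(spec$background_gray * c(0.9, 1.0, 0.9), c(3L, S, S))
  branch_col <- c(0.25, 0.32, 0.18)

  skel <- matrix(FALSE, S, S)
  stalk <- line_pixels(S, 0.95 * S, S / 2, 0.20 * S, S / 2 + runif(1, -2, 2))
  skel[cbind(stalk$y, stalk$x)] <- TRUE
  n_branch <- sample(6:9, 1L)
  branch_pts <- list()
  for (b in seq_len(n_branch)) {
    oy <- runif(1, 0.22, 0.55) * S
    ox <- S / 2
    ang <- runif(1, 15, 75) * pi / 180 * sample(c(-1, 1), 1L)
    len <- runif(1, 0.22, 0.38) * S
    seg <- line_pixels(S, oy, ox, oy + len * cos(ang) * 0.9,
                       ox + len * sin(ang))
    skel[cbind(seg$y, seg$x)] <- TRUE
    branch_pts[[b]] <- seg
  }
  mask <- as.array(EBImage::dilate(EBImage::Image(skel * 1),
                                   EBImage::makeBrush(3L, "box"))) > 0
  px <- which(mask, arr.ind = TRUE)
  img <- img_set(img, data.frame(y = px[, 1L], x = px[, 2L]), branch_col)

  anther_px <- matrix(FALSE, S, S)
  if (spec$level > 0L) {
    pts <- do.call(rbind, branch_pts)
    pts <- pts[sample.int(nrow(pts)), , drop = FALSE]
    pts <- pts[rep(seq_len(nrow(pts)), 4L), , drop = FALSE]  # allow revisits
    r <- max(1L, round(S / 70))
    env_area <- sum(mask)
    target <- spec$density
    acol <- c(0.90, 0.85, 0.45)
    for (i in seq_len(nrow(pts))) {
      jit <- runif(2, -1, 1)
      d <- disk_pixels(S, pts$y[i] + jit[1L], pts$x[i] + jit[2L], r)
      anther_px[cbind(d$y, d$x)] <- TRUE
      img <- img_set(img, d, pmin(pmax(acol + rnorm(3, 0, 0.03), 0), 1))
      if (sum(anther_px & mask) / env_area >= target) break
    }
    if (sum(anther_px & mask) / env_area < spec$bands$breaks[spec$level]) {
      stop("generation error: infeasible density ", target,
           " for the tassel geometry")
    }
  }
  finish_scene(img, mask, anther_px, spec)
}

#' Generate a labelled synthetic dataset
#'
#' Per-level sample counts are honoured exactly.  One global seed streams
#' per-sample seeds through a counter scheme, so the dataset is
#' reproducible as a whole while samples stay independent.
#'
#' @param n_per_level integer vector of length 6: samples per level 0-5.
#' @param organ `"ear"` or `"tassel"`.
#' @param base_seed global seed.
#' @param image_size square image size.
#' @param bands [level_bands()].
#' @param noise_sigma additive pixel noise sd.
#' @return List with `samples` (list of `image_sample`) and `manifest`
#'   (data frame: id, organ, level, coverage, seed).
#' @export
generate_dataset <- function(n_per_level, organ = "ear", base_seed = 1L,
                             image_size = 139L, bands = level_bands(),
                             noise_sigma = 0.02) {
  if (length(n_per_level) != 6L) {
    stop("usage error: n_per_level must have length 6")
  }
  if (any(n_per_level < 0)) stop("usage error: negative per-level counts")
  gen <- if (organ == "ear") generate_ear_image else generate_tassel_image
  samples <- list()
  rows <- list()
  counter <- 0L
  for (level in 0:5) {
    for (i in seq_len(n_per_level[level + 1L])) {
      counter <- counter + 1L
      seed_i <- as.integer((as.numeric(base_seed) * 1000003 + counter) %%
                             2147483647)
      sp <- scene_spec(organ, level, image_size = image_size, bands = bands,
                       noise_sigma = noise_sigma, seed = seed_i)
      smp <- gen(sp)
      smp$id <- sprintf("%s_%03d_L%d", organ, counter, level)
      samples[[counter]] <- smp
      rows[[counter]] <- data.frame(id = smp$id, organ = organ,
                                    level = smp$level,
                                    coverage = smp$coverage, seed = seed_i)
    }
  }
  list(samples = samples, manifest = do.call(rbind, rows))
}

#' Write a dataset to disk as PNG images plus a CSV manifest
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if needed); images under
#'   `images/`, single-channel masks under `masks/`.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ds$samples))
  for (i in seq_along(ds$samples)) {
    smp <- ds$samples[[i]]
    p <- file.path(dir, "images", paste0(smp$id, ".png"))
    EBImage::writeImage(EBImage::Image(aperm(smp$image, c(2L, 3L, 1L)),
                                       colormode = "Color"), p)
    EBImage::writeImage(EBImage::Image(smp$mask * 1),
                        file.path(dir, "masks", paste0(smp$id, ".png")))
    paths[i] <- p
  }
  manifest <- cbind(ds$manifest, path = paths)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

## ---- splits -----------------------------------------------------------------

#' Stratified dataset splits
#'
#' All schemes stratify by grade level: `holdout_90_10` (train/test),
#' `train_val_test_80_10_10`, `kfold_10` (ten disjoint folds covering every
#' sample), and `balanced`, which first downsamples levels listed in `caps`
#' to the cap size and then applies the 90/10 holdout.
#'
#' @param manifest data frame with columns `id` and `level`.
#' @param scheme split scheme name.
#' @param seed RNG seed.
#' @param caps named integer vector (names = levels as characters) of
#'   per-level downsampling caps; only with `scheme = "balanced"`.
#' @return A `split_plan` list with `scheme` and id vectors `train`/`test`
#'   (plus `val` or `folds` where applicable).
#' @export
make_splits <- function(manifest,
                        scheme = c("holdout_90_10", "train_val_test_80_10_10",
                                   "kfold_10", "balanced"),
                        seed = 1L, caps = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(caps) && scheme != "balanced") {
    stop("usage error: caps only apply to the balanced scheme")
  }
  set.seed(seed)
  ids <- as.character(manifest$id)
  lev <- manifest$level

  if (scheme == "balanced") {
    if (is.null(caps)) stop("usage error: balanced scheme requires caps")
    keep <- unlist(lapply(split(seq_along(ids), lev), function(ix) {
      l <- as.character(lev[ix[1L]])
      if (!is.null(caps[l]) && !is.na(caps[l])) {
        if (caps[l] > length(ix)) {
          stop("usage error: cap ", caps[l], " exceeds class size ",
               length(ix), " for level ", l)
        }
        sample(ix, caps[l])
      } else ix
    }), use.names = FALSE)
    sub <- manifest[sort(keep), , drop = FALSE]
    plan <- make_splits(sub, "holdout_90_10", seed = seed + 1L)
    plan$scheme <- "balanced"
    plan$kept <- as.character(sub$id)
    return(plan)
  }

  by_level <- split(seq_along(ids), lev)
  plan <- list(scheme = scheme)
  if (scheme == "kfold_10") {
    folds <- vector("list", 10L)
    for (ix in by_level) {
      ix <- sample(ix)
      fl <- rep_len(1:10, length(ix))
      for (f in 1:10) folds[[f]] <- c(folds[[f]], ix[fl == f])
    }
    plan$folds <- lapply(folds, function(ix) ids[sort(ix)])
  } else {
    test <- c(); val <- c()
    for (ix in by_level) {
      ix <- sample(ix)
      n <- length(ix)
      n_test <- round(0.1 * n)
      test <- c(test, ix[seq_len(n_test)])
      if (scheme == "train_val_test_80_10_10") {
        val <- c(val, ix[n_test + seq_len(round(0.1 * n))])
      }
    }
    rest <- setdiff(seq_along(ids), c(test, val))
    plan$train <- ids[sort(rest)]
    if (scheme == "train_val_test_80_10_10") plan$val <- ids[sort(val)]
    plan$test <- ids[sort(test)]
  }
  class(plan) <- "split_plan"
  plan
}

#' Write a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = FALSE)
  invisible(path)
}
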