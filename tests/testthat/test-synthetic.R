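test_that("coverage bands assign levels as documented", {
  b <- level_bands()
  expect_equal(assign_level(0, b), 0L)
  expect_equal(assign_level(1, b), 5L)
  expect_equal(assign_level(0.35, b), 3L)
  expect_equal(assign_level(c(0.05, 0.1, 0.100001, 0.7, 0.70001), b),
               c(1L, 1L, 2L, 4L, 5L))
  expect_error(assign_level(1.2, b), "usage error")
  expect_error(assign_level(-0.1, b), "usage error")
  expect_error(level_bands(c(0, 0.5, 0.4, 0.6, 0.8, 1)))
})

test_that("ear scenes honour their band, mask and determinism contracts", {
  s0 <- generate_ear_image(scene_spec("ear", 0L, image_size = 75L, seed = 4))
  expect_equal(s0$level, 0L)
  expect_equal(s0$coverage, 0)
  expect_gt(sum(s0$mask), 0)

  s5 <- generate_ear_image(scene_spec("ear", 5L, image_size = 75L, seed = 4))
  expect_equal(s5$level, 5L)
  expect_true(s5$coverage > 0.7 && s5$coverage <= 1)

  for (lv in c(1L, 3L)) {
    s <- generate_ear_image(scene_spec("ear", lv, image_size = 75L,
                                       seed = 10 + lv))
    expect_equal(assign_level(s$coverage, s$spec$bands), s$level)
    expect_equal(s$level, lv)
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_equal(dim(s$image), c(3L, 75L, 75L))
  }

  a <- generate_ear_image(scene_spec("ear", 3L, image_size = 75L, seed = 7))
  b <- generate_ear_image(scene_spec("ear", 3L, image_size = 75L, seed = 7))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})

test_that("tassel scenes place anthers along the branch envelope", {
  s0 <- generate_tassel_image(scene_spec("tassel", 0L, image_size = 75L,
                                         seed = 2))
  expect_equal(s0$level, 0L)
  expect_equal(s0$coverage, 0)

  cov <- vapply(1:5, function(lv) {
    generate_tassel_image(scene_spec("tassel", lv, image_size = 75L,
                                     seed = 33))$coverage
  }, numeric(1))
  expect_true(all(diff(cov) > 0))  # coverage grows with level, fixed geometry

  s <- generate_tassel_image(scene_spec("tassel", 4L, image_size = 75L,
                                        seed = 5))
  expect_equal(assign_level(s$coverage, s$spec$bands), 4L)
  expect_identical(s$image,
                   generate_tassel_image(scene_spec("tassel", 4L,
                                                    image_size = 75L,
                                                    seed = 5))$image)
})

test_that("datasets honour per-level counts with a reproducible manifest", {
  ds <- generate_dataset(c(3L, 3L, 3L, 3L, 3L, 3L), "ear", base_seed = 17,
                         image_size = 75L)
  expect_length(ds$samples, 18L)
  expect_equal(as.integer(table(ds$manifest$level)), rep(3L, 6))
  ds2 <- generate_dataset(rep(3L, 6L), "ear", base_seed = 17,
                          image_size = 75L)
  expect_identical(ds$manifest, ds2$manifest)

  imb <- generate_dataset(c(6L, 6L, 1L, 1L, 1L, 1L), "tassel", base_seed = 3,
                          image_size = 75L)
  expect_equal(as.integer(table(factor(imb$manifest$level, levels = 0:5))),
               c(6L, 6L, 1L, 1L, 1L, 1L))
  expect_error(generate_dataset(c(-1L, rep(1L, 5)), "ear"), "usage error")
  expect_error(generate_dataset(rep(1L, 5), "ear"), "usage error")
})

test_that("splits stratify, partition and cap as documented", {
  manifest <- data.frame(id = sprintf("s%03d", 1:120),
                         level = rep(0:5, each = 20))
  h <- make_splits(manifest, "holdout_90_10", seed = 1)
  expect_length(h$test, 12L)
  expect_length(h$train, 108L)
  expect_length(intersect(h$train, h$test), 0L)
  # stratification within one sample per level
  lev <- manifest$level[match(h$test, manifest$id)]
  expect_true(all(abs(table(factor(lev, levels = 0:5)) - 2) <= 1))

  t3 <- make_splits(manifest, "train_val_test_80_10_10", seed = 2)
  expect_length(t3$val, 12L)
  expect_length(t3$test, 12L)
  expect_length(t3$train, 96L)
  expect_equal(sort(c(t3$train, t3$val, t3$test)), sort(manifest$id))

  kf <- make_splits(manifest, "kfold_10", seed = 3)
  expect_length(kf$folds, 10L)
  all_ids <- unlist(kf$folds)
  expect_equal(sort(all_ids), sort(manifest$id))   # disjoint cover
  expect_equal(anyDuplicated(all_ids), 0L)

  bal <- make_splits(manifest, "balanced", seed = 4, caps = c("0" = 10L))
  expect_length(bal$kept, 110L)
  expect_equal(sum(manifest$level[match(bal$kept, manifest$id)] == 0), 10L)
  expect_error(make_splits(manifest, "balanced", seed = 4,
                           caps = c("0" = 25L)), "usage error")
  expect_error(make_splits(manifest, "holdout_90_10", caps = c("0" = 5L)),
               "usage error")

  p <- tempfile(fileext = ".json")
  write_split_plan(h, p)
  expect_true(file.exists(p))
  unlink(p)
})

test_that("dataset export writes images, masks and manifest", {
  ds <- generate_dataset(rep(1L, 6L), "ear", base_seed = 9, image_size = 64L)
  dir <- tempfile("ds_")
  mp <- write_dataset(ds, dir)
  man <- utils::read.csv(mp)
  expect_equal(nrow(man), 6L)
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(file.path(dir, "masks",
                                        paste0(man$id, ".png")))))
  # PNG round trip preserves the scene up to 8-bit quantisation
  x <- preprocess_image(man$path[6L], size = 64L, normalize = FALSE)
  expect_equal(x, ds$samples[[6L]]$image, tolerance = 0.01)
  unlink(dir, recursive = TRUE)
})
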