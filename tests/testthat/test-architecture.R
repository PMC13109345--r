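fw <- maizegrader:::ly_forward

test_that("stem maps 3x299x299 to 256x35x35 through the documented trace", {
  set.seed(1)
  st <- stem_module()
  x <- array(rnorm(3 * 299 * 299, 0, 0.1), c(3L, 299L, 299L))
  # stage-by-stage spatial trace 299 -> 149 -> 147 -> 147 -> 73 -> 71 -> 35
  ch <- st$children
  y <- fw(ch$conv1, x);  expect_equal(dim(y)[2:3], c(149L, 149L))
  y <- fw(ch$conv2, y);  expect_equal(dim(y)[2:3], c(147L, 147L))
  y <- fw(ch$conv3, y);  expect_equal(dim(y)[2:3], c(147L, 147L))
  y <- fw(ch$pool, y);   expect_equal(dim(y)[2:3], c(73L, 73L))
  y <- fw(ch$erf$children$conv2, fw(ch$erf$children$conv1, y))
  expect_equal(dim(y)[2:3], c(71L, 71L))
  y <- fw(ch$erf$children$conv3, y)
  expect_equal(dim(y)[1:3], c(256L, 35L, 35L))
  # assembled
  out <- stem_forward(stem_module(), x)
  expect_equal(dim(out)[1:3], c(256L, 35L, 35L))
  expect_error(model_forward(build_model(irgam_tiny_config()),
                             array(0, c(3L, 100L, 100L))), "139")
})

test_that("stem of all-zero input with zero-initialised weights is zero", {
  st <- stem_module(3L, c(4L, 4L, 4L), c(4L, 4L, 8L))
  for (l in maizegrader:::module_layers(st)) maizegrader:::zero_layer(l)
  y <- stem_forward(st, array(0, c(3L, 75L, 75L)))
  expect_true(all(y == 0))
})

test_that("ERF is stride/padding polymorphic", {
  set.seed(2)
  # residual-block context preserves spatial dims
  e1 <- erf_module(8L, c(8L, 8L, 8L))
  x <- array(rnorm(8 * 12 * 12), c(8L, 12L, 12L))
  expect_equal(dim(erf_forward(e1, x))[1:3], c(8L, 12L, 12L))
  # stem context: 73 -> 71 -> 35
  e2 <- erf_module(4L, c(4L, 4L, 8L), strides = c(1L, 1L, 2L),
                   paddings = c("valid", "valid", "valid"))
  y <- erf_forward(e2, array(rnorm(4 * 73 * 73), c(4L, 73L, 73L)))
  expect_equal(dim(y)[1:3], c(8L, 35L, 35L))
  # zeroed weights annihilate any input
  for (l in maizegrader:::module_layers(e1)) maizegrader:::zero_layer(l)
  expect_true(all(erf_forward(e1, x) == 0))
})

test_that("residual blocks preserve shape and reduce to identity when fused to zero", {
  set.seed(3)
  xa <- array(rnorm(256 * 35 * 35, 0, 0.5), c(256L, 35L, 35L))
  ba <- inception_resnet_a()
  expect_equal(dim(fw(ba, xa)), c(256L, 35L, 35L, 1L))

  # residual identity at machine precision on non-negative input
  ba2 <- inception_resnet_a(16L, 8L, c(8L, 8L), c(8L, 8L, 8L))
  maizegrader:::zero_layer(ba2$children$fuse)
  xs <- array(abs(rnorm(16 * 9 * 9)), c(16L, 9L, 9L))
  expect_equal(fw(ba2, xs)[, , , 1L], xs, tolerance = 1e-15)

  bb <- inception_resnet_b(24L, 8L, c(8L, 8L, 8L))
  xb <- array(abs(rnorm(24 * 9 * 9)), c(24L, 9L, 9L))
  expect_equal(dim(fw(bb, xb)), c(24L, 9L, 9L, 1L))
  maizegrader:::zero_layer(bb$children$fuse)
  expect_equal(fw(bb, xb)[, , , 1L], xb, tolerance = 1e-15)
})

test_that("A-block branch widths (32, 32, 32) concatenate to 96 channels", {
  ba <- inception_resnet_a(256L, 32L, c(32L, 32L), c(32L, 48L, 32L))
  expect_equal(sum(ba$branch_sizes), 96L)
  expect_equal(ba$children$fuse$in_c, 96L)
})

test_that("asymmetric 1x7 / 7x1 convolutions preserve 17x17 under same padding", {
  l17 <- conv_layer(4L, 4L, 1L, 7L, padding = "same")
  l71 <- conv_layer(4L, 4L, 7L, 1L, padding = "same")
  x <- array(rnorm(4 * 17 * 17), c(4L, 17L, 17L))
  expect_equal(dim(fw(l71, fw(l17, x)))[2:3], c(17L, 17L))
})

test_that("reduction stages emit the documented shapes and channel accounting", {
  set.seed(4)
  ra <- reduction_a()
  expect_equal(ra$branch_sizes, c(384L, 256L, 256L))
  expect_equal(ra$out_c, 896L)
  y <- fw(ra, array(rnorm(256 * 35 * 35, 0, 0.3), c(256L, 35L, 35L)))
  expect_equal(dim(y), c(896L, 17L, 17L, 1L))

  rb <- reduction_b()
  expect_equal(rb$branch_sizes[4L], 896L)  # pool branch preserves channels
  expect_equal(rb$out_c, 1792L)
  y2 <- fw(rb, array(rnorm(896 * 17 * 17, 0, 0.3), c(896L, 17L, 17L)))
  expect_equal(dim(y2), c(1792L, 8L, 8L, 1L))
})

test_that("attention gates stay in (0, 1), scale by exactly 0.25 at zero init,
           and use hidden width channels/rate", {
  set.seed(5)
  g <- gam_module(32L, 4L)
  expect_equal(g$hidden, 8L)
  expect_equal(gam_module(1792L, 16L)$hidden, 112L)
  expect_error(gam_module(30L, 4L), "configuration error")

  x <- array(rnorm(32 * 5 * 5), c(32L, 5L, 5L))
  res <- gam_forward(g, x)
  expect_true(all(res$channel_weights > 0 & res$channel_weights < 1))
  expect_true(all(res$spatial_weights > 0 & res$spatial_weights < 1))
  expect_true(all(abs(res$output) <= abs(maizegrader:::as_batch(x))))
  expect_equal(dim(res$output), c(32L, 5L, 5L, 1L))
  expect_equal(res$output,
               maizegrader:::as_batch(x) * res$channel_weights * res$spatial_weights)
  expect_true(all(gam_forward(g, array(0, c(32L, 5L, 5L)))$output == 0))

  for (l in maizegrader:::module_layers(g)) maizegrader:::zero_layer(l)
  res0 <- gam_forward(g, x)
  expect_equal(res0$output, maizegrader:::as_batch(x) * 0.25, tolerance = 1e-15)
})

test_that("full model emits six probabilities with lower-level tie-breaking", {
  cfg <- irgam_tiny_config(input_size = 75L)
  m <- build_model(cfg, seed = 9)
  x <- array(runif(3 * 75 * 75) * 2 - 1, c(3L, 75L, 75L))
  p <- predict_proba(m, x)
  expect_equal(dim(p), c(1L, 6L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))
  # zero head -> equal logits -> uniform probabilities, tie resolves to level 0
  maizegrader:::zero_layer(m$stages$logits)
  p0 <- predict_proba(m, x)
  expect_equal(as.numeric(p0), rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(as.integer(attr(p0, "level")), 0L)
  # closed-form softmax
  expect_equal(softmax(c(1, 0, 0, 0, 0, 0))[1L, 1L], exp(1) / (exp(1) + 5),
               tolerance = 1e-12)
})

test_that("parameter audit equals analytic layer-by-layer counts", {
  # single 3x3 conv, 3 -> 8, with bias
  l <- conv_layer(3L, 8L, use_bn = FALSE)
  expect_equal(sum(vapply(maizegrader:::ly_param_names(l),
                          function(f) length(l[[f]]), numeric(1))),
               3 * 3 * 3 * 8 + 8)

  # three toy configs, counted independently from the width algebra
  analytic_conv <- function(ic, oc, kh, kw, bn = TRUE) {
    ic * oc * kh * kw + if (bn) 2 * oc else oc
  }
  cfg <- irgam_tiny_config(input_size = 75L)
  for (nb in c(1L, 2L)) {
    cfg2 <- irgam_tiny_config(input_size = 75L, n_blocks_a = nb)
    audit <- count_parameters(build_model(cfg2, seed = 1))
    w <- maizegrader:::config_widths(cfg2)
    stem <- analytic_conv(3, 8, 3, 3) + analytic_conv(8, 8, 3, 3) +
      analytic_conv(8, 16, 3, 3) + analytic_conv(16, 16, 1, 1) +
      analytic_conv(16, 24, 3, 3) + analytic_conv(24, 32, 3, 3)
    blk_a <- analytic_conv(32, 8, 1, 1) + analytic_conv(32, 8, 1, 1) +
      analytic_conv(8, 8, 3, 3) + analytic_conv(32, 8, 1, 1) +
      analytic_conv(8, 12, 3, 3) + analytic_conv(12, 16, 3, 3) +
      analytic_conv(8 + 8 + 16, 32, 1, 1)
    red_a <- analytic_conv(32, 16, 3, 3) + analytic_conv(32, 16, 1, 1) +
      analytic_conv(16, 16, 3, 3) + analytic_conv(16, 16, 3, 3)
    blk_b <- analytic_conv(64, 16, 1, 1) + analytic_conv(64, 16, 1, 1) +
      analytic_conv(16, 16, 1, 7) + analytic_conv(16, 16, 7, 1) +
      analytic_conv(32, 64, 1, 1)
    red_b <- analytic_conv(64, 16, 1, 1) + analytic_conv(16, 32, 3, 3) +
      analytic_conv(64, 16, 1, 1) + analytic_conv(16, 32, 3, 3) +
      analytic_conv(64, 16, 1, 1) + analytic_conv(16, 16, 3, 3) +
      analytic_conv(16, 32, 3, 3)
    gam <- (160 * 40 + 40) + (40 * 160 + 160) +
      (160 * 40 * 49 + 40) + (40 * 160 * 49 + 160)
    head <- 160 * 6 + 6
    expect_equal(audit$total_params,
                 stem + nb * blk_a + red_a + blk_b + red_b + gam + head)
    expect_equal(audit$bytes, 4 * audit$total_params)
    expect_equal(audit$size_mib, round(audit$bytes / 1024^2, 2))
  }
})

test_that("ablation variants rewire the graph as declared", {
  cfg <- irgam_tiny_config(input_size = 75L)
  full <- build_model(cfg, seed = 31)
  ident <- build_ablation_variant(cfg, "full", seed = 31)
  expect_identical(count_parameters(full)$per_layer,
                   count_parameters(ident)$per_layer)

  red <- build_ablation_variant(cfg, "reduction_to_strided_conv", seed = 31)
  expect_s3_class(red$stages$reduction_a, "conv_layer")
  expect_equal(red$stages$reduction_a$out_c, 64L)
  x <- array(runif(3 * 75 * 75) * 2 - 1, c(3L, 75L, 75L))
  expect_equal(dim(model_forward(red, x)), c(6L, 1L))

  nog <- build_ablation_variant(cfg, "no_gam", seed = 31)
  expect_false("gam" %in% names(nog$stages))
  expect_false(any(grepl("^gam", count_parameters(nog)$per_layer$name)))
  expect_equal(dim(model_forward(nog, x)), c(6L, 1L))

  da <- build_ablation_variant(cfg, "drop_a", seed = 31)
  db <- build_ablation_variant(cfg, "drop_b", seed = 31)
  expect_false("block_a" %in% names(da$stages))
  expect_false("block_b" %in% names(db$stages))
  expect_equal(dim(model_forward(da, x)), c(6L, 1L))
  expect_equal(dim(model_forward(db, x)), c(6L, 1L))

  expect_error(build_ablation_variant(cfg, "bogus"), "usage error")

  # stacking depth changes only the A-stage parameter count
  a1 <- count_parameters(build_model(irgam_tiny_config(input_size = 75L,
                                                       n_blocks_a = 1L)))
  a3 <- count_parameters(build_model(irgam_tiny_config(input_size = 75L,
                                                       n_blocks_a = 3L)))
  non_a1 <- a1$per_layer[!grepl("^block_a", a1$per_layer$name), ]
  non_a3 <- a3$per_layer[!grepl("^block_a", a3$per_layer$name), ]
  rownames(non_a1) <- rownames(non_a3) <- NULL
  expect_identical(non_a1, non_a3)
  expect_gt(a3$total_params, a1$total_params)
})

test_that("checkpoint round-trips weights and predictions exactly", {
  cfg <- irgam_tiny_config(input_size = 75L)
  m <- build_model(cfg, seed = 5)
  x <- array(runif(3 * 75 * 75) * 2 - 1, c(3L, 75L, 75L))
  p1 <- predict_proba(m, x)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_proba(m2, x), p1)
  unlink(path)
})
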