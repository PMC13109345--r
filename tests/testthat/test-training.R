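test_that("cross-entropy matches its closed forms", {
  perfect <- diag(6)[c(1, 4, 6), ]
  expect_equal(cross_entropy(perfect, c(0L, 3L, 5L)), 0, tolerance = 1e-12)
  uniform <- matrix(1 / 6, 4, 6)
  expect_equal(cross_entropy(uniform, c(0L, 1L, 2L, 5L)), log(6),
               tolerance = 1e-12)
  p <- matrix(c(0.7, 0.3, 0, 0, 0, 0,
                0.2, 0.8, 0, 0, 0, 0), 2, 6, byrow = TRUE)
  expect_equal(cross_entropy(p, c(0L, 1L)), -(log(0.7) + log(0.8)) / 2,
               tolerance = 1e-12)
  expect_error(cross_entropy(uniform, c(0L, 1L)), "usage error")
  expect_error(cross_entropy(uniform, c(0L, 1L, 2L, 6L)), "usage error")
  expect_error(cross_entropy(matrix(0.5, 2, 6), c(0L, 1L)), "usage error")
})

test_that("cosine schedule hits its endpoints and decreases monotonically", {
  cfg <- train_config(t_max = 1000L)
  expect_equal(cosine_lr(0, cfg), 1e-4)
  expect_equal(cosine_lr(1000, cfg), 1e-6)
  expect_equal(cosine_lr(500, cfg), (1e-4 + 1e-6) / 2)
  lr <- cosine_lr(0:1000, cfg)
  expect_true(all(diff(lr) < 0))
  expect_true(all(lr >= 1e-6 & lr <= 1e-4))
  expect_error(cosine_lr(1001, cfg), "usage error")
  expect_error(cosine_lr(-1, cfg), "usage error")
})

test_that("Adam matches an independent transcription of its update rule", {
  # independent straight-line transcription, kept separate from the package
  ref_adam <- function(theta, grad_fn, n, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
    m <- v <- theta * 0
    for (t in seq_len(n)) {
      g <- grad_fn(theta)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^t)
      vh <- v / (1 - b2^t)
      theta <- theta - lr * mh / (sqrt(vh) + eps)
    }
    theta
  }
  # 2-parameter quadratic f(x, y) = (x-3)^2 + 2(y+1)^2
  grad_fn <- function(th) c(2 * (th[1] - 3), 4 * (th[2] + 1))
  cfg <- train_config()
  st <- adam_init(list(th = c(0, 0)))
  params <- list(th = c(0, 0))
  for (t in 1:10) {
    u <- adam_step(st, list(th = grad_fn(params$th)), params, lr = 0.05, cfg)
    st <- u$state; params <- u$params
  }
  expect_equal(params$th, ref_adam(c(0, 0), grad_fn, 10, 0.05),
               tolerance = 1e-10)

  # one-step closed form: theta0 = 0, g = 1, lr = 0.1 -> -0.1/(1 + eps)
  u1 <- adam_step(adam_init(list(a = 0)), list(a = 1), list(a = 0), 0.1, cfg)
  expect_equal(u1$params$a, -0.1 / (1 + 1e-8), tolerance = 1e-12)

  # zero gradient is a fixed point
  u0 <- adam_step(adam_init(list(a = 2)), list(a = 0), list(a = 2), 0.1, cfg)
  expect_equal(u0$params$a, 2)

  expect_error(adam_step(adam_init(list(a = 0)), list(a = NaN), list(a = 0),
                         0.1, cfg), "numeric error")
})

test_that("initialisation schemes have their defining statistics", {
  set.seed(77)
  l <- conv_layer(16L, 32L, 5L, 5L)   # fan_in 400, 12800 weights
  maizegrader:::init_layer_weights(l, "he")
  expect_equal(stats::var(as.numeric(l$W)), 2 / 400, tolerance = 0.1)
  maizegrader:::init_layer_weights(l, "xavier")
  expect_equal(stats::var(as.numeric(l$W)), 2 / (400 + 800), tolerance = 0.1)
  d <- maizegrader:::dense_layer(64L, 64L)
  maizegrader:::init_layer_weights(d, "orthogonal")
  expect_equal(d$W %*% t(d$W), diag(64), tolerance = 1e-5)
  expect_error(init_params(build_model(irgam_tiny_config(input_size = 75L)),
                           "bogus"), "usage error")
  # determinism under seed
  m1 <- build_model(irgam_tiny_config(input_size = 75L), seed = 3)
  m2 <- build_model(irgam_tiny_config(input_size = 75L), seed = 3)
  expect_identical(maizegrader:::model_param_list(m1),
                   maizegrader:::model_param_list(m2))
})

test_that("augmentation yields exactly three label-safe, seeded variants", {
  set.seed(1)
  smp <- list(image = array(runif(3 * 16 * 16, 0.2, 0.8), c(3L, 16L, 16L)),
              level = 4L, id = "s1")
  v1 <- augment_sample(smp, seed = 9)
  v2 <- augment_sample(smp, seed = 9)
  expect_length(v1, 3L)
  expect_identical(v1, v2)
  for (v in v1) {
    expect_equal(v$level, 4L)
    expect_equal(dim(v$image), dim(smp$image))
    expect_true(all(v$image >= 0 & v$image <= 1))
  }
  expect_false(identical(v1[[1L]]$image, smp$image))  # noise changed pixels
  # parameter limits degenerate to the identity
  v0 <- augment_sample(smp, seed = 9, noise_sigma = 0,
                       brightness_factors = c(1, 1), blur_sigma = 0)
  expect_equal(v0[[1L]]$image, smp$image)
  expect_equal(v0[[2L]]$image, smp$image)
  expect_equal(v0[[3L]]$image, smp$image)
})

test_that("a single optimisation step decreases the batch loss", {
  set.seed(13)
  cfg <- irgam_config(input_size = 75L, dropout = 0,
                      stem_conv = c(4L, 4L, 8L), stem_erf = c(8L, 8L, 16L),
                      n_blocks_a = 1L, a_br1 = 4L, a_br2 = c(4L, 4L),
                      a_erf = c(4L, 4L, 8L), ra_conv = 8L, ra_erf = c(8L, 8L, 8L),
                      n_blocks_b = 1L, b_br1 = 8L, b_br2 = c(8L, 8L, 8L),
                      rb_br1 = c(8L, 8L), rb_br2 = c(8L, 8L),
                      rb_erf = c(8L, 8L, 8L), gam_rate = 4L)
  m <- build_model(cfg, seed = 13)
  xb <- array(runif(3 * 75 * 75 * 8) * 2 - 1, c(3L, 75L, 75L, 8L))
  yb <- rep(0:3, 2)
  batch_loss <- function(keep) {
    cross_entropy(softmax(t(model_forward(m, xb, training = TRUE,
                                          keep = keep))), yb)
  }
  l0 <- batch_loss(keep = TRUE)
  p <- softmax(t(model_forward(m, xb, training = TRUE, keep = TRUE)))
  dl <- t(p)
  dl[cbind(yb + 1L, seq_along(yb))] <- dl[cbind(yb + 1L, seq_along(yb))] - 1
  model_backward(m, dl / length(yb))
  params <- maizegrader:::model_param_list(m)
  u <- adam_step(adam_init(params), maizegrader:::model_grad_list(m),
                 params, lr = 1e-3, train_config())
  maizegrader:::model_set_params(m, u$params)
  expect_lt(batch_loss(keep = FALSE), l0)
})

test_that("training is seeded, reproducible, and a no-op at zero epochs", {
  ds <- generate_dataset(rep(3L, 6L), "ear", base_seed = 5,
                         image_size = 75L)
  cfg <- irgam_tiny_config(input_size = 75L)
  tc <- train_config(batch_size = 6L, epochs = 2L, lr_max = 1e-3,
                     lr_min = 1e-5, seed = 42L)
  m1 <- build_model(cfg, seed = 42)
  h1 <- train(m1, ds$samples, tc)$history
  m2 <- build_model(cfg, seed = 42)
  h2 <- train(m2, ds$samples, tc)$history
  expect_identical(h1, h2)
  expect_identical(maizegrader:::model_param_list(m1),
                   maizegrader:::model_param_list(m2))
  expect_equal(nrow(h1), 2L)
  expect_true(all(is.finite(h1$mean_loss)))

  m0 <- build_model(cfg, seed = 42)
  before <- maizegrader:::model_param_list(m0)
  out <- train(m0, ds$samples, train_config(epochs = 0L, seed = 1L))
  expect_identical(maizegrader:::model_param_list(m0), before)
  expect_equal(nrow(out$history), 0L)
  expect_error(train(build_model(cfg), list(), tc), "usage error")
})

test_that("augmented training pool grows fourfold and still learns", {
  ds <- generate_dataset(rep(2L, 6L), "ear", base_seed = 8, image_size = 75L)
  cfg <- irgam_tiny_config(input_size = 75L)
  m <- build_model(cfg, seed = 2)
  tc <- train_config(batch_size = 16L, epochs = 1L, lr_max = 1e-3,
                     lr_min = 1e-5, seed = 2L, augment = TRUE)
  fit <- train(m, ds$samples, tc)
  # 12 originals + 36 variants = 48 samples -> 3 iterations of batch 16
  expect_equal(nrow(fit$history), 1L)
  expect_true(is.finite(fit$history$mean_loss))
})
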