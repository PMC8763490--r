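# CNN building blocks, training mechanics, reproducibility.

test_that("relu and softmax behave elementwise", {
  expect_equal(relu(c(-2, 0, 5)), c(0, 0, 5))
  expect_equal(relu(matrix(c(-1, 2, -3, 4), 2)), matrix(c(0, 2, 0, 4), 2))
  p <- softmax(c(1, 2, 3))
  expect_equal(sum(p), 1)
  expect_true(all(diff(p) > 0))
  pm <- softmax(matrix(rnorm(12), 3, 4))
  expect_equal(colSums(pm), rep(1, 4))
})

test_that("cross-entropy matches the explicit per-sample loop", {
  expect_equal(cross_entropy(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(cross_entropy(c(1, 0, 0, 0), rep(0.25, 4)), log(4))
  set.seed(3)
  m <- 6; n <- 10
  z <- t(vapply(sample(m, n, TRUE), function(k) {
    v <- numeric(m); v[k] <- 1; v
  }, numeric(m)))
  p <- matrix(rexp(n * m), n, m)
  p <- p / rowSums(p)
  manual <- 0
  for (i in 1:n) {
    for (c in 1:m) manual <- manual - z[i, c] * log(max(p[i, c], 1e-12))
  }
  expect_lt(abs(cross_entropy(z, p) - manual / n), 1e-10)
  expect_error(cross_entropy(z, p * 2), "summing to 1")
})

test_that("softmax cross-entropy gradient matches finite differences", {
  set.seed(7)
  z <- rnorm(5)
  y <- c(0, 0, 1, 0, 0)
  analytic <- softmax(z) - y      # d/dz of -sum y log softmax(z)
  h <- 1e-6
  fd <- vapply(1:5, function(i) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    (cross_entropy(y, softmax(zp)) - cross_entropy(y, softmax(zm))) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(analytic - fd)), 1e-5)
})

test_that("the learning-rate schedule steps by the decay factor", {
  expect_equal(lr_schedule(0, 0.01), 0.01)
  expect_equal(lr_schedule(10, 0.01), 0.001)
  expect_equal(lr_schedule(25, 0.01), 1e-4)
  expect_equal(lr_schedule(0:59, 1),
               10^-rep(0:5, each = 10))
})

test_that("architecture geometry follows from the configuration", {
  cfg <- mcnn_config()
  expect_equal(cfg$input_shape[1] / 2^cfg$n_blocks, 4)  # 256 -> 4 after 6 pools
  m <- build_mcnn(cfg)
  expect_equal(length(m$conv_w), 6)
  expect_equal(dim(m$conv_w[[1]]), c(8L, 9L * 8L))
  expect_equal(dim(m$fc_w[[1]]), c(4096L, 4L * 4L * 256L))
  expect_equal(m$n_params,
               sum(lengths(m$conv_w)) + sum(lengths(m$conv_b)) +
                 sum(lengths(m$fc_w)) + sum(lengths(m$fc_b)))
  # 64x64 input collapses to 1x1 after six pools
  cfg64 <- mcnn_benchmark_config()
  m64 <- build_mcnn(cfg64)
  expect_equal(m64$flat_features, 128L)
  # spatial collapse below 1x1 is a configuration error
  expect_error(mcnn_config(input_shape = c(32, 32, 8), n_blocks = 6),
               "pool")
  # incremental-depth study configurations are all constructible
  for (nb in 1:6) {
    mk <- build_mcnn(mcnn_config(input_shape = c(64, 64, 4), n_blocks = nb,
                                 channel_progression = rep(4, nb),
                                 fc_units = 32, n_classes = 4))
    expect_equal(length(mk$conv_w), nb)
  }
})

test_that("predictions are normalized and near-uniform at initialization", {
  cfg <- mcnn_config(input_shape = c(32, 32, 2), n_blocks = 3,
                     channel_progression = c(4, 8, 16), fc_units = 64,
                     n_classes = 5, seed = 2)
  m <- build_mcnn(cfg)
  set.seed(9)
  x <- array(rnorm(32 * 32 * 2 * 20), c(32, 32, 2, 20))
  pr <- predict(m, x)
  expect_equal(rowSums(pr$probabilities), rep(1, 20), tolerance = 1e-6)
  expect_lt(mean(apply(pr$probabilities, 1, max)), 2 / 5)
  expect_error(predict(m, array(0, c(16, 16, 2, 1))), "shape")
})

test_that("training separates a linearly separable two-class set", {
  cfg <- mcnn_config(input_shape = c(32, 32, 2), n_blocks = 2,
                     channel_progression = c(4, 8), fc_units = 32,
                     n_classes = 2, lr0 = 0.01, batch_size = 10,
                     dropout_rate = 0.2, seed = 5)
  m <- build_mcnn(cfg)
  set.seed(31)
  n <- 40
  x <- array(rnorm(32 * 32 * 2 * n, sd = 0.1), c(32, 32, 2, n))
  y <- rep(c("dim", "bright"), each = n / 2)
  x[10:20, 10:20, , y == "bright"] <- x[10:20, 10:20, , y == "bright"] + 1
  m <- train_mcnn(m, x, y, x_val = x, y_val = y, epochs = 5)
  expect_equal(max(m$history$val_acc), 1.0)   # perfect within 5 epochs
  # initial loss of the first epoch starts near log(n_classes)
  expect_lt(abs(m$history$train_loss[1] - log(2)) / log(2), 0.5)
})

test_that("training is bit-reproducible for a fixed seed", {
  cfg <- mcnn_config(input_shape = c(16, 16, 1), n_blocks = 2,
                     channel_progression = c(3, 4), fc_units = 16,
                     n_classes = 3, batch_size = 4, seed = 123)
  set.seed(8)
  x <- array(rnorm(16 * 16 * 12), c(16, 16, 1, 12))
  y <- rep(c("a", "b", "c"), 4)
  m1 <- train_mcnn(build_mcnn(cfg), x, y, epochs = 4)
  m2 <- train_mcnn(build_mcnn(cfg), x, y, epochs = 4)
  expect_identical(m1$conv_w, m2$conv_w)
  expect_identical(m1$fc_w, m2$fc_w)
  expect_identical(m1$history, m2$history)
  # the learning-rate column equals the schedule exactly
  expect_identical(m1$history$lr,
                   lr_schedule(m1$history$epoch - 1, cfg$lr0,
                               cfg$lr_decay_factor, cfg$lr_decay_every))
})

test_that("models save and load as a single portable file", {
  cfg <- mcnn_config(input_shape = c(16, 16, 1), n_blocks = 1,
                     channel_progression = 2, fc_units = 8, n_classes = 2)
  m <- build_mcnn(cfg, class_labels = c("x", "y"))
  path <- tempfile(fileext = ".rds")
  save_mcnn(m, path)
  m2 <- load_mcnn(path)
  expect_identical(m$conv_w, m2$conv_w)
  expect_identical(m2$config$n_blocks, 1L)
  set.seed(1)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  expect_identical(predict(m, x), predict(m2, x))
})
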