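test_that("initialization is seeded, bounded and reproducible", {
  cfg <- ae_config(seed = 42L)
  m1 <- ae_init(cfg); m2 <- ae_init(cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  m3 <- ae_init(ae_config(seed = 43L))
  expect_false(identical(m1$W1, m3$W1))
  lim <- sqrt(6 / (256 + 64))
  expect_lte(max(abs(m1$W1)), lim)
  expect_lte(max(abs(m1$W2)), lim)
  expect_equal(m1$b1, numeric(64))
  expect_equal(m1$b2, numeric(256))
  # initialization does not disturb the caller's RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(ae_init(cfg)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("training on a single repeated pattern converges toward it", {
  set.seed(3)
  v <- abs(stats::rnorm(256, sd = 10))
  frames <- matrix(rep(v, 50), nrow = 50, byrow = TRUE)
  m <- ae_train(ae_init(ae_config(seed = 1L)), frames)
  expect_length(m$loss_trace, 25L)
  expect_lt(m$loss_trace[25L], m$loss_trace[1L])
  err <- ae_error(m, frames)
  init_err <- ae_error(ae_init(ae_config(seed = 1L)), frames)
  expect_lt(mean(err$scalar), 0.2 * mean(init_err$scalar))
})

test_that("all-zero frames with zero biases are a fixed point with zero loss", {
  frames <- matrix(0, 30, 256)
  m <- ae_train(ae_init(ae_config(seed = 5L)), frames)
  expect_equal(m$loss_trace, numeric(25))
  expect_equal(ae_error(m, frames)$errors, matrix(0, 30, 256))
})

test_that("error of a zero-weight model is the input itself; scalar is the mean", {
  m <- ae_init(ae_config(seed = 1L))
  m$W1[] <- 0; m$W2[] <- 0
  set.seed(9)
  X <- matrix(stats::rnorm(10 * 256), 10, 256)
  ef <- ae_error(m, X)
  expect_equal(ef$errors, abs(X))
  expect_equal(ef$scalar, rowMeans(abs(X)))
  expect_error(ae_error(m, X[, 1:100]), "input_dim")
})

test_that("training is deterministic and full-batch updates are order-invariant", {
  set.seed(11)
  X <- matrix(abs(stats::rnorm(60 * 256, sd = 5)), 60, 256)
  cfg <- ae_config(seed = 2L)
  m1 <- ae_train(ae_init(cfg), X)
  m2 <- ae_train(ae_init(cfg), X)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$loss_trace, m2$loss_trace)
  cfg_fb <- ae_config(seed = 2L, batch_size = NULL)
  perm <- sample(nrow(X))
  f1 <- ae_train(ae_init(cfg_fb), X)
  f2 <- ae_train(ae_init(cfg_fb), X[perm, ])
  expect_equal(f1$W1, f2$W1, tolerance = 1e-12)
  expect_equal(f1$loss_trace, f2$loss_trace, tolerance = 1e-12)
})

test_that("reconstruction error separates background subspace from orthogonal frames", {
  for (seed in 1:2) {
    fx <- subspace_fixture(seed)
    m <- ae_train(ae_init(ae_config(seed = seed)), fx$background)
    e_bg <- mean(ae_error(m, fx$background)$scalar)
    e_an <- mean(ae_error(m, fx$anomalous)$scalar)
    expect_gte(e_an / e_bg, 5)
  }
})

test_that("models survive a JSON save/load round trip", {
  set.seed(13)
  X <- matrix(abs(stats::rnorm(40 * 256, sd = 3)), 40, 256)
  m <- ae_train(ae_init(ae_config(seed = 7L)), X)
  p <- withr::local_tempfile(fileext = ".json")
  ae_save(m, p)
  m2 <- ae_load(p)
  expect_equal(m2$W1, m$W1)
  expect_equal(m2$b2, m$b2)
  expect_equal(m2$scale, m$scale)
  expect_equal(ae_error(m2, X)$scalar, ae_error(m, X)$scalar)
})
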