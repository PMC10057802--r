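test_that("degenerate Viterbi cases behave as closed forms", {
  set.seed(1)
  X <- matrix(stats::rnorm(20 * 4), 20, 4)
  # single state: constant path
  m1 <- hmm_model(matrix(0, 1, 4))
  expect_equal(viterbi_segment(X, m1, hmm_config()), rep(1L, 20))
  # zero penalty: per-frame nearest centroid
  C <- matrix(stats::rnorm(3 * 4, sd = 2), 3, 4)
  m3 <- hmm_model(C)
  path0 <- viterbi_segment(X, m3, hmm_config(penalty = 0))
  nearest <- apply(X, 1L, function(x)
    which.min(colSums((t(C) - x)^2)))
  expect_equal(path0, unname(nearest))
  expect_error(viterbi_segment(X, hmm_model(matrix(0, 1, 3)), hmm_config()),
               "dimension")
})

test_that("Viterbi equals exhaustive minimization on small instances", {
  set.seed(99)
  for (case in 1:100) {
    T_ <- sample(2:8, 1L); K <- sample(2:3, 1L); d <- sample(1:3, 1L)
    X <- matrix(stats::rnorm(T_ * d, sd = 2), T_, d)
    C <- matrix(stats::rnorm(K * d, sd = 2), K, d)
    pen <- sample(c(0, 0.5, 2, 10), 1L)
    model <- hmm_model(C)
    E <- eegseg:::.emission_cost(X, model)
    path <- viterbi_segment(X, model, hmm_config(penalty = pen))
    bf <- brute_force_viterbi(E, pen)
    got <- sum(E[cbind(seq_len(T_), path)]) + pen * sum(diff(path) != 0)
    expect_equal(got, bf$cost, tolerance = 1e-12)
    expect_true(any(apply(bf$paths, 1L, function(p) all(p == path))))
  }
})

test_that("raising the penalty never increases the number of transitions", {
  set.seed(123)
  for (case in 1:30) {
    T_ <- 8L; K <- 3L
    X <- matrix(stats::rnorm(T_ * 2, sd = 2), T_, 2L)
    model <- hmm_model(matrix(stats::rnorm(K * 2, sd = 2), K, 2L))
    trans <- vapply(c(0, 0.2, 1, 5, 25), function(pen)
      sum(diff(viterbi_segment(X, model, hmm_config(penalty = pen))) != 0),
      numeric(1))
    expect_true(all(diff(trans) <= 0))
  }
})

test_that("a single tight regime yields exactly one state", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(stats::rnorm(300 * 16), 300, 16)
    hs <- hypothesize_states(X, hmm_config())
    expect_equal(nrow(hs$model$centroids), 1L)
    expect_equal(hs$path, rep(1L, 300))
  }
})

test_that("three planted regimes are recovered with exact boundaries", {
  hits <- 0L
  for (seed in 1:10) {
    pb <- planted_blocks(seed)
    hs <- hypothesize_states(pb$X, hmm_config())
    if (nrow(hs$model$centroids) == 3L) {
      b <- which(diff(hs$path) != 0L)
      if (length(b) == 2L && all(abs(b - pb$boundaries) <= 1L))
        hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("a burst shorter than min_frequency is pruned and absorbed", {
  set.seed(5)
  d <- 16L
  X <- rbind(matrix(stats::rnorm(100 * d), 100, d),
             matrix(stats::rnorm(10 * d, mean = 30), 10, d),
             matrix(stats::rnorm(100 * d), 100, d))
  hs <- hypothesize_states(X, hmm_config(min_frequency = 20L))
  expect_equal(nrow(hs$model$centroids), 1L)
  expect_equal(length(hs$path), 210L)
  # with a permissive min_frequency the same burst gets its own state
  hs2 <- hypothesize_states(X, hmm_config(min_frequency = 5L))
  expect_equal(nrow(hs2$model$centroids), 2L)
  expect_equal(sum(hs2$path != hs2$path[1L]), 10L)
})

test_that("the hypothesis loop is deterministic and states keep min support", {
  pb <- planted_blocks(3L)
  h1 <- hypothesize_states(pb$X, hmm_config())
  h2 <- hypothesize_states(pb$X, hmm_config())
  expect_identical(h1$model$centroids, h2$model$centroids)
  expect_identical(h1$path, h2$path)
  counts <- tabulate(h1$path, nbins = nrow(h1$model$centroids))
  expect_true(all(counts >= 20L))
  # scale covariance: rescaling the input rescales centroids, not the path
  h3 <- hypothesize_states(pb$X * 1000, hmm_config())
  expect_identical(h3$path, h1$path)
  expect_equal(h3$model$centroids, h1$model$centroids * 1000)
})

test_that("label_track flags non-background frames and conserves counts", {
  pb <- planted_blocks(7L)
  hs <- hypothesize_states(pb$X, hmm_config())
  err <- rowMeans(abs(pb$X))
  tr <- label_track(hs$path, hs$model, err)
  bg <- tr$background_id
  expect_equal(sum(tr$flags), length(hs$path) - sum(hs$path == bg))
  expect_equal(which(!tr$flags), which(hs$path == bg))
  # single-state track: no flags
  one <- label_track(rep(1L, 50), hmm_model(matrix(0, 1, 2)), rep(1, 50))
  expect_false(any(one$flags))
  # 90/10 split: minority flagged
  path <- c(rep(1L, 90), rep(2L, 10))
  two <- label_track(path, hmm_model(matrix(0, 2, 2)), seq_len(100))
  expect_equal(two$background_id, 1L)
  expect_equal(sum(two$flags), 10L)
  expect_error(label_track(path, hmm_model(matrix(0, 2, 2)), 1:5),
               "lengths differ")
})

test_that("error-ratio flag policy only flags high-error states", {
  path <- c(rep(1L, 60), rep(2L, 30), rep(3L, 30))
  err <- c(rep(1, 60), rep(1.2, 30), rep(10, 30))
  m <- hmm_model(matrix(0, 3, 2))
  tr <- label_track(path, m, err, policy = "error_ratio", theta = 2)
  expect_equal(sum(tr$flags), 30L)
  expect_true(all(which(tr$flags) > 90L))
})
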