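# Shared helpers: tiny recordings, an exhaustive Viterbi oracle, and
# independent metric formulas used to cross-check the implementation.

make_sine_rec <- function(n_channels = 2L, seconds = 4L, sr = 256L,
                          freqs = NULL, amp = 50) {
  t <- (seq_len(seconds * sr) - 1L) / sr
  if (is.null(freqs)) freqs <- 5 + seq_len(n_channels)
  sig <- sapply(freqs, function(f) amp * sin(2 * pi * f * t))
  recording(matrix(sig, ncol = n_channels), sr, file_id = "sine")
}

# exhaustive minimization over all K^T labelings; returns min cost and the
# full set of optimal paths
brute_force_viterbi <- function(E, penalty) {
  T_ <- nrow(E); K <- ncol(E)
  grids <- expand.grid(rep(list(seq_len(K)), T_))
  costs <- apply(grids, 1L, function(p)
    sum(E[cbind(seq_len(T_), p)]) + penalty * sum(diff(p) != 0))
  best <- min(costs)
  list(cost = best,
       paths = unname(as.matrix(grids[costs <= best + 1e-12, , drop = FALSE])))
}

# independent metric formulas, written directly from their definitions
oracle_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
       accuracy = div(tp + tn, tp + fp + tn + fn),
       f1 = div(2 * tp, 2 * tp + fp + fn),
       ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
       fpr = div(fp, fp + tn), fnr = div(fn, fn + tp),
       fdr = div(fp, fp + tp), fomr = div(fn, fn + tn),
       mcc = {
         den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
         if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
       })
}

# 3 well-separated planted regimes in d dimensions, L frames each
planted_blocks <- function(seed, d = 32L, L = 60L, sep = 6) {
  set.seed(seed)
  C <- matrix(stats::rnorm(3 * d, 0, sep), 3, d)
  X <- rbind(C[rep(1L, L), ], C[rep(2L, L), ], C[rep(3L, L), ]) +
    matrix(stats::rnorm(3 * L * d), 3L * L, d)
  list(X = X, boundaries = c(L, 2L * L))
}

# rank-limited background frames plus frames from an orthogonal subspace
subspace_fixture <- function(seed, d = 256L, r = 48L, n_bg = 400L,
                             n_anom = 100L) {
  set.seed(seed + 1000L)
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  bg <- matrix(stats::rnorm(n_bg * r), n_bg, r) %*% t(Q[, 1:r]) +
    matrix(stats::rnorm(n_bg * d, 0, 1e-3), n_bg, d)
  anom <- matrix(stats::rnorm(n_anom * r), n_anom, r) %*%
    t(Q[, (r + 1L):(2L * r)])
  list(background = bg, anomalous = anom)
}
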