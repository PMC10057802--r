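# Penalized-Viterbi segmentation with a generative state-hypothesis loop.
# States are centroids in the frame-vector space; the optimal path minimizes
# total emission cost plus a fixed penalty per state change, which yields
# piecewise-constant segmentations. New states are hypothesized from the
# worst-fitting contiguous stretch of frames and must both reduce the total
# path cost and claim at least `min_frequency` frames to survive.

#' HMM segmenter configuration
#'
#' @param penalty non-negative additive cost per state transition in the
#'   Viterbi path (default 200).
#' @param min_frequency minimum number of frames a state must claim to
#'   survive (default 20); also the length of the sliding window used to
#'   hypothesize new states.
#' @param max_iterations cap on hypothesis-loop iterations (default 20).
#' @return object of class `hmm_config`.
#' @details The per-frame emission cost is the squared Euclidean deviation
#'   between the frame vector and the state centroid, divided by the model's
#'   robust scale (twice the robust per-dimension variance of the training
#'   sequence, the unit-Gaussian log-likelihood convention; see
#'   [hypothesize_states()]). A typical background frame then costs about
#'   `d / 2`, so the default penalty of 200 is paid off by a contiguous
#'   anomalous stretch of a few frames but not by temporally scattered
#'   variance, independent of the amplitude units of the input.
#' @export
hmm_config <- function(penalty = 200, min_frequency = 20L,
                       max_iterations = 20L) {
  if (penalty < 0) stop("penalty must be >= 0")
  if (min_frequency < 1L) stop("min_frequency must be >= 1")
  structure(list(penalty = as.numeric(penalty),
                 min_frequency = as.integer(min_frequency),
                 max_iterations = as.integer(max_iterations)),
            class = "hmm_config")
}

#' Construct an HMM state model
#'
#' @param centroids numeric matrix, one state centroid per row.
#' @param scale positive emission scale divisor (default 1).
#' @return object of class `hmm_model`.
#' @export
hmm_model <- function(centroids, scale = 1) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 1L) stop("need at least one state")
  if (!all(is.finite(centroids))) stop("centroids must be finite")
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  structure(list(centroids = centroids, scale = scale), class = "hmm_model")
}

# F x K matrix of emission costs: squared Euclidean deviation from the
# centroid divided by the model's scale (2x the robust per-dimension
# variance, the unit-Gaussian negative log-likelihood convention; 1 when
# unset, i.e. plain squared distance)
.emission_cost <- function(X, model) {
  d <- ncol(X)
  C <- model$centroids
  if (ncol(C) != d)
    stop("frame dimension (", d, ") does not match centroid dimension (",
         ncol(C), ")")
  E <- outer(rowSums(X^2), rep(1, nrow(C))) -
    2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  pmax(E, 0) / model$scale
}

# total path cost under the penalized objective
.path_cost <- function(E, path, penalty) {
  sum(E[cbind(seq_along(path), path)]) +
    penalty * sum(diff(path) != 0L)
}

#' Penalized Viterbi segmentation
#'
#' Finds the state path minimizing the sum of per-frame emission costs plus
#' `penalty` for every transition (`path[t] != path[t-1]`). The dynamic
#' program is exact; among cost-ties the lexicographically smallest path
#' (lower state ids first, which also favors staying in the current state
#' when it is the lower id) is returned, so results are deterministic across
#' platforms.
#'
#' @param X numeric matrix of frame vectors (`F x d`).
#' @param model an [hmm_model()].
#' @param cfg an [hmm_config()]; only `penalty` is used here.
#' @return integer vector of state ids (row indices into
#'   `model$centroids`), length `F`.
#' @export
viterbi_segment <- function(X, model, cfg = hmm_config()) {
  X <- as.matrix(X)
  F_ <- nrow(X)
  if (F_ < 1L) stop("need at least one frame")
  E <- .emission_cost(X, model)
  K <- ncol(E)
  if (K == 1L) return(rep(1L, F_))
  pen <- cfg$penalty
  # backward DP: S[t, k] = min cost of labeling frames t..F starting in k
  S <- E
  for (t in (F_ - 1L):1L) {
    m <- min(S[t + 1L, ])
    S[t, ] <- E[t, ] + pmin(S[t + 1L, ], m + pen)
  }
  # forward reconstruction, smallest id among optimal continuations
  path <- integer(F_)
  path[1L] <- which.min(S[1L, ])
  if (F_ > 1L) for (t in 2L:F_) {
    cont <- S[t, ] + pen
    cont[path[t - 1L]] <- S[t, path[t - 1L]]
    path[t] <- which.min(cont)
  }
  path
}

#' Hypothesize, characterize and prune HMM states for one sequence
#'
#' The generative loop: (1) start from a single state at the global
#' centroid; (2) Viterbi-segment; (3) re-estimate each state's centroid from
#' its claimed frames; (4) locate the contiguous stretch of
#' `min_frequency` frames with the highest mean emission cost under the
#' current segmentation and propose its centroid as a new state; (5) accept
#' the proposal only if it lowers the total path cost (emissions plus
#' transition penalties) and the new state claims at least `min_frequency`
#' frames; states that fall below `min_frequency` are dropped and their
#' frames reassigned on the next Viterbi pass; (6) stop when a proposal is
#' rejected or after `max_iterations`. Deterministic for fixed input.
#'
#' The emission scale is fixed once from the sequence as twice the robust
#' per-dimension variance: `2 * median_t(||x_t - mean(x)||^2) / d` (1 if
#' that is zero; the median protects the estimate from rare high-amplitude
#' frames). Dividing the squared deviation by it makes segmentation
#' invariant to rescaling the input, so `penalty` has a stable meaning
#' across recordings and units.
#'
#' @param X numeric matrix of frame vectors (`F x d`).
#' @param cfg an [hmm_config()].
#' @return list with `model` (an [hmm_model()]) and `path` (integer state
#'   ids, length `F`).
#' @export
hypothesize_states <- function(X, cfg = hmm_config()) {
  X <- as.matrix(X)
  F_ <- nrow(X); d <- ncol(X)
  if (F_ < 1L) stop("need at least one frame")
  g <- colMeans(X)
  dev <- rowSums((X - rep(g, each = F_))^2)
  scale <- 2 * stats::median(dev) / d  # 2x robust per-dimension variance
  if (!is.finite(scale) || scale <= 0) scale <- 1

  model <- hmm_model(matrix(g, nrow = 1L), scale = scale)
  path <- viterbi_segment(X, model, cfg)

  recenter <- function(model, path) {
    for (k in seq_len(nrow(model$centroids))) {
      idx <- which(path == k)
      if (length(idx))
        model$centroids[k, ] <- colMeans(X[idx, , drop = FALSE])
    }
    model
  }
  w <- min(cfg$min_frequency, F_)

  for (iter in seq_len(cfg$max_iterations)) {
    model <- recenter(model, path)
    path <- viterbi_segment(X, model, cfg)
    # prune under-supported states (keep at least one)
    counts <- tabulate(path, nbins = nrow(model$centroids))
    if (nrow(model$centroids) > 1L && any(counts < cfg$min_frequency)) {
      keep <- counts >= cfg$min_frequency
      if (!any(keep)) keep <- seq_along(counts) == which.max(counts)
      model$centroids <- model$centroids[keep, , drop = FALSE]
      path <- viterbi_segment(X, model, cfg)
      model <- recenter(model, path)
      path <- viterbi_segment(X, model, cfg)
    }
    E <- .emission_cost(X, model)
    cost <- .path_cost(E, path, cfg$penalty)
    # propose: centroid of the worst-fitting window of w frames
    ec <- E[cbind(seq_len(F_), path)]
    win <- stats::filter(ec, rep(1 / w, w), sides = 1)
    t_end <- which.max(win[w:F_]) + w - 1L
    idx <- (t_end - w + 1L):t_end
    cand <- colMeans(X[idx, , drop = FALSE])
    trial <- model
    trial$centroids <- rbind(model$centroids, cand)
    trial_path <- viterbi_segment(X, trial, cfg)
    trial_counts <- tabulate(trial_path, nbins = nrow(trial$centroids))
    new_id <- nrow(trial$centroids)
    trial_cost <- .path_cost(.emission_cost(X, trial), trial_path,
                             cfg$penalty)
    if (trial_counts[new_id] >= cfg$min_frequency &&
        trial_cost < cost - 1e-9) {
      model <- trial
      path <- trial_path
    } else break
  }
  # final consolidation: recenter and enforce the support invariant
  model <- recenter(model, path)
  path <- viterbi_segment(X, model, cfg)
  counts <- tabulate(path, nbins = nrow(model$centroids))
  if (nrow(model$centroids) > 1L && any(counts < cfg$min_frequency)) {
    keep <- counts >= cfg$min_frequency
    if (!any(keep)) keep <- seq_along(counts) == which.max(counts)
    model$centroids <- model$centroids[keep, , drop = FALSE]
    path <- viterbi_segment(X, model, cfg)
  }
  list(model = model, path = path)
}

#' Label a segmented channel: background state and anomaly flags
#'
#' Computes each state's mean scalar reconstruction error, declares the most
#' frequent state the background (ties to the lower id), and flags frames
#' according to `policy`: `"non_background"` (default) flags every frame
#' whose state is not the background; `"error_ratio"` flags frames of states
#' whose mean scalar error exceeds `theta` times the background state's.
#'
#' @param path integer state-id sequence from [viterbi_segment()].
#' @param model the [hmm_model()] that produced it.
#' @param scalar_error per-frame scalar reconstruction error (length `F`).
#' @param policy anomaly binarization policy.
#' @param theta ratio threshold for `policy = "error_ratio"` (default 2).
#' @return object of class `state_track`: list with `states` (the path),
#'   `state_mean_error` (named by state id), `background_id`, `flags`
#'   (logical, length `F`), `policy`.
#' @export
label_track <- function(path, model, scalar_error,
                        policy = c("non_background", "error_ratio"),
                        theta = 2) {
  policy <- match.arg(policy)
  if (length(path) != length(scalar_error))
    stop("path and scalar_error lengths differ")
  K <- nrow(model$centroids)
  counts <- tabulate(path, nbins = K)
  background_id <- which.max(counts)  # ties -> lower id
  mean_err <- vapply(seq_len(K), function(k) {
    idx <- which(path == k)
    if (length(idx)) mean(scalar_error[idx]) else NA_real_
  }, numeric(1))
  flags <- if (policy == "non_background") {
    path != background_id
  } else {
    anom <- which(mean_err > theta * mean_err[background_id])
    path %in% anom
  }
  structure(list(states = as.integer(path),
                 state_mean_error = stats::setNames(mean_err, seq_len(K)),
                 background_id = as.integer(background_id),
                 flags = flags, policy = policy),
            class = "state_track")
}

#' @export
print.state_track <- function(x, ...) {
  cat(sprintf(
    "<state_track: %d frame(s), %d state(s), background %d, %d flagged>\n",
    length(x$states), length(x$state_mean_error), x$background_id,
    sum(x$flags)))
  invisible(x)
}
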