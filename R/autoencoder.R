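# Single-hidden-layer autoencoder trained per channel per recording. The
# bottleneck (64 units for a 256-bin spectrum) forces the network to learn a
# compact basis for the recording's dominant spectral patterns; frames the
# basis cannot reconstruct — rare high-amplitude discharges — leave a large
# reconstruction error, which is the anomaly signal passed downstream.

#' Autoencoder configuration
#'
#' A single-layer encoder and single-layer decoder with a leaky-rectifier
#' hidden activation (negative slope `alpha`) and a linear output, trained on
#' mean-squared reconstruction error at learning rate 0.001 for 25 epochs.
#' Weights are initialized uniformly in `±sqrt(6 / (fan_in + fan_out))`
#' under `seed`; biases start at zero.
#'
#' @param input_dim input/output width (256 spectral bins).
#' @param hidden_dim bottleneck width (64, a quarter of the input).
#' @param alpha negative slope of the leaky rectifier (0.01).
#' @param learning_rate step size (0.001).
#' @param epochs training passes over the frames (25).
#' @param seed integer RNG seed for weight initialization.
#' @param batch_size frames per gradient step; `NULL` = full batch. Default
#'   16, a small-minibatch regime that lets 25 epochs at this learning rate
#'   actually converge on a few hundred frames.
#' @param optimizer `"adam"` (default; the convention at lr 0.001) or
#'   `"gd"` for plain gradient descent.
#' @param normalize_input scale frames by the channel's peak magnitude before
#'   training (default TRUE); errors are reported back on the original scale.
#' @return object of class `ae_config`.
#' @export
ae_config <- function(input_dim = 256L, hidden_dim = 64L, alpha = 0.01,
                      learning_rate = 0.001, epochs = 25L, seed = 1L,
                      batch_size = 16L, optimizer = c("adam", "gd"),
                      normalize_input = TRUE) {
  input_dim <- as.integer(input_dim); hidden_dim <- as.integer(hidden_dim)
  if (hidden_dim >= input_dim) stop("hidden_dim must be < input_dim")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(input_dim = input_dim, hidden_dim = hidden_dim,
                 alpha = alpha, learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 optimizer = match.arg(optimizer),
                 normalize_input = isTRUE(normalize_input)),
            class = "ae_config")
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Initialize an autoencoder model
#'
#' @param cfg an [ae_config()].
#' @return object of class `ae_model`: encoder weights `W1`
#'   (hidden x input) and bias `b1`, decoder weights `W2` (input x hidden)
#'   and bias `b2`, the config, an empty `loss_trace`, and `scale = 1`.
#' @export
ae_init <- function(cfg = ae_config()) {
  stopifnot(inherits(cfg, "ae_config"))
  lim <- sqrt(6 / (cfg$input_dim + cfg$hidden_dim))
  with_seed(cfg$seed, {
    W1 <- matrix(stats::runif(cfg$hidden_dim * cfg$input_dim, -lim, lim),
                 cfg$hidden_dim, cfg$input_dim)
    W2 <- matrix(stats::runif(cfg$input_dim * cfg$hidden_dim, -lim, lim),
                 cfg$input_dim, cfg$hidden_dim)
    structure(list(W1 = W1, b1 = numeric(cfg$hidden_dim),
                   W2 = W2, b2 = numeric(cfg$input_dim),
                   cfg = cfg, loss_trace = numeric(0), scale = 1),
              class = "ae_model")
  })
}

.ae_forward <- function(model, X) {
  Z <- sweep(X %*% t(model$W1), 2L, model$b1, `+`)
  H <- ifelse(Z > 0, Z, model$cfg$alpha * Z)
  Xhat <- sweep(H %*% t(model$W2), 2L, model$b2, `+`)
  list(Z = Z, H = H, Xhat = Xhat)
}

#' Train an autoencoder on one channel's frame matrix
#'
#' Minimizes mean squared reconstruction error for exactly `cfg$epochs`
#' passes; the leaky rectifier acts on the hidden layer only, the decoder
#' output is linear. The per-epoch mean loss (on the full frame matrix,
#' after that epoch's updates) is recorded in `loss_trace`. Training is
#' deterministic: batches are consecutive row blocks, no shuffling.
#'
#' @param model an [ae_init()] model.
#' @param frames numeric matrix `F x input_dim` of spectral magnitudes.
#' @return the trained `ae_model` (with `scale` set when
#'   `cfg$normalize_input`).
#' @export
ae_train <- function(model, frames) {
  stopifnot(inherits(model, "ae_model"))
  frames <- as.matrix(frames)
  cfg <- model$cfg
  if (ncol(frames) != cfg$input_dim)
    stop("frame width (", ncol(frames), ") does not match input_dim (",
         cfg$input_dim, ")")
  F_ <- nrow(frames)
  if (F_ < 1L) stop("need at least one frame to train")
  if (cfg$normalize_input) {
    s <- max(abs(frames))
    model$scale <- if (s > 0) s else 1
  }
  X <- frames / model$scale
  bs <- if (is.null(cfg$batch_size)) F_ else min(cfg$batch_size, F_)
  batch_starts <- seq(1L, F_, by = bs)
  adam <- cfg$optimizer == "adam"
  if (adam) {
    mom <- lapply(list(model$W1, model$b1, model$W2, model$b2),
                  function(p) list(m = p * 0, v = p * 0))
    b1m <- 0.9; b2m <- 0.999; eps <- 1e-8; t_step <- 0L
  }
  loss_trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    for (s0 in batch_starts) {
      rows <- s0:min(s0 + bs - 1L, F_)
      Xb <- X[rows, , drop = FALSE]
      fw <- .ae_forward(model, Xb)
      n_el <- length(Xb)
      dXhat <- 2 * (fw$Xhat - Xb) / n_el
      gW2 <- t(dXhat) %*% fw$H
      gb2 <- colSums(dXhat)
      dH <- dXhat %*% model$W2
      dZ <- dH * ifelse(fw$Z > 0, 1, cfg$alpha)
      gW1 <- t(dZ) %*% Xb
      gb1 <- colSums(dZ)
      if (adam) {
        t_step <- t_step + 1L
        upd <- function(i, g) {
          mom[[i]]$m <<- b1m * mom[[i]]$m + (1 - b1m) * g
          mom[[i]]$v <<- b2m * mom[[i]]$v + (1 - b2m) * g * g
          mhat <- mom[[i]]$m / (1 - b1m^t_step)
          vhat <- mom[[i]]$v / (1 - b2m^t_step)
          cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        model$W1 <- model$W1 - upd(1L, gW1)
        model$b1 <- model$b1 - upd(2L, gb1)
        model$W2 <- model$W2 - upd(3L, gW2)
        model$b2 <- model$b2 - upd(4L, gb2)
      } else {
        lr <- cfg$learning_rate
        model$W1 <- model$W1 - lr * gW1
        model$b1 <- model$b1 - lr * gb1
        model$W2 <- model$W2 - lr * gW2
        model$b2 <- model$b2 - lr * gb2
      }
    }
    fw <- .ae_forward(model, X)
    loss <- mean((fw$Xhat - X)^2)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss at epoch ", epoch,
           "); consider normalize_input = TRUE or a smaller learning rate")
    loss_trace[epoch] <- loss
  }
  model$loss_trace <- loss_trace
  model
}

#' Per-frame reconstruction error
#'
#' Runs frames through the trained autoencoder and returns the element-wise
#' absolute difference between input and reconstruction, on the original
#' (pre-normalization) scale, plus the per-frame scalar error (mean over the
#' spectral bins).
#'
#' @param model a trained `ae_model`.
#' @param frames numeric matrix `F x input_dim`.
#' @return object of class `error_frames`: list with `errors`
#'   (`F x input_dim`, non-negative) and `scalar` (length `F`).
#' @export
ae_error <- function(model, frames) {
  stopifnot(inherits(model, "ae_model"))
  frames <- as.matrix(frames)
  if (ncol(frames) != model$cfg$input_dim)
    stop("frame width (", ncol(frames), ") does not match input_dim (",
         model$cfg$input_dim, ")")
  X <- frames / model$scale
  fw <- .ae_forward(model, X)
  err <- abs(X - fw$Xhat) * model$scale
  structure(list(errors = err, scalar = rowMeans(err)),
            class = "error_frames")
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf("<ae_model: %d -> %d -> %d, %s>\n", x$cfg$input_dim,
              x$cfg$hidden_dim, x$cfg$input_dim,
              if (length(x$loss_trace))
                sprintf("trained %d epochs, final loss %.3g",
                        length(x$loss_trace), utils::tail(x$loss_trace, 1))
              else "untrained"))
  invisible(x)
}

#' Save / load an autoencoder model as JSON
#'
#' Plain-text serialization of weights, biases, config, normalization scale
#' and loss trace, for reproducibility audits.
#'
#' @param model an `ae_model`.
#' @param path file path.
#' @return `path` (save) or the restored `ae_model` (load).
#' @export
ae_save <- function(model, path) {
  stopifnot(inherits(model, "ae_model"))
  obj <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              cfg = unclass(model$cfg), loss_trace = model$loss_trace,
              scale = model$scale)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname ae_save
#' @export
ae_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$cfg
  cfg$batch_size <- if (is.null(cfg$batch_size)) NULL else cfg$batch_size
  cfg <- do.call(ae_config, cfg)
  structure(list(W1 = matrix(obj$W1, cfg$hidden_dim, cfg$input_dim),
                 b1 = as.numeric(obj$b1),
                 W2 = matrix(obj$W2, cfg$input_dim, cfg$hidden_dim),
                 b2 = as.numeric(obj$b2),
                 cfg = cfg, loss_trace = as.numeric(obj$loss_trace),
                 scale = as.numeric(obj$scale)),
            class = "ae_model")
}
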