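#' Logistic sigmoid
#'
#' `sigmoid(a) = 1 / (1 + exp(-a))`, applied elementwise. Monotone increasing
#' with range (0, 1); saturates (to 0 or 1 in floating point) for large `|a|`.
#'
#' @param a numeric scalar, vector or matrix.
#' @return object of the same shape with values in (0, 1).
#' @export
sigmoid <- function(a) 1 / (1 + exp(-a))

#' Masking corruption
#'
#' Sets each entry of `x` to zero independently with probability `fraction`
#' (the denoising autoencoder's input corruption). With `seed` given the mask
#' is reproducible and the caller's RNG state is left untouched; with
#' `seed = NULL` the current RNG stream is consumed.
#'
#' @param x numeric vector or matrix.
#' @param fraction corruption probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return corrupted copy of `x`.
#' @export
corrupt <- function(x, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop_param("fraction must be in [0, 1]")
  if (fraction == 0) return(x)
  mask <- if (is.null(seed)) stats::runif(length(x)) >= fraction
          else with_seed(seed, stats::runif(length(x)) >= fraction)
  x * mask
}

new_dae <- function(W, b, W_dec, b_dec, trained = FALSE) {
  stopifnot(nrow(W) == ncol(W_dec), ncol(W) == nrow(W_dec),
            length(b) == nrow(W), length(b_dec) == nrow(W_dec),
            all(is.finite(W)), all(is.finite(W_dec)))
  structure(list(W = W, b = b, W_dec = W_dec, b_dec = b_dec,
                 trained = trained),
            class = "dae")
}

init_dae <- function(input_dim, hidden) {
  r_enc <- 4 * sqrt(6 / (input_dim + hidden))
  W <- matrix(stats::runif(hidden * input_dim, -r_enc, r_enc), hidden, input_dim)
  W_dec <- matrix(stats::runif(hidden * input_dim, -r_enc, r_enc), input_dim, hidden)
  new_dae(W, rep(0, hidden), W_dec, rep(0, input_dim))
}

#' @export
print.dae <- function(x, ...) {
  cat("denoising autoencoder: ", ncol(x$W), " -> ", nrow(x$W), " -> ",
      nrow(x$W_dec), if (isTRUE(x$trained)) " (trained)" else " (untrained)",
      "\n", sep = "")
  if (!is.null(x$final_mse)) cat("  clean-input reconstruction mse: ",
                                 format(x$final_mse, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Encoder forward pass
#'
#' Hidden activations `Y = sigmoid(W x + b)`, one column per time sample.
#'
#' @param ae a `dae` (from [train_autoencoder()] or internal init).
#' @param x input matrix (input_dim x samples) or vector.
#' @return hidden activation matrix (hidden x samples), entries in (0, 1).
#' @export
encode <- function(ae, x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(ae$W))
    stop_param("input dimension ", nrow(x), " does not match encoder (",
               ncol(ae$W), ")")
  sigmoid(ae$W %*% x + ae$b)
}

#' Decoder forward pass
#'
#' Reconstruction `Z = sigmoid(W' y + b')`.
#'
#' @param ae a `dae`.
#' @param y hidden activation matrix (hidden x samples) or vector.
#' @return reconstruction matrix (input_dim x samples), entries in (0, 1).
#' @export
decode <- function(ae, y) {
  y <- as.matrix(y)
  if (nrow(y) != ncol(ae$W_dec))
    stop_param("hidden dimension ", nrow(y), " does not match decoder (",
               ncol(ae$W_dec), ")")
  sigmoid(ae$W_dec %*% y + ae$b_dec)
}

#' Training configuration for denoising autoencoders
#'
#' Defaults follow the reference configuration for one-minute EEG segments:
#' corruption probability 0.5, learning rate 1, minibatch 200, 8 epochs.
#'
#' @param corruption_fraction per-entry masking probability in \[0, 1\].
#' @param learning_rate SGD step size (>= 0; 0 makes training a no-op).
#' @param minibatch minibatch size (positive integer).
#' @param epochs number of passes over the data (positive integer).
#' @param seed integer seed controlling weight initialisation, shuffling and
#'   corruption masks; fixed seed gives bit-identical training runs.
#' @return a `train_config` list.
#' @export
train_config <- function(corruption_fraction = 0.5, learning_rate = 1,
                         minibatch = 200, epochs = 8, seed = 1L) {
  if (corruption_fraction < 0 || corruption_fraction > 1)
    stop_param("corruption_fraction must be in [0, 1]")
  if (learning_rate < 0) stop_param("learning_rate must be >= 0")
  if (minibatch < 1 || epochs < 1) stop_param("minibatch and epochs must be >= 1")
  structure(list(corruption_fraction = corruption_fraction,
                 learning_rate = learning_rate,
                 minibatch = as.integer(minibatch),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

# clean-input reconstruction mse (grand mean over entries)
dae_clean_mse <- function(ae, x) mean((x - decode(ae, encode(ae, x)))^2)

#' Train one denoising autoencoder
#'
#' Minibatch stochastic gradient descent on the squared reconstruction error
#' between the clean input and the reconstruction of a masking-corrupted copy.
#' Per minibatch: `X1 = corrupt(X)`, `Y = sigmoid(W X1 + b)`,
#' `Z = sigmoid(W' Y + b')`, loss `mean over samples of sum_i (x_i - z_i)^2`,
#' plain SGD updates on `W, b, W', b'` (untied decoder weights). Weight
#' initialisation is uniform in `+/- 4 sqrt(6 / (fan_in + fan_out))`.
#'
#' @param x input matrix (channels x samples), scaled to \[0, 1\].
#' @param hidden number of hidden units (>= 1). Values >= the input dimension
#'   are allowed but warned about (no longer a bottleneck).
#' @param cfg a [train_config()].
#' @return a trained `dae` with extra fields `final_mse` (clean-input grand
#'   mean squared error), `channel_mse` (per-channel time-averaged squared
#'   error), and `loss_history` (clean-input mse at epoch 0..epochs).
#' @export
train_autoencoder <- function(x, hidden, cfg = train_config()) {
  x <- as.matrix(x)
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
    stop_param("input must be scaled to [0, 1]; see stack_train")
  if (hidden < 1) stop_param("hidden must be >= 1")
  if (hidden >= nrow(x))
    warning("hidden (", hidden, ") >= input dimension (", nrow(x),
            "): no longer a bottleneck", call. = FALSE)
  nsmp <- ncol(x)
  bs <- min(cfg$minibatch, nsmp)
  with_seed(cfg$seed, {
    ae <- init_dae(nrow(x), as.integer(hidden))
    history <- dae_clean_mse(ae, x)
    lr <- cfg$learning_rate
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nsmp)
      for (start in seq(1, nsmp, by = bs)) {
        idx <- ord[start:min(start + bs - 1, nsmp)]
        xb <- x[, idx, drop = FALSE]
        x1 <- corrupt(xb, cfg$corruption_fraction)
        y <- sigmoid(ae$W %*% x1 + ae$b)
        z <- sigmoid(ae$W_dec %*% y + ae$b_dec)
        if (lr > 0) {
          B <- length(idx)
          dz <- (2 / B) * (z - xb) * z * (1 - z)
          dy <- crossprod(ae$W_dec, dz) * y * (1 - y)
          ae$W_dec <- ae$W_dec - lr * tcrossprod(dz, y)
          ae$b_dec <- ae$b_dec - lr * rowSums(dz)
          ae$W <- ae$W - lr * tcrossprod(dy, x1)
          ae$b <- ae$b - lr * rowSums(dy)
        }
      }
      history <- c(history, dae_clean_mse(ae, x))
    }
    z_final <- decode(ae, encode(ae, x))
    ae$trained <- TRUE
    ae$final_mse <- mean((x - z_final)^2)
    ae$channel_mse <- rowMeans((x - z_final)^2)
    ae$loss_history <- history
    ae
  })
}

#' Greedy two-stage stacked denoising autoencoder
#'
#' Trains the first autoencoder on the min-max-scaled input, then feeds its
#' clean hidden output to a second autoencoder (corruption re-applied at the
#' second stage's input) -- the standard greedy layer-wise recipe. The deepest
#' hidden layer (m units) is the extracted feature space.
#'
#' @param x input matrix (channels x samples), raw scale; a per-channel
#'   min-max scaler to \[0, 1\] is fit and stored on the model.
#' @param n hidden units of stage 1 (`m <= n`; `n < channels` for a
#'   bottleneck, larger values are warned about by [train_autoencoder()]).
#' @param m hidden units of stage 2.
#' @param cfg a [train_config()]; stage 2 uses a seed derived from `cfg$seed`.
#' @return an `sdae_model`: `stages` (two `dae`s), `n`, `m`, `scaler`
#'   (per-channel `lo`/`hi`), reconstruction summaries `err1` (sum over
#'   channels of time-averaged squared input error) and `err2` (same over the
#'   n stage-1 units), and `cfg`.
#' @export
stack_train <- function(x, n, m, cfg = train_config()) {
  x <- as.matrix(x)
  if (m > n) stop_param("m (", m, ") must be <= n (", n, ")")
  if (m < 1) stop_param("m must be >= 1")
  lo <- apply(x, 1, min); hi <- apply(x, 1, max)
  span <- hi - lo
  flat <- span <= 0
  span[flat] <- 1
  xs <- (x - lo) / span
  xs[flat, ] <- 0.5                       # constant channels sit mid-range
  ae1 <- train_autoencoder(xs, n, cfg)
  y1 <- encode(ae1, xs)
  cfg2 <- cfg
  cfg2$seed <- child_seed(cfg$seed, 2L)
  ae2 <- train_autoencoder(y1, m, cfg2)
  y1_hat <- decode(ae2, encode(ae2, y1))
  z1 <- decode(ae1, y1)
  structure(list(
    stages = list(ae1, ae2), n = as.integer(n), m = as.integer(m),
    scaler = list(lo = lo, hi = hi, span = span, flat = flat),
    err1 = sum(rowMeans((xs - z1)^2)),
    err2 = sum(rowMeans((y1 - y1_hat)^2)),
    cfg = cfg),
    class = "sdae_model")
}

#' @export
print.sdae_model <- function(x, ...) {
  cat("stacked denoising autoencoder: ", length(x$scaler$lo), " -> ", x$n,
      " -> ", x$m, "\n  reconstruction error (stage 1 / stage 2): ",
      format(x$err1, digits = 5), " / ", format(x$err2, digits = 5), "\n",
      sep = "")
  invisible(x)
}

sdae_scale <- function(model, x) {
  xs <- (x - model$scaler$lo) / model$scaler$span
  if (any(model$scaler$flat)) xs[model$scaler$flat, ] <- 0.5
  xs
}

#' Extract the per-area denoised feature series
#'
#' Runs the input through both encoders and averages the m deepest hidden
#' series into a single feature time series (one value per sample).
#'
#' @param model a trained `sdae_model` from [stack_train()].
#' @param x input matrix with the same channel count the model was trained on.
#' @return numeric vector of length `ncol(x)`.
#' @export
extract_feature <- function(model, x) {
  if (!inherits(model, "sdae_model") || !isTRUE(model$stages[[1]]$trained))
    stop("extract_feature requires a trained sdae_model", call. = FALSE)
  x <- as.matrix(x)
  if (nrow(x) != length(model$scaler$lo))
    stop_param("channel count ", nrow(x), " does not match training (",
               length(model$scaler$lo), ")")
  y2 <- encode(model$stages[[2]], encode(model$stages[[1]], sdae_scale(model, x)))
  colMeans(y2)
}

#' Save / load a stacked model as JSON
#'
#' Weights, biases, scaler and configuration are written as one JSON document
#' (full double precision), portable across platforms.
#'
#' @param model an `sdae_model`.
#' @param path file path (`.json`).
#' @return `path` (save) or the restored `sdae_model` (load).
#' @export
save_sdae <- function(model, path) {
  stopifnot(inherits(model, "sdae_model"))
  ser_dae <- function(ae) list(W = ae$W, b = ae$b, W_dec = ae$W_dec,
                               b_dec = ae$b_dec, final_mse = ae$final_mse,
                               channel_mse = ae$channel_mse,
                               loss_history = ae$loss_history)
  jsonlite::write_json(
    list(n = model$n, m = model$m, err1 = model$err1, err2 = model$err2,
         scaler = model$scaler, cfg = unclass(model$cfg),
         stage1 = ser_dae(model$stages[[1]]),
         stage2 = ser_dae(model$stages[[2]])),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_sdae
#' @export
load_sdae <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_dae <- function(s) {
    ae <- new_dae(as.matrix(s$W), as.numeric(s$b), as.matrix(s$W_dec),
                  as.numeric(s$b_dec), trained = TRUE)
    ae$final_mse <- s$final_mse
    ae$channel_mse <- as.numeric(s$channel_mse)
    ae$loss_history <- as.numeric(s$loss_history)
    ae
  }
  cfg <- do.call(train_config, as.list(j$cfg))
  structure(list(
    stages = list(de_dae(j$stage1), de_dae(j$stage2)),
    n = as.integer(j$n), m = as.integer(j$m),
    scaler = list(lo = as.numeric(j$scaler$lo), hi = as.numeric(j$scaler$hi),
                  span = as.numeric(j$scaler$span),
                  flat = as.logical(j$scaler$flat)),
    err1 = j$err1, err2 = j$err2, cfg = cfg),
    class = "sdae_model")
}
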