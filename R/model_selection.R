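#' Short-time Fourier transform (magnitude spectrogram)
#'
#' Hann-windowed framed FFT magnitudes. Frames start at
#' `1, 1 + hop, 1 + 2 hop, ...`, so the frame count is
#' `floor((length(x) - window_len) / hop) + 1`.
#'
#' @param x numeric time series.
#' @param fs sampling rate in Hz.
#' @param window_len window length in samples (default 1 s); must not exceed
#'   `length(x)`.
#' @param hop hop size in samples (default 50% of the window).
#' @return an `stft_gram`: `coeffs` (frequency bins x frames, nonnegative
#'   magnitudes), `freqs` (Hz per bin up to Nyquist), `q` (frame count),
#'   `window_len`, `hop`, and the window vector `w`.
#' @export
stft <- function(x, fs, window_len = round(fs), hop = max(1, window_len %/% 2)) {
  n <- length(x)
  window_len <- as.integer(window_len); hop <- as.integer(hop)
  if (window_len < 2) stop_param("window_len must be >= 2")
  if (window_len > n)
    stop_param("window_len (", window_len, ") exceeds signal length (", n, ")")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, window_len - 1) / (window_len - 1))
  starts <- seq(1L, n - window_len + 1L, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + window_len - 1L)] * w,
                   numeric(window_len))
  nf <- window_len %/% 2L + 1L
  coeffs <- Mod(stats::mvfft(frames))[seq_len(nf), , drop = FALSE]
  structure(list(coeffs = coeffs,
                 freqs = (seq_len(nf) - 1) * fs / window_len,
                 q = length(starts), window_len = window_len, hop = hop, w = w),
            class = "stft_gram")
}

#' Min-max normalised time-summed STFT scores
#'
#' For each frequency bin `i` at or below `freq_ceiling`, sums the magnitude
#' coefficients over the `q` time frames and min-max normalises across those
#' `d` bins: the smallest time sum maps to 0, the largest to 1. When all time
#' sums are equal (zero spectral contrast) every score is defined as 0.
#'
#' @param gram an [stft()] result.
#' @param freq_ceiling top of the analysis band in Hz (default 20 Hz); at
#'   least 2 bins must fall at or below it.
#' @return numeric vector of `d` scores in \[0, 1\], named by bin frequency.
#' @export
normalize_cstft <- function(gram, freq_ceiling = 20) {
  sel <- gram$freqs <= freq_ceiling
  if (sum(sel) < 2)
    stop_param("need >= 2 STFT bins at or below ", freq_ceiling, " Hz")
  s <- rowSums(gram$coeffs[sel, , drop = FALSE])
  rng <- range(s)
  out <- if (rng[2] - rng[1] <= 0) rep(0, length(s))
         else (s - rng[1]) / (rng[2] - rng[1])
  names(out) <- format(gram$freqs[sel], trim = TRUE)
  out
}

#' Model-selection score c_f
#'
#' Balances autoencoder fidelity against low-frequency spectral contrast of
#' the extracted feature:
#' `c_f = lambda * exp(-(e1 + e2) / (2c)) + (1 - lambda) * sum_j cbar_j^3`,
#' where `e1` is the stage-1 reconstruction error (time-averaged squared
#' error summed over the c input channels), `e2` the stage-2 error (summed
#' over the n stage-1 units), and `cbar` the min-max normalised time-summed
#' STFT scores of the extracted feature below the frequency ceiling. Cubing
#' rewards a few dominant bins over uniform energy. Bounds:
#' `0 <= c_f <= lambda + (1 - lambda) * d`.
#'
#' @param recon_err_1 stage-1 reconstruction error (sum over channels of
#'   time-mean squared error).
#' @param recon_err_2 stage-2 reconstruction error (sum over the n units).
#' @param cscores normalised scores from [normalize_cstft()], each in \[0, 1\].
#' @param lambda weight in \[0, 1\] on the reconstruction term.
#' @param c input channel count (the `2c` scaling of the exponent).
#' @return scalar c_f score.
#' @export
compute_cf <- function(recon_err_1, recon_err_2, cscores, lambda, c) {
  if (lambda < 0 || lambda > 1) stop_param("lambda must be in [0, 1]")
  if (any(cscores < -1e-12 | cscores > 1 + 1e-12))
    stop_param("cscores must lie in [0, 1]")
  if (!all(is.finite(c(recon_err_1, recon_err_2)))) stop_param("errors must be finite")
  lambda * exp(-(recon_err_1 + recon_err_2) / (2 * c)) +
    (1 - lambda) * sum(cscores^3)
}

#' Selection configuration for the (n, m) grid
#'
#' Defaults follow the reference operating point: `U_def = 30`, `C_def = 15`,
#' `C_com = 5`, `lambda = 0.2`, and a 20 Hz frequency ceiling. `C_def` must
#' stay below the input channel count so every admissible stage-1 width is a
#' bottleneck.
#'
#' @param U_def cap on the product `m * n` (positive integer).
#' @param C_def exclusive upper bound on `n` (positive integer).
#' @param C_com exclusive upper bound on `m` (positive integer).
#' @param lambda weight in \[0, 1\] for [compute_cf()].
#' @param freq_ceiling analysis-band top in Hz.
#' @return a `selection_config` list.
#' @export
selection_config <- function(U_def = 30, C_def = 15, C_com = 5,
                             lambda = 0.2, freq_ceiling = 20) {
  if (U_def < 1 || C_def < 1 || C_com < 1)
    stop_param("U_def, C_def, C_com must be positive integers")
  if (lambda < 0 || lambda > 1) stop_param("lambda must be in [0, 1]")
  structure(list(U_def = as.integer(U_def), C_def = as.integer(C_def),
                 C_com = as.integer(C_com), lambda = lambda,
                 freq_ceiling = freq_ceiling),
            class = "selection_config")
}

#' Admissible (n, m) hidden-size pairs
#'
#' Enumerates every integer pair satisfying `1 <= m < C_com`, `m <= n < C_def`
#' and `m * n <= U_def`. The product constraint is read as an upper bound so
#' that the reference pair (n = 8, m = 3) is admissible under the default
#' constants.
#'
#' @param cfg a [selection_config()].
#' @return data frame with integer columns `n`, `m`, ordered by `n` then `m`.
#' @export
admissible_pairs <- function(cfg = selection_config()) {
  grid <- expand.grid(m = seq_len(max(cfg$C_com - 1L, 0L)),
                      n = seq_len(max(cfg$C_def - 1L, 0L)))
  grid <- grid[grid$m <= grid$n & grid$m * grid$n <= cfg$U_def, c("n", "m")]
  if (nrow(grid) == 0)
    stop_param("admissible (n, m) set is empty under this configuration")
  grid <- grid[order(grid$n, grid$m), ]
  rownames(grid) <- NULL
  grid
}

#' Grid search over hidden-layer sizes by c_f
#'
#' Trains one stacked denoising autoencoder per admissible `(n, m)` pair
#' (all with the same seed), extracts the per-area feature, computes its STFT
#' (1 s Hann window, 50% hop) and scores each pair with [compute_cf()]. The
#' pair with the highest c_f wins; ties break toward smaller `m`, then
#' smaller `n`.
#'
#' @param x area channel matrix (channels x samples); the channel count must
#'   exceed `cfg$C_def`.
#' @param fs sampling rate of `x` in Hz.
#' @param cfg a [selection_config()].
#' @param tcfg a [train_config()].
#' @return a `selection_result`: `grid` (data frame `n`, `m`, `err1`, `err2`,
#'   `stft_term`, `cf`), `chosen` (named vector `n`, `m`), and `models = NULL`
#'   (models are retrained on demand to keep the object light).
#' @export
grid_search <- function(x, fs, cfg = selection_config(), tcfg = train_config()) {
  x <- as.matrix(x)
  if (nrow(x) <= cfg$C_def)
    stop_param("channel count (", nrow(x), ") must exceed C_def (", cfg$C_def, ")")
  pairs <- admissible_pairs(cfg)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    n <- pairs$n[i]; m <- pairs$m[i]
    model <- tryCatch(stack_train(x, n, m, tcfg), error = function(e)
      stop("grid_search failed at (n=", n, ", m=", m, "): ",
           conditionMessage(e), call. = FALSE))
    feat <- extract_feature(model, x)
    cs <- normalize_cstft(stft(feat, fs), cfg$freq_ceiling)
    stft_term <- sum(cs^3)
    data.frame(n = n, m = m, err1 = model$err1, err2 = model$err2,
               stft_term = stft_term,
               cf = compute_cf(model$err1, model$err2, cs, cfg$lambda, nrow(x)))
  })
  grid <- do.call(rbind, res)
  best <- which(grid$cf == max(grid$cf))
  best <- best[order(grid$m[best], grid$n[best])][1]
  structure(list(grid = grid,
                 chosen = c(n = grid$n[best], m = grid$m[best]),
                 cfg = cfg, tcfg = tcfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("c_f grid search over ", nrow(x$grid), " admissible (n, m) pairs\n",
      "  chosen: n = ", x$chosen["n"], ", m = ", x$chosen["m"],
      " (c_f = ", format(max(x$grid$cf), digits = 5), ")\n", sep = "")
  invisible(x)
}

#' Export a selection grid as CSV
#'
#' @param result a [grid_search()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_grid <- function(result, path) {
  utils::write.csv(result$grid, path, row.names = FALSE)
  invisible(path)
}

#' Heat-map of the c_f selection grid
#'
#' @param result a [grid_search()] result.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the matrix displayed (n by m, NA where inadmissible).
#' @export
plot_cf_grid <- function(result, ...) {
  g <- result$grid
  ns <- sort(unique(g$n)); ms <- sort(unique(g$m))
  z <- matrix(NA_real_, length(ns), length(ms), dimnames = list(ns, ms))
  z[cbind(match(g$n, ns), match(g$m, ms))] <- g$cf
  graphics::image(ns, ms, z, xlab = "n (stage-1 units)",
                  ylab = "m (stage-2 units)", main = "c_f", ...)
  invisible(z)
}
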