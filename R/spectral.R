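#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments (default 2 s, 50%
#' overlap), one-sided density normalised so that `sum(power) * df`
#' approximates the time-domain variance (Parseval).
#'
#' @param x numeric time series.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default `round(2 * fs)`); the
#'   series must hold at least one segment.
#' @param overlap fractional segment overlap in \[0, 1) (default 0.5).
#' @return a `power_spectrum`: `freqs` (Hz, strictly increasing), `power`
#'   (nonnegative, one-sided density in input-units^2 / Hz), `df` (bin width).
#' @export
power_spectrum <- function(x, fs, seg_len = round(2 * fs), overlap = 0.5) {
  if (length(x) < seg_len)
    stop_param("signal shorter (", length(x), ") than one segment (", seg_len, ")")
  hop <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  gram <- stft(x, fs, window_len = seg_len, hop = hop)
  scale <- fs * sum(gram$w^2)
  power <- rowMeans(gram$coeffs^2) / scale
  nf <- length(power)
  # one-sided doubling: all interior bins; Nyquist bin only exists for even L
  dbl <- seq(2L, if (gram$window_len %% 2L == 0L) nf - 1L else nf)
  power[dbl] <- 2 * power[dbl]
  structure(list(freqs = gram$freqs, power = power, df = fs / gram$window_len),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("power_spectrum: ", length(x$freqs), " bins, 0-",
      max(x$freqs), " Hz (df = ", format(x$df, digits = 4), " Hz)\n", sep = "")
  invisible(x)
}

band_bins <- function(freqs, band) {
  bands <- if (inherits(band, "band_spec")) list(band) else band
  sel <- rep(FALSE, length(freqs))
  for (b in bands) {
    if (!inherits(b, "band_spec")) stop_param("band must be band_spec or a list of them")
    sel <- sel | (freqs >= b$lo & freqs <= b$hi)
  }
  sel
}

#' Ratio of first-primary-frequency power to average in-band power (RPFA)
#'
#' The "first primary frequency" is the in-band bin of maximal power; RPFA is
#' that maximum divided by the mean power over the in-band bins, a peakiness /
#' signal-to-noise proxy that is always >= 1 and invariant to overall signal
#' gain. Condition-specific band unions are supported (e.g. alpha + beta for
#' awake recordings, delta + theta for fatigue), evaluated over the pooled
#' bin set.
#'
#' @param ps a [power_spectrum()].
#' @param band a [band_spec()] or a list of them (band union).
#' @return scalar RPFA >= 1.
#' @export
rpfa <- function(ps, band) {
  sel <- band_bins(ps$freqs, band)
  if (!any(sel)) stop_param("band contains no spectral bins")
  p <- ps$power[sel]
  if (all(p <= 0)) stop_param("all-zero in-band power: RPFA undefined")
  max(p) / mean(p)
}

#' PCA baseline feature extractor
#'
#' Projects the channel matrix onto its top-k principal axes (channel
#' covariance, centered, unscaled) and averages the k projection series into
#' one comparison feature, mirroring the stacked-autoencoder feature's
#' construction.
#'
#' @param x channel matrix (channels x samples).
#' @param k number of components (`1 <= k <= channels`).
#' @return list: `series` (k x samples projections, ordered by decreasing
#'   variance), `explained_variance` (length k), `feature` (mean of the k
#'   series), `rotation` (channels x k loadings).
#' @export
pca_extract <- function(x, k) {
  x <- as.matrix(x)
  if (k < 1 || k > nrow(x))
    stop_param("k must be in 1..channels (", nrow(x), ")")
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  series <- t(pr$x[, seq_len(k), drop = FALSE])
  list(series = series,
       explained_variance = pr$sdev[seq_len(k)]^2,
       feature = colMeans(series),
       rotation = pr$rotation[, seq_len(k), drop = FALSE])
}

#' Paired two-sided t-test
#'
#' Classical paired t on the differences `a - b`. Degenerate inputs
#' (zero-variance differences) are reported explicitly rather than erroring:
#' identical vectors give `t = 0, p = 1`; a constant nonzero difference gives
#' an infinite `t` with `p = 0`.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list: `t`, `df`, `p`, `mean_diff`, `degenerate` (logical).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop_param("a and b must have equal length")
  if (length(a) < 2) stop_param("need at least 2 paired observations")
  d <- a - b
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                df = length(d) - 1L,
                p = if (md == 0) 1 else 0,
                mean_diff = md, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate), degenerate = FALSE)
}

#' RPFA comparison table for one recording
#'
#' Computes RPFA per area for three extractors on the same area matrix: the
#' plain channel average ("original"), the PCA baseline (k = m components),
#' and the stacked-autoencoder feature.
#'
#' @param rec an [eeg_recording()] with areas attached.
#' @param models named list of trained `sdae_model`s, one per area.
#' @param band a [band_spec()] or list of them (condition-specific band union).
#' @return data frame with columns `area`, `method`, `rpfa`.
#' @export
rpfa_table <- function(rec, models, band) {
  if (is.null(rec$areas)) stop_param("recording has no area map")
  rows <- lapply(names(rec$areas), function(a) {
    x <- area_matrix(rec, a)
    model <- models[[a]]
    feats <- list(
      original = colMeans(x),
      pca = pca_extract(x, model$m)$feature,
      sdae = extract_feature(model, x))
    data.frame(area = a, method = names(feats),
               rpfa = vapply(feats, function(f)
                 rpfa(power_spectrum(f, rec$fs), band), numeric(1)),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
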