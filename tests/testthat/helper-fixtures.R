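# fixtures are built in code; nothing is read from disk

# recording on a rows x cols grid montage with given data generator
grid_recording <- function(rows, cols, n_samples, fs = 100,
                           fill = function(nch, n) matrix(stats::rnorm(nch * n), nch, n),
                           seed = 1) {
  g <- make_grid_montage(rows, cols)
  nch <- rows * cols
  data <- eegsdae:::with_seed(seed, fill(nch, n_samples))
  eeg_recording(data, fs = fs, labels = g$labels, montage = g$montage)
}

# brute-force per-sample surface Laplacian (independent oracle)
laplacian_oracle <- function(rec) {
  out <- rec$data
  for (ch in rec$labels) {
    nb <- rec$montage[[ch]]
    if (is.null(nb) || identical(nb, "incomplete")) next
    for (t in seq_len(ncol(out)))
      out[ch, t] <- rec$data[ch, t] -
        (rec$data[nb[1], t] + rec$data[nb[2], t] +
           rec$data[nb[3], t] + rec$data[nb[4], t]) / 4
  }
  out
}

# small, fast synthetic spec for pipeline-level tests
small_synth_spec <- function(seed = 1, duration = 30, ...) {
  synthetic_spec(duration = duration, seed = seed, ...)
}

rms <- function(x) sqrt(mean(x^2))

# central portion of a filtered signal, away from filtfilt edge transients
mid <- function(x, frac = 0.8) {
  n <- length(x)
  lo <- ceiling(n * (1 - frac) / 2)
  x[lo:(n - lo)]
}
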