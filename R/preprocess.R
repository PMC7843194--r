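#' Band-pass and notch filter a recording
#'
#' Applies a zero-phase Butterworth band-pass (order 4, forward-backward) and
#' a zero-phase Butterworth band-stop notch (order 2) to every channel.
#' Typical mains-noise suppression for 1200 Hz EEG uses a 0.5-100 Hz pass band
#' with a 48-52 Hz notch. Zero-phase application means no group delay, at the
#' price of doubled filter order.
#'
#' @param rec an [eeg_recording()].
#' @param band a [band_spec()]; `band$hi` must be below the Nyquist rate.
#'   If `band$lo <= 0` a low-pass is used instead of a band-pass.
#' @param notch_lo,notch_hi notch edges in Hz; set either to `NULL` to skip
#'   the notch. Must lie inside the pass band.
#' @return a filtered [eeg_recording()] of identical shape.
#' @export
bandpass_notch <- function(rec, band = band_spec("custom", 0.5, 100),
                           notch_lo = 48, notch_hi = 52) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (band$hi >= nyq)
    stop_param("band hi (", band$hi, " Hz) must be below Nyquist (", nyq, " Hz)")
  do_notch <- !is.null(notch_lo) && !is.null(notch_hi)
  if (do_notch && !(notch_lo > band$lo && notch_hi < band$hi))
    stop_param("notch interval must lie inside the pass band")

  bp <- if (band$lo > 0) {
    signal::butter(4, c(band$lo, band$hi) / nyq, type = "pass")
  } else {
    signal::butter(4, band$hi / nyq, type = "low")
  }
  ns <- if (do_notch) signal::butter(2, c(notch_lo, notch_hi) / nyq,
                                     type = "stop")
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- signal::filtfilt(bp, out[i, ])
    if (do_notch) x <- signal::filtfilt(ns, x)
    out[i, ] <- x
  }
  rec$data <- out
  rec$meta$filtered <- list(band = unclass(band), notch = if (do_notch)
    c(notch_lo, notch_hi))
  rec
}

#' Surface Laplacian spatial filter
#'
#' Sharpens the spatial resolution of scalp recordings by subtracting, at each
#' sample, the mean of a channel's four symmetric neighbours from the channel
#' itself: `V_C = V_CO - (V1 + V2 + V3 + V4) / 4`. Channels whose montage
#' entry is `"incomplete"` (or missing) are passed through unchanged and
#' flagged in `meta$laplacian_complete`.
#'
#' The operator is linear and annihilates spatially constant fields on all
#' complete-montage channels.
#'
#' @param rec an [eeg_recording()] with a montage attached.
#' @return an [eeg_recording()]; `meta$laplacian_complete` is a named logical
#'   vector marking which channels were filtered.
#' @export
surface_laplacian <- function(rec) {
  validate_recording(rec)
  if (is.null(rec$montage))
    stop("surface_laplacian requires a montage; attach one first", call. = FALSE)
  out <- rec$data
  complete <- stats::setNames(rep(FALSE, length(rec$labels)), rec$labels)
  for (ch in rec$labels) {
    nb <- rec$montage[[ch]]
    if (is.null(nb) || identical(nb, "incomplete")) next
    complete[ch] <- TRUE
    out[ch, ] <- rec$data[ch, ] -
      (rec$data[nb[1], ] + rec$data[nb[2], ] +
         rec$data[nb[3], ] + rec$data[nb[4], ]) / 4
  }
  rec$data <- out
  rec$meta$laplacian_complete <- complete
  rec
}

#' Decimate a recording to a lower sampling rate
#'
#' Anti-alias filters (8th-order Chebyshev type I low-pass, zero phase) and
#' downsamples each channel by an integer factor. Intended to bring 1200 Hz
#' recordings down to a working rate (default pipeline target 120 Hz) once
#' all content of interest sits well below the new Nyquist rate; the target
#' must keep at least a 20 Hz analysis band, i.e. `target_fs / 2 > 20`.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate in Hz; `fs / target_fs` must be a
#'   positive integer.
#' @return an [eeg_recording()] at the new rate.
#' @export
decimate_recording <- function(rec, target_fs) {
  validate_recording(rec)
  if (target_fs / 2 <= 20)
    stop_param("target_fs/2 must exceed the 20 Hz analysis band")
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop_param("fs/target_fs must be a positive integer, got ", q)
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  n_out <- length(signal::decimate(rec$data[1, ], q))
  out <- matrix(0, nrow(rec$data), n_out, dimnames = list(rec$labels, NULL))
  for (i in seq_len(nrow(out))) out[i, ] <- signal::decimate(rec$data[i, ], q)
  rec$data <- out
  rec$fs <- rec$fs / q
  rec
}
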