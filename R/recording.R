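#' Multichannel EEG recording container
#'
#' An `eeg_recording` bundles a channels-by-samples numeric matrix with its
#' sampling rate, channel labels, an optional four-neighbour montage map and
#' an optional grouping of channels into brain areas. The montage drives the
#' surface Laplacian ([surface_laplacian()]); the area map drives per-area
#' feature extraction and connectivity.
#'
#' @param data numeric matrix, channels x samples (microvolt-scale values).
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of channel identifiers, one per row of
#'   `data`. Defaults to the rownames of `data` or `"ch1"`, `"ch2"`, ...
#' @param montage named list mapping a channel label to either a character
#'   vector of exactly four neighbour labels or the string `"incomplete"` for
#'   channels without a full symmetric neighbour set. May be `NULL`.
#' @param areas named list mapping an area identifier to a character vector of
#'   channel labels; lists must be disjoint. May be `NULL`.
#' @param meta free-form list of provenance metadata.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = NULL, montage = NULL,
                          areas = NULL, meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) {
    labels <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  }
  rownames(data) <- labels
  rec <- structure(
    list(data = data, fs = as.numeric(fs), labels = as.character(labels),
         montage = montage, areas = areas, meta = meta),
    class = "eeg_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate an `eeg_recording`
#'
#' Checks the container invariants: equal-length channels with at least one
#' sample, a positive sampling rate, montage neighbours that resolve to known
#' channel labels, and disjoint area lists.
#'
#' @param rec an [eeg_recording()].
#' @return `rec`, invisibly; errors if an invariant is violated.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stop_param("not an eeg_recording")
  if (!is.matrix(rec$data) || !is.numeric(rec$data))
    stop_param("data must be a numeric matrix")
  if (ncol(rec$data) < 1L) stop_param("every channel needs at least 1 sample")
  if (!is.finite(rec$fs) || rec$fs <= 0) stop_param("fs must be > 0")
  if (length(rec$labels) != nrow(rec$data))
    stop_param("labels length must equal channel count")
  if (anyDuplicated(rec$labels)) stop_param("channel labels must be unique")
  if (!is.null(rec$montage)) {
    bad <- setdiff(names(rec$montage), rec$labels)
    if (length(bad))
      stop_param("montage keys not in labels: ", paste(bad, collapse = ", "))
    for (ch in names(rec$montage)) {
      nb <- rec$montage[[ch]]
      if (identical(nb, "incomplete")) next
      if (length(nb) != 4L)
        stop_param("montage for ", ch, " must list 4 neighbours or 'incomplete'")
      miss <- setdiff(nb, rec$labels)
      if (length(miss))
        stop_param("montage neighbour(s) of ", ch, " not in labels: ",
                   paste(miss, collapse = ", "))
    }
  }
  if (!is.null(rec$areas)) {
    all_ch <- unlist(rec$areas, use.names = FALSE)
    if (anyDuplicated(all_ch)) stop_param("area channel lists must be disjoint")
    miss <- setdiff(all_ch, rec$labels)
    if (length(miss))
      stop_param("area channel(s) not in labels: ", paste(miss, collapse = ", "))
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("eeg_recording: ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2), " s)\n",
      sep = "")
  if (!is.null(x$montage)) {
    ncomp <- sum(vapply(x$montage, function(nb) !identical(nb, "incomplete"),
                        logical(1)))
    cat("  montage: ", length(x$montage), " channels mapped, ", ncomp,
        " with complete 4-neighbour sets\n", sep = "")
  }
  if (!is.null(x$areas))
    cat("  areas: ", paste(names(x$areas), vapply(x$areas, length, 1L),
                           sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract the channel matrix of one area
#'
#' @param rec an [eeg_recording()] with an area map attached.
#' @param area area identifier (name in `rec$areas`).
#' @return numeric matrix (area channels x samples).
#' @export
area_matrix <- function(rec, area) {
  if (is.null(rec$areas)) stop_param("recording has no area map attached")
  area <- as.character(area)
  if (!area %in% names(rec$areas)) stop_param("unknown area: ", area)
  rec$data[rec$areas[[area]], , drop = FALSE]
}

#' Frequency band specification
#'
#' The classical EEG rhythms are available as presets: delta 0.5-4 Hz,
#' theta 4-7 Hz, alpha 8-13 Hz, beta 13-30 Hz.
#'
#' @param name band name; one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"custom"`.
#' @param lo,hi band edges in Hz (`0 <= lo < hi`). Preset names fill these in
#'   when omitted.
#' @return object of class `band_spec` with fields `name`, `lo`, `hi`.
#' @export
#' @examples
#' band_spec("alpha")
#' band_spec("custom", 0.5, 100)
band_spec <- function(name = "custom", lo = NULL, hi = NULL) {
  presets <- list(delta = c(0.5, 4), theta = c(4, 7),
                  alpha = c(8, 13), beta = c(13, 30))
  name <- match.arg(name, c(names(presets), "custom"))
  if (name != "custom" && (is.null(lo) || is.null(hi))) {
    lo <- lo %||% presets[[name]][1]
    hi <- hi %||% presets[[name]][2]
  }
  if (is.null(lo) || is.null(hi)) stop_param("custom band needs lo and hi")
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!(lo >= 0 && lo < hi)) stop_param("band requires 0 <= lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat("band_spec ", x$name, ": ", x$lo, "-", x$hi, " Hz\n", sep = "")
  invisible(x)
}
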