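# Minimal EDF/EDF+ support: fixed-width ASCII header + little-endian int16
# data records. Only continuous recordings with one common sampling rate are
# handled; annotation channels are not parsed.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Read an EDF/EDF+ file
#'
#' Parses the European Data Format header and signal records into an
#' [eeg_recording()]. All signals must share one sampling rate (equal samples
#' per data record); annotation channels ("EDF Annotations") are dropped.
#' Montage and area grouping are not part of EDF and stay `NULL` until
#' attached from configuration.
#'
#' @param path path to a readable EDF/EDF+ file.
#' @return an [eeg_recording()] with `data`, `fs` and `labels` populated.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_param("cannot read EDF file: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop_param("not an EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))

  rd(8)                                   # version
  rd(80); rd(80)                          # patient, recording id
  rd(8); rd(8)                            # start date, time
  header_bytes <- num(rd(8))
  rd(44)                                  # reserved
  n_records <- num(rd(8))
  record_dur <- num(rd(8))
  ns <- as.integer(num(rd(4)))
  if (is.na(ns) || ns < 1) stop_param("EDF format error: bad signal count")
  if (sz < header_bytes) stop_param("EDF format error: truncated signal headers")

  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- trimws(fld(16))
  fld(80)                                 # transducer
  fld(8)                                  # physical dimension
  phys_min <- as.numeric(trimws(fld(8)))
  phys_max <- as.numeric(trimws(fld(8)))
  dig_min <- as.numeric(trimws(fld(8)))
  dig_max <- as.numeric(trimws(fld(8)))
  fld(80)                                 # prefiltering
  nsamp <- as.integer(trimws(fld(8)))
  fld(32)                                 # reserved

  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop_param("EDF file contains no signal channels: ", path)
  if (length(unique(nsamp[keep])) != 1L)
    stop_param("EDF format error: channels of unequal length per record")
  if (!is.finite(record_dur) || record_dur <= 0)
    stop_param("EDF format error: bad record duration")
  fs <- nsamp[keep][1] / record_dur

  if (n_records < 0) {                    # unknown: infer from file size
    rec_bytes <- sum(nsamp) * 2
    n_records <- floor((sz - header_bytes) / rec_bytes)
  }
  total <- n_records * sum(nsamp)
  raw_vals <- readBin(con, "integer", n = total, size = 2,
                      signed = TRUE, endian = "little")
  if (length(raw_vals) < total)
    stop_param("EDF format error: data records truncated")

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  gain[!is.finite(gain)] <- 1
  offset <- phys_min - gain * dig_min

  data <- matrix(0, nrow = sum(keep), ncol = n_records * nsamp[keep][1])
  idx <- 0L
  starts <- cumsum(c(0L, nsamp))[seq_len(ns)]     # per-signal offset in record
  rec_len <- sum(nsamp)
  out_row <- 0L
  for (s in seq_len(ns)) {
    if (!keep[s]) next
    out_row <- out_row + 1L
    cols <- as.vector(outer(seq_len(nsamp[s]), (seq_len(n_records) - 1L) * rec_len,
                            `+`) + starts[s])
    data[out_row, ] <- gain[s] * raw_vals[cols] + offset[s]
  }
  eeg_recording(data, fs = fs, labels = labels[keep],
                meta = list(source = path, format = "edf"))
}

#' Write an EDF file
#'
#' Serialises a recording as a single-record EDF file with 16-bit samples.
#' Physical ranges are set per channel from the data extremes, so the
#' round-trip error is bounded by the 16-bit quantisation step.
#'
#' @param rec an [eeg_recording()]; `fs * n_samples / fs` must be expressible,
#'   i.e. any positive `fs` is accepted.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  validate_recording(rec)
  nch <- nrow(rec$data); nsmp <- ncol(rec$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(edf_pad(x, w)), con)

  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (nch + 1), 8)
  wr("", 44)
  wr(1, 8)                                 # one data record
  wr(format(nsmp / rec$fs, digits = 7), 8) # record duration in seconds
  wr(nch, 4)

  pmin <- apply(rec$data, 1, min); pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  fmt8 <- function(v) vapply(v, function(z) edf_pad(formatC(z, digits = 6,
                                                            format = "g"), 8),
                             character(1))
  for (lab in rec$labels) wr(lab, 16)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (v in fmt8(pmin)) writeBin(charToRaw(v), con)
  for (v in fmt8(pmax)) writeBin(charToRaw(v), con)
  for (i in seq_len(nch)) wr(-32768, 8)
  for (i in seq_len(nch)) wr(32767, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(nsmp, 8)
  for (i in seq_len(nch)) wr("", 32)

  for (i in seq_len(nch)) {
    g <- (pmax[i] - pmin[i]) / 65535
    dig <- as.integer(round((rec$data[i, ] - pmin[i]) / g) - 32768)
    dig <- pmin(pmax(dig, -32768L), 32767L)
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Write a recording as a portable text container
#'
#' Two files are produced: `<prefix>_data.tsv` (channels x samples, one row
#' per channel, full double precision) and `<prefix>_meta.json` holding the
#' sampling rate, labels, montage, areas and metadata.
#'
#' @param rec an [eeg_recording()].
#' @param prefix path prefix for the two output files.
#' @return character vector of the two paths, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  validate_recording(rec)
  dpath <- paste0(prefix, "_data.tsv")
  mpath <- paste0(prefix, "_meta.json")
  dir.create(dirname(dpath), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(format(rec$data, digits = 17, trim = TRUE),
                     dpath, sep = "\t", quote = FALSE,
                     row.names = rec$labels, col.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, labels = rec$labels, montage = rec$montage,
         areas = rec$areas, meta = rec$meta),
    mpath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(dpath, mpath))
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix path prefix used at write time.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(prefix) {
  dpath <- paste0(prefix, "_data.tsv")
  mpath <- paste0(prefix, "_meta.json")
  if (!file.exists(dpath) || !file.exists(mpath))
    stop_param("recording container not found at prefix: ", prefix)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  tab <- utils::read.table(dpath, sep = "\t", row.names = 1)
  montage <- meta$montage
  if (!is.null(montage)) montage <- lapply(montage, as.character)
  areas <- meta$areas
  if (!is.null(areas)) areas <- lapply(areas, as.character)
  eeg_recording(as.matrix(tab), fs = meta$fs, labels = meta$labels,
                montage = montage, areas = areas,
                meta = as.list(meta$meta %||% list()))
}
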