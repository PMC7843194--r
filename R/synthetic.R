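#' Regular-grid montage builder
#'
#' Lays channels on a `rows x cols` grid (row-major labels `"R<r>C<c>"`).
#' Interior channels receive their four orthogonal neighbours (up, down,
#' left, right -- symmetric in pairs about the centre); border channels are
#' flagged `"incomplete"`.
#'
#' @param rows,cols grid dimensions (`rows, cols >= 1`; interior channels
#'   exist only when both are >= 3).
#' @return list: `montage` (named list as used by [eeg_recording()]),
#'   `labels` (row-major channel order), `rows`, `cols`.
#' @export
make_grid_montage <- function(rows, cols) {
  lab <- function(r, c) sprintf("R%dC%d", r, c)
  labels <- as.vector(t(outer(seq_len(rows), seq_len(cols), lab)))
  montage <- vector("list", rows * cols)
  names(montage) <- labels
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    montage[[lab(r, c)]] <-
      if (r > 1 && r < rows && c > 1 && c < cols)
        c(lab(r - 1, c), lab(r + 1, c), lab(r, c - 1), lab(r, c + 1))
      else "incomplete"
  }
  list(montage = montage, labels = labels, rows = rows, cols = cols)
}

#' Specification of a synthetic multichannel EEG recording
#'
#' Describes ground-truthed pseudo-EEG: per-area band-limited rhythms
#' (narrowband-filtered noise, so spectra resemble real EEG rather than pure
#' tones) buried in low-frequency drift and broadband noise, with known
#' directed lag-coupling between area sources. Defaults emulate one minute of
#' a four-area recording at the 120 Hz working rate, with a directed chain
#' `1 -> 2 -> 3 -> 4` (lag 2 samples, gain 0.6).
#'
#' Each rhythm is a list `list(band =, center =, amplitude =)`; each coupling
#' edge a list `list(from =, to =, lag =, gain =)` acting on the latent area
#' sources. Channels receive their area's source through heterogeneous gains
#' (uniform on \[0.5, 1.5\]) plus an area-shared 0.2-0.5 Hz drift and
#' independent white noise.
#'
#' @param n_areas number of areas (default 4).
#' @param channels_per_area channels per area (default 9; laid out as a
#'   square-ish grid block per area).
#' @param fs sampling rate in Hz (default 120; must exceed twice the highest
#'   rhythm centre).
#' @param duration recording length in seconds (default 60).
#' @param rhythms per-area list of rhythm specs (length `n_areas`).
#' @param coupling list of directed lag-coupling edges (lags >= 1 sample).
#' @param noise list with `broadband_sd` (per-channel white noise SD) and
#'   `drift_amplitude` (SD of the shared 0.2-0.5 Hz drift).
#' @param seed integer seed; generation is fully reproducible.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_areas = 4, channels_per_area = 9, fs = 120,
                           duration = 60,
                           rhythms = NULL, coupling = NULL,
                           noise = list(broadband_sd = 1, drift_amplitude = 2),
                           seed = 1L) {
  if (is.null(rhythms)) {
    defaults <- list(
      list(band = band_spec("alpha"), center = 10,  amplitude = 1),
      list(band = band_spec("theta"), center = 6,   amplitude = 1),
      list(band = band_spec("alpha"), center = 11,  amplitude = 1),
      list(band = band_spec("theta"), center = 5,   amplitude = 1))
    rhythms <- rep(defaults, length.out = n_areas)
  }
  if (is.null(coupling)) {
    coupling <- if (n_areas >= 2)
      lapply(seq_len(n_areas - 1), function(i)
        list(from = i, to = i + 1, lag = 2L, gain = 0.6))
    else list()
  }
  if (length(rhythms) != n_areas) stop_param("need one rhythm spec per area")
  maxf <- max(vapply(rhythms, function(r) r$center, numeric(1)))
  if (fs <= 2 * maxf)
    stop_param("fs must exceed twice the highest rhythm frequency")
  for (e in coupling) {
    if (e$lag < 1) stop_param("coupling lags must be >= 1 sample")
    if (!is.finite(e$gain)) stop_param("coupling gains must be finite")
    if (e$from < 1 || e$from > n_areas || e$to < 1 || e$to > n_areas)
      stop_param("coupling area index out of range")
  }
  structure(list(n_areas = as.integer(n_areas),
                 channels_per_area = as.integer(channels_per_area),
                 fs = fs, duration = duration, rhythms = rhythms,
                 coupling = coupling, noise = noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# spectral radius of the companion matrix implied by the coupling edges
coupling_spectral_radius <- function(n_areas, coupling) {
  if (!length(coupling)) return(0)
  pmaxlag <- max(vapply(coupling, function(e) e$lag, numeric(1)))
  A <- array(0, dim = c(n_areas, n_areas, pmaxlag))
  for (e in coupling) A[e$to, e$from, e$lag] <- A[e$to, e$from, e$lag] + e$gain
  comp <- matrix(0, n_areas * pmaxlag, n_areas * pmaxlag)
  for (j in seq_len(pmaxlag))
    comp[seq_len(n_areas), (j - 1) * n_areas + seq_len(n_areas)] <- A[, , j]
  if (pmaxlag > 1)
    comp[n_areas + seq_len(n_areas * (pmaxlag - 1)),
         seq_len(n_areas * (pmaxlag - 1))] <- diag(n_areas * (pmaxlag - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# narrowband-filtered unit-variance noise around `center` (+/- 1 Hz)
narrowband_noise <- function(n, fs, center, sd_target) {
  half_bw <- 1
  lo <- max(center - half_bw, 0.1); hi <- min(center + half_bw, fs / 2 * 0.98)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 4 * fs))
  x <- x[(2 * fs + 1):(2 * fs + n)]       # drop filter edge transients
  x * sd_target / stats::sd(x)
}

#' Generate a ground-truthed synthetic recording
#'
#' Latent per-area sources are band-limited rhythms plus lagged contributions
#' from coupled areas (`s_to(t) += gain * s_from(t - lag)`); channels are
#' `gain_ch * s_area + drift_area + white noise`, arranged on one grid-montage
#' block per area so the surface Laplacian applies. Montage neighbourhoods
#' never span area boundaries: cross-area channel mixing would couple areas
#' that the ground-truth adjacency declares independent.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `recording` (an [eeg_recording()] with montage and areas
#'   attached), `adjacency` (logical ground truth, `adjacency[target, source]`
#'   to match [significance()]), `edges` (data frame `from`, `to`, `lag`,
#'   `gain`), `sources` (latent area sources, n_areas x samples).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rho <- coupling_spectral_radius(spec$n_areas, spec$coupling)
  if (rho >= 1)
    stop_param("unstable coupling: companion spectral radius ", round(rho, 3))
  n <- as.integer(round(spec$fs * spec$duration))
  na <- spec$n_areas; cpa <- spec$channels_per_area

  with_seed(spec$seed, {
    rhy <- matrix(0, na, n)
    for (i in seq_len(na)) {
      r <- spec$rhythms[[i]]
      rhy[i, ] <- narrowband_noise(n, spec$fs, r$center, r$amplitude)
    }
    # latent sources with lagged coupling
    s <- rhy
    if (length(spec$coupling)) {
      for (t in seq_len(n)) {
        for (e in spec$coupling) {
          if (t > e$lag) s[e$to, t] <- s[e$to, t] + e$gain * s[e$from, t - e$lag]
        }
      }
    }
    # shared per-area low-frequency drift (0.2-0.5 Hz)
    drift <- matrix(0, na, n)
    if (spec$noise$drift_amplitude > 0) {
      bf <- signal::butter(2, c(0.2, 0.5) / (spec$fs / 2), type = "pass")
      for (i in seq_len(na)) {
        d <- signal::filtfilt(bf, stats::rnorm(n + 8 * spec$fs))
        d <- d[(4 * spec$fs + 1):(4 * spec$fs + n)]
        drift[i, ] <- d * spec$noise$drift_amplitude / stats::sd(d)
      }
    }
    # montage: an independent block_r x block_c grid per area, so that
    # Laplacian neighbourhoods never span area boundaries (cross-area channel
    # mixing would couple areas the ground truth declares independent)
    block_r <- max(which(cpa %% seq_len(floor(sqrt(cpa))) == 0))
    block_c <- cpa %/% block_r
    block <- make_grid_montage(block_r, block_c)
    montage <- list()
    area_labels <- vector("list", na)
    for (a in seq_len(na)) {
      relabel <- stats::setNames(paste0("A", a, block$labels), block$labels)
      for (ch in block$labels) {
        nb <- block$montage[[ch]]
        montage[[relabel[[ch]]]] <-
          if (identical(nb, "incomplete")) "incomplete" else unname(relabel[nb])
      }
      area_labels[[a]] <- unname(relabel[block$labels])
    }
    grid <- list(montage = montage,
                 labels = unlist(area_labels),
                 block_labels = area_labels)
    areas <- stats::setNames(vector("list", na), paste0("area", seq_len(na)))
    data <- matrix(0, na * cpa, n)
    row_i <- 0L
    ordered_labels <- character(na * cpa)
    for (a in seq_len(na)) {
      block_labs <- grid$block_labels[[a]]
      areas[[a]] <- block_labs
      for (ch in block_labs) {
        row_i <- row_i + 1L
        g <- stats::runif(1, 0.5, 1.5)
        data[row_i, ] <- g * s[a, ] + drift[a, ] +
          stats::rnorm(n, sd = spec$noise$broadband_sd)
        ordered_labels[row_i] <- ch
      }
    }
    rec <- eeg_recording(data, fs = spec$fs, labels = ordered_labels,
                         montage = grid$montage, areas = areas,
                         meta = list(synthetic = TRUE, seed = spec$seed))
    adjacency <- matrix(FALSE, na, na,
                        dimnames = list(names(areas), names(areas)))
    edges <- data.frame(from = integer(), to = integer(),
                        lag = integer(), gain = numeric())
    for (e in spec$coupling) {
      adjacency[e$to, e$from] <- TRUE
      edges <- rbind(edges, data.frame(from = e$from, to = e$to,
                                       lag = e$lag, gain = e$gain))
    }
    list(recording = rec, adjacency = adjacency, edges = edges,
         sources = s)
  })
}
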