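## Synthetic-data generators: evoked dipole fields at controlled SNR,
## oscillatory ERD/ERS epochs, empty-room noise, and a fixture atlas.
##
## SNR convention used throughout: SNR = RMS of the noiseless sensor signal
## (over all channels and samples of the simulated record) divided by the
## standard deviation of the additive white noise.

rms <- function(x) sqrt(mean(x^2))

#' Add white noise at a target signal-to-noise ratio
#'
#' Adds i.i.d. Gaussian noise to every sample of `signal`, with standard
#' deviation `RMS(signal) / snr` where the RMS is taken over all channels and
#' samples.  `snr = Inf` returns the signal unchanged.
#'
#' @param signal numeric matrix (channels x samples).
#' @param snr positive scalar or `Inf`.
#' @param seed optional integer seed.
#' @return Matrix of the same shape, with attribute `"noise_sd"`.
#' @export
add_noise <- function(signal, snr, seed = NULL) {
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("`snr` must be a positive scalar (or Inf)")
  if (is.infinite(snr)) {
    attr(signal, "noise_sd") <- 0
    return(signal)
  }
  s <- rms(signal)
  if (s == 0) stop("cannot set a finite SNR for an all-zero signal")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sd <- s / snr
  out <- signal + matrix(stats::rnorm(length(signal), sd = sd),
                         nrow(signal), ncol(signal))
  attr(out, "noise_sd") <- sd
  out
}

## Evoked source waveform: one-cycle raised-cosine burst,
## s(t) = A/2 (1 - cos(2 pi f (t - t0 + 1/(2f)))) on [t0 - 1/(2f), t0 + 1/(2f)]
## peaking at t0.  Defaults emulate an auditory evoked deflection.
raised_cosine_burst <- function(times, freq = 10, latency = 0.3,
                                amplitude = 20e-9) {
  half <- 1 / (2 * freq)
  w <- numeric(length(times))
  inside <- abs(times - latency) <= half
  w[inside] <- amplitude * 0.5 *
    (1 + cos(2 * pi * freq * (times[inside] - latency)))
  w
}

#' Simulate a trial-averaged evoked field from point dipoles
#'
#' The noiseless sensor record is the outer product of the dipole lead field
#' and a source waveform (default: one-cycle 10 Hz raised-cosine burst of
#' 20 nA m peaking at 300 ms); white noise is then added at the requested SNR
#' (see [add_noise()]).  Multiple sources superpose.  A ground-truth record
#' (locations, orientations, waveform, peak latency, noise SD) is attached so
#' localization error can be scored with no other state.
#'
#' @param head,array geometry.
#' @param location matrix (k x 3) or 3-vector of source positions, metres.
#' @param orientation matching unit moment orientation(s).
#' @param snr positive scalar or `Inf`.
#' @param seed integer seed for the noise.
#' @param fs sampling rate, Hz.
#' @param window simulated time span in seconds, default `c(0, 0.6)`.
#' @param waveform list with `freq`, `latency` (s), `amplitude` (A m);
#'   partial lists are completed with defaults.
#' @return An `evoked` object: `data` (channels x samples, T/m), `times`,
#'   `fs`, `channel_names`, `n_trials_averaged`, plus a `truth` field.
#' @export
simulate_evoked <- function(head, array, location, orientation,
                            snr = Inf, seed = NULL, fs = 1000,
                            window = c(0, 0.6),
                            waveform = list()) {
  wf <- utils::modifyList(list(freq = 10, latency = 0.3, amplitude = 20e-9),
                          waveform)
  loc <- if (is.null(dim(location))) matrix(as.numeric(location), ncol = 3)
         else as.matrix(location)
  ori <- if (is.null(dim(orientation))) matrix(as.numeric(orientation), ncol = 3)
         else as.matrix(orientation)
  if (nrow(loc) != nrow(ori)) stop("one orientation per location required")
  times <- seq(window[1], window[2], by = 1 / fs)
  s <- raised_cosine_burst(times, wf$freq, wf$latency, 1)
  clean <- matrix(0, n_channels(array), length(times))
  for (k in seq_len(nrow(loc))) {
    check_inside(head, loc[k, ])
    g <- as.numeric(dipole_leadfield(head, array, loc[k, ]) %*%
                      (wf$amplitude * ori[k, ] / sqrt(sum(ori[k, ]^2))))
    clean <- clean + outer(g, s)
  }
  noisy <- add_noise(clean, snr, seed)
  evoked(data = noisy, fs = fs, times = times,
         channel_names = array$channel_names,
         n_trials_averaged = 1L,
         truth = list(location = loc, orientation = ori, waveform = wf,
                      peak_latency = wf$latency, snr = snr,
                      noise_sd = attr(noisy, "noise_sd"), seed = seed))
}

#' Simulate epochs with an event-related power change (ERD/ERS)
#'
#' Each trial carries a band-limited oscillation at the source (white noise
#' band-pass filtered to `band`, independent phase per trial) whose amplitude
#' is scaled by `sqrt(1 + power_change)` inside the active window; the trial
#' average therefore tends to zero and the effect is invisible to
#' evoked-field methods but visible to the DICS beamformer.  Sensor-level
#' white noise is added at `snr` (RMS convention, see [add_noise()]).
#'
#' @param head,array geometry; `location`, `orientation` a single source.
#' @param band `c(f_lo, f_hi)` Hz, inside (0, Nyquist).
#' @param power_change fractional power change in the active window
#'   (> -1); negative = ERD, positive = ERS, 0 = null.
#' @param n_trials number of epochs (>= 1).
#' @param snr sensor-level SNR (RMS of noiseless signal / noise SD).
#' @param fs sampling rate; `window` epoch span (s, relative to stimulus);
#'   `baseline_win`/`active_win` the two analysis windows.
#' @param amplitude source RMS amplitude in the baseline state, A m.
#' @param seed integer seed.
#' @return An `epochs` object with a `truth` field recording the windows and
#'   the sign of the change.
#' @export
simulate_erd_epochs <- function(head, array, location, orientation,
                                band = c(8, 12), power_change = -0.5,
                                n_trials = 30L, snr = 1,
                                fs = 600, window = c(-1, 1),
                                baseline_win = c(-0.5, -0.1),
                                active_win = c(0.25, 0.65),
                                amplitude = 20e-9, seed = NULL) {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop("`band` must satisfy 0 < f_lo < f_hi < Nyquist")
  if (power_change <= -1) stop("`power_change` must be > -1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  check_inside(head, location)
  times <- seq(window[1], window[2], by = 1 / fs)
  nt <- length(times)
  g <- as.numeric(dipole_leadfield(head, array, as.numeric(location)) %*%
                    (as.numeric(orientation) / sqrt(sum(as.numeric(orientation)^2))))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  gain <- rep(1, nt)
  gain[times >= active_win[1] & times <= active_win[2]] <-
    sqrt(1 + power_change)
  clean <- array(0, c(n_trials, length(g), nt))
  for (tr in seq_len(n_trials)) {
    src <- as.numeric(signal::filtfilt(bf, stats::rnorm(nt)))
    src <- amplitude * src / rms(src) * gain
    clean[tr, , ] <- outer(g, src)
  }
  sd_noise <- if (is.infinite(snr)) 0 else rms(clean) / snr
  data <- clean + array(stats::rnorm(length(clean), sd = sd_noise), dim(clean))
  epochs(data = data, fs = fs, times = times,
         channel_names = array$channel_names,
         truth = list(location = as.numeric(location),
                      orientation = as.numeric(orientation),
                      band = band, power_change = power_change,
                      baseline_win = baseline_win, active_win = active_win,
                      direction = if (power_change < 0) "ERD" else "ERS",
                      noise_sd = sd_noise, seed = seed))
}

#' Simulate an empty-room noise recording
#'
#' I.i.d. Gaussian channel noise used to estimate the sensor noise
#' covariance.  With fewer samples than channels the sample covariance is
#' rank deficient; a warning is issued and the result flagged.
#'
#' @param array sensor array; `n_samples` record length; `noise_sd` channel
#'   noise SD (T/m); `seed` integer; `fs` nominal sampling rate.
#' @return Object of class `raw_noise`: `data` (channels x samples),
#'   `fs`, `channel_names`, `noise_sd`, `rank_deficient`.
#' @export
simulate_empty_room <- function(array, n_samples, noise_sd = 1e-12,
                                seed = NULL, fs = 1000) {
  nch <- n_channels(array)
  rank_def <- n_samples < nch
  if (rank_def)
    warning("fewer samples than channels: sample covariance will be rank deficient")
  if (!is.null(seed)) set.seed(as.integer(seed))
  structure(list(data = matrix(stats::rnorm(nch * n_samples, sd = noise_sd),
                               nch, n_samples),
                 fs = fs, channel_names = array$channel_names,
                 noise_sd = noise_sd, rank_deficient = rank_def),
            class = "raw_noise")
}

#' Synthetic ROI atlas over a source grid
#'
#' Partitions the grid into `2 * n_rois_per_hemisphere` regions by a Voronoi
#' tessellation around ROI seed points drawn at random in the left hemisphere
#' and mirrored exactly across the sagittal midplane, so left/right ROI
#' geometry is symmetric.  A symmetric subset of ROIs in each hemisphere is
#' flagged as "language" regions.  This is a synthetic stand-in for a real
#' parcellation (e.g. a volumetric brain atlas): it reproduces the structure
#' the laterality machinery needs (labels, hemispheres, language flags,
#' centroids), not anatomy.
#'
#' @param grid a [source_grid()] (must have points in both hemispheres).
#' @param n_rois_per_hemisphere number of ROIs per side.
#' @param language_fraction fraction of ROIs per hemisphere flagged as
#'   language-specific (at least one).
#' @param seed integer seed.
#' @return Object of class `atlas`: `table` (data.frame point, roi,
#'   hemisphere, is_language), `rois` (data.frame roi, hemisphere,
#'   is_language, cx, cy, cz with centroid coordinates in metres).
#' @export
make_fixture_atlas <- function(grid, n_rois_per_hemisphere = 20L,
                               language_fraction = 0.4, seed = 1L) {
  pts <- grid$points
  xrel <- pts[, 1] - grid$head$center[1]
  left <- which(xrel < 0)
  right <- which(xrel > 0)
  if (!length(left) || !length(right))
    stop("grid must contain points in both hemispheres")
  nr <- as.integer(n_rois_per_hemisphere)
  if (nr < 1 || nr > length(left))
    stop("`n_rois_per_hemisphere` must be between 1 and the number of points per hemisphere")
  set.seed(as.integer(seed))
  seeds_l <- pts[sample(left, nr), , drop = FALSE]
  seeds_r <- seeds_l
  seeds_r[, 1] <- 2 * grid$head$center[1] - seeds_r[, 1]   # mirror in x

  assign_side <- function(idx, seeds) {
    p <- pts[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(seeds^2), `+`) - 2 * p %*% t(seeds)
    max.col(-d2, ties.method = "first")
  }
  roi <- integer(nrow(pts))
  roi[left] <- assign_side(left, seeds_l)
  roi[right] <- nr + assign_side(right, seeds_r)
  hemi <- ifelse(xrel < 0, "L", "R")
  n_lang <- max(1L, round(language_fraction * nr))
  lang_ids <- sample(nr, n_lang)            # same ids both sides: symmetric
  is_lang_roi <- c(seq_len(nr) %in% lang_ids, seq_len(nr) %in% lang_ids)

  roi_label <- sprintf("%s%02d", rep(c("L", "R"), each = nr),
                       c(seq_len(nr), seq_len(nr)))
  tab <- data.frame(point = seq_len(nrow(pts)), roi = roi_label[roi],
                    hemisphere = hemi, is_language = is_lang_roi[roi],
                    stringsAsFactors = FALSE)
  cent <- t(vapply(seq_len(2L * nr), function(r) {
    colMeans(pts[roi == r, , drop = FALSE])
  }, numeric(3)))
  rois <- data.frame(roi = roi_label, hemisphere = rep(c("L", "R"), each = nr),
                     is_language = is_lang_roi,
                     cx = cent[, 1], cy = cent[, 2], cz = cent[, 3],
                     stringsAsFactors = FALSE)
  structure(list(table = tab, rois = rois, n_points = nrow(pts)),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("Synthetic atlas: %d points, %d ROIs (%d language-flagged)\n",
              x$n_points, nrow(x$rois), sum(x$rois$is_language)))
  invisible(x)
}

#' Write / read an atlas as TSV
#'
#' The per-point table carries columns point_index, roi_label, hemisphere and
#' is_language_roi; ROI centroids are recomputed on read from a grid.
#' @param atlas an `atlas`; `path` file path; `grid` the generating grid.
#' @export
write_atlas_tsv <- function(atlas, path) {
  tab <- atlas$table
  names(tab) <- c("point_index", "roi_label", "hemisphere", "is_language_roi")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path, grid) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("point_index", "roi_label", "hemisphere", "is_language_roi")
  if (!all(need %in% names(tab)))
    stop("atlas TSV must have columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$point_index), ]
  rl <- unique(tab$roi_label)
  cent <- t(vapply(rl, function(r) {
    colMeans(grid$points[tab$point_index[tab$roi_label == r], , drop = FALSE])
  }, numeric(3)))
  rois <- data.frame(roi = rl,
                     hemisphere = tab$hemisphere[match(rl, tab$roi_label)],
                     is_language = tab$is_language_roi[match(rl, tab$roi_label)],
                     cx = cent[, 1], cy = cent[, 2], cz = cent[, 3],
                     stringsAsFactors = FALSE)
  structure(list(table = data.frame(point = tab$point_index,
                                    roi = tab$roi_label,
                                    hemisphere = tab$hemisphere,
                                    is_language = tab$is_language_roi,
                                    stringsAsFactors = FALSE),
                 rois = rois, n_points = nrow(tab)),
            class = "atlas")
}
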