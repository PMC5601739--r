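#' Preprocessing parameters
#'
#' Parameters of the spectral processing chain. Defaults follow the
#' standard serum-profiling workflow: 5-point moving-average smoothing,
#' S/N cut-off 5.0 for peak detection, a 100 Th local mass window for
#' baseline and noise estimation, and a 0.1% relative tolerance for
#' cross-sample peak alignment.
#'
#' @param smooth_window Odd moving-average width in points (>= 1).
#' @param snr_cutoff Signal-to-noise cut-off for peak detection (> 0).
#' @param baseline_mass_window Local mass window (Th) for baseline and
#'   noise estimation.
#' @param align_tol_rel Relative m/z tolerance for alignment, in (0, 0.01].
#' @param mz_min,mz_max Acquisition range; points outside are cropped.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(smooth_window = 5, snr_cutoff = 5,
                              baseline_mass_window = 100,
                              align_tol_rel = 0.001,
                              mz_min = 1000, mz_max = 10000) {
  if (smooth_window < 1 || smooth_window %% 2 != 1) {
    stop("smooth_window must be an odd integer >= 1", call. = FALSE)
  }
  if (snr_cutoff <= 0) stop("snr_cutoff must be positive", call. = FALSE)
  if (baseline_mass_window <= 0) {
    stop("baseline_mass_window must be positive", call. = FALSE)
  }
  if (align_tol_rel <= 0 || align_tol_rel > 0.01) {
    stop("align_tol_rel must be in (0, 0.01]", call. = FALSE)
  }
  if (mz_min >= mz_max) stop("need mz_min < mz_max", call. = FALSE)
  structure(list(smooth_window = as.integer(smooth_window),
                 snr_cutoff = snr_cutoff,
                 baseline_mass_window = baseline_mass_window,
                 align_tol_rel = align_tol_rel,
                 mz_min = mz_min, mz_max = mz_max),
            class = "preprocess_params")
}

#' Moving-average smoothing
#'
#' Replaces each intensity by the mean over a centered window of
#' `window` points. Windows are truncated (shrunk) at the spectrum edges,
#' so no data are invented at the boundaries and a constant spectrum is
#' left unchanged. The operation is linear in the intensities.
#'
#' @param s A [spectrum()].
#' @param window Odd window width in points.
#' @return The smoothed spectrum.
#' @examples
#' s <- spectrum(1:5, c(0, 0, 10, 0, 0))
#' smooth_spectrum(s, 5)$intensity  # c(10/3, 10/4, 2, 10/4, 10/3)
#' @export
smooth_spectrum <- function(s, window = 5) {
  stopifnot(inherits(s, "spectrum"))
  if (window < 1 || window %% 2 != 1) {
    stop("smoothing window must be an odd integer >= 1", call. = FALSE)
  }
  n <- length(s$mz)
  if (window > n) stop("smoothing window exceeds spectrum length", call. = FALSE)
  if (window > 1) {
    h <- (window - 1L) %/% 2L
    cs <- cumsum(c(0, s$intensity))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    s$intensity <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  log_step(s, sprintf("smooth(window=%d)", window))
}

# strict local maxima; plateaus resolved to their leftmost point
local_maxima <- function(y) {
  dz <- diff(y)
  nz <- which(dz != 0)
  if (length(nz) < 2L) return(integer())
  sgn <- sign(dz[nz])
  turn <- which(sgn[-length(sgn)] == 1 & sgn[-1] == -1)
  nz[turn] + 1L
}

# window anchor index sequence covering [1, n] at roughly `width` Th spacing
window_breaks <- function(mz, width) {
  brk <- seq(mz[1], mz[length(mz)], by = width)
  if (tail(brk, 1) < mz[length(mz)]) brk <- c(brk, mz[length(mz)])
  brk
}

#' Estimate a spectrum baseline
#'
#' Locates the dominant local intensity maxima (prominent above 3x the
#' local robust noise), takes the minimum intensity between consecutive
#' dominant maxima as baseline anchors, adds the within-window minimum for
#' mass windows containing no dominant maximum, and linearly interpolates
#' the anchors over the full m/z grid (constant extrapolation at the
#' ends).
#'
#' @param s A (smoothed) [spectrum()].
#' @param mass_window Local mass window (Th).
#' @return Numeric baseline, same length as the spectrum, everywhere
#'   `<= max(intensity)`.
#' @export
estimate_baseline <- function(s, mass_window = 100) {
  stopifnot(inherits(s, "spectrum"))
  if (mass_window <= 0) stop("mass_window must be positive", call. = FALSE)
  mz <- s$mz; y <- s$intensity; n <- length(y)
  span <- mz[n] - mz[1]
  if (mass_window >= span) {
    warning("mass_window wider than the spectrum span; using a flat global-minimum baseline")
    return(rep(min(y), n))
  }
  brk <- window_breaks(mz, mass_window)
  win <- findInterval(mz, brk, rightmost.closed = TRUE)
  # local robust scale per window, for the dominance threshold
  med <- tapply(y, win, median)
  scale <- tapply(y, win, mad)
  maxima <- local_maxima(y)
  wkey <- as.character(win[maxima])
  dominant <- maxima[y[maxima] - med[wkey] > 3 * scale[wkey]]
  anchors <- integer()
  if (length(dominant) >= 2L) {
    for (k in seq_len(length(dominant) - 1L)) {
      seg <- dominant[k]:dominant[k + 1L]
      anchors <- c(anchors, seg[which.min(y[seg])])
    }
  }
  has_dom <- unique(win[dominant])
  for (w in setdiff(unique(win), has_dom)) {
    idx <- which(win == w)
    anchors <- c(anchors, idx[which.min(y[idx])])
  }
  anchors <- sort(unique(anchors))
  if (length(anchors) < 2L) return(rep(min(y), n))
  base <- approx(mz[anchors], y[anchors], xout = mz, rule = 2)$y
  pmin(base, max(y))
}

#' Subtract a baseline from a spectrum
#'
#' Intensities are clamped at zero: baseline subtraction never produces
#' negative values.
#'
#' @param s A [spectrum()].
#' @param baseline Numeric vector from [estimate_baseline()], same length.
#' @return The baseline-subtracted spectrum.
#' @export
subtract_baseline <- function(s, baseline) {
  stopifnot(inherits(s, "spectrum"))
  if (length(baseline) != length(s$mz)) {
    stop("baseline length must match the spectrum", call. = FALSE)
  }
  s$intensity <- pmax(s$intensity - baseline, 0)
  log_step(s, "subtract_baseline")
}

#' Estimate the local noise level
#'
#' Robust noise scale per local mass window: 1.4826 times the median
#' absolute deviation of the (baseline-subtracted) intensities within
#' half-overlapping windows, interpolated to every grid point.
#'
#' @param s A baseline-subtracted [spectrum()].
#' @param mass_window Local mass window (Th).
#' @return Numeric noise level per grid point (non-negative).
#' @export
estimate_noise <- function(s, mass_window = 100) {
  stopifnot(inherits(s, "spectrum"))
  if (mass_window <= 0) stop("mass_window must be positive", call. = FALSE)
  mz <- s$mz; y <- s$intensity; n <- length(y)
  if (length(unique(y)) == 1L) {
    warning("all intensities identical; noise level is 0")
    return(rep(0, n))
  }
  centers <- seq(mz[1], mz[n], by = mass_window / 2)
  half <- mass_window / 2
  lev <- vapply(centers, function(cm) {
    idx <- which(mz >= cm - half & mz <= cm + half)
    if (length(idx) < 3L) return(NA_real_)
    mad(y[idx])
  }, numeric(1))
  ok <- is.finite(lev)
  if (sum(ok) < 2L) return(rep(mad(y), n))
  approx(centers[ok], lev[ok], xout = mz, rule = 2)$y
}

#' Detect peaks by signal-to-noise thresholding
#'
#' Local maxima (strictly greater than both neighbours; plateaus resolved
#' to their leftmost point) whose apex intensity divided by the local
#' noise level is at least `snr_cutoff`. Peaks exactly at the cut-off are
#' kept. The reported m/z is the intensity-weighted centroid over the
#' contiguous region above half the apex height; the intensity is the
#' apex height. Raising the cut-off never adds a peak.
#'
#' @param s A smoothed, baseline-subtracted [spectrum()].
#' @param noise Noise level per grid point from [estimate_noise()].
#' @param snr_cutoff Minimum S/N (default 5.0).
#' @return A `peak_list`: data.frame with columns `mz`, `intensity`,
#'   `snr`, sorted by `mz`, with the sample id as attribute.
#' @export
detect_peaks <- function(s, noise, snr_cutoff = 5) {
  stopifnot(inherits(s, "spectrum"))
  if (length(noise) != length(s$mz)) {
    stop("noise length must match the spectrum", call. = FALSE)
  }
  y <- s$intensity; mz <- s$mz
  apex <- local_maxima(y)
  if (length(apex)) {
    snr <- ifelse(noise[apex] > 0, y[apex] / noise[apex],
                  ifelse(y[apex] > 0, Inf, 0))
    keep <- snr >= snr_cutoff
    apex <- apex[keep]; snr <- snr[keep]
  } else {
    snr <- numeric()
  }
  cent <- vapply(apex, function(i) {
    half <- y[i] / 2
    lo <- i; while (lo > 1L && y[lo - 1L] >= half) lo <- lo - 1L
    hi <- i; while (hi < length(y) && y[hi + 1L] >= half) hi <- hi + 1L
    idx <- lo:hi
    sum(mz[idx] * y[idx]) / sum(y[idx])
  }, numeric(1))
  pl <- data.frame(mz = cent, intensity = y[apex], snr = snr)
  pl <- pl[order(pl$mz), , drop = FALSE]
  # resolution floor: merge apexes closer than 2 grid steps, keep the higher
  if (nrow(pl) > 1L) {
    floor_th <- 2 * min(diff(mz))
    repeat {
      gap <- diff(pl$mz)
      j <- which(gap < floor_th)
      if (!length(j)) break
      j <- j[1]
      drop <- if (pl$intensity[j] >= pl$intensity[j + 1L]) j + 1L else j
      pl <- pl[-drop, , drop = FALSE]
    }
  }
  rownames(pl) <- NULL
  structure(pl, sample_id = s$sample_id,
            class = c("peak_list", "data.frame"))
}

#' Total-ion-current normalization
#'
#' Divides every intensity by the spectrum's total intensity sum, so that
#' intensities sum to one. Idempotent; undefined (an error) for an
#' all-zero spectrum.
#'
#' @param s A [spectrum()].
#' @return The normalized spectrum.
#' @export
normalize_tic <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  tot <- sum(s$intensity)
  if (tot <= 0) {
    stop("cannot TIC-normalize a spectrum with no positive intensity",
         call. = FALSE)
  }
  s$intensity <- s$intensity / tot
  log_step(s, "normalize_tic")
}

#' Run the full processing chain on one spectrum
#'
#' Canonical fixed order: crop to the acquisition range, smooth, estimate
#' and subtract the baseline, estimate the local noise, TIC-normalize
#' (the noise series is scaled by the same factor, so S/N is unchanged),
#' and detect peaks. Every step is recorded in the processing log. The
#' function is pure: identical input and parameters give identical
#' output.
#'
#' @param s A raw [spectrum()].
#' @param params A [preprocess_params()].
#' @return List with elements `spectrum` (processed) and `peaks`
#'   (its `peak_list`).
#' @export
preprocess_spectrum <- function(s, params = preprocess_params()) {
  stopifnot(inherits(s, "spectrum"), inherits(params, "preprocess_params"))
  keep <- s$mz >= params$mz_min & s$mz <= params$mz_max
  if (sum(keep) < 2L) stop("fewer than 2 points inside [mz_min, mz_max]",
                           call. = FALSE)
  s <- spectrum(s$mz[keep], s$intensity[keep], s$sample_id,
                c(s$processing_log,
                  sprintf("crop(%g,%g)", params$mz_min, params$mz_max)))
  s <- smooth_spectrum(s, params$smooth_window)
  base <- estimate_baseline(s, params$baseline_mass_window)
  s <- subtract_baseline(s, base)
  noise <- estimate_noise(s, params$baseline_mass_window)
  tot <- sum(s$intensity)
  s <- normalize_tic(s)
  noise <- noise / tot
  peaks <- detect_peaks(s, noise, params$snr_cutoff)
  s <- log_step(s, sprintf("detect_peaks(snr>=%g)", params$snr_cutoff))
  list(spectrum = s, peaks = peaks)
}

#' Preprocess every spectrum of a cohort
#'
#' Applies [preprocess_spectrum()] to each spectrum of a `spectrum_set`
#' (or to each file of a manifest read with [read_manifest()]).
#'
#' @param x A `spectrum_set` or a manifest data.frame.
#' @param params A [preprocess_params()].
#' @param keep_spectra Keep the processed spectra (memory-heavy) or only
#'   the peak lists.
#' @return List with `peaklists`, `labels`, `sample_ids`, `cohort_id` and
#'   (optionally) `spectra`.
#' @export
preprocess_cohort <- function(x, params = preprocess_params(),
                              keep_spectra = FALSE) {
  if (is.data.frame(x)) {
    spectra <- lapply(seq_len(nrow(x)), function(i) {
      read_spectrum(x$file[i], sample_id = x$sample_id[i])
    })
    labels <- x$label
    ids <- x$sample_id
    cohort_id <- if (length(unique(x$cohort)) == 1L) x$cohort[1] else "mixed"
  } else {
    stopifnot(inherits(x, "spectrum_set"))
    spectra <- x$spectra
    labels <- x$labels
    ids <- vapply(spectra, `[[`, character(1), "sample_id")
    cohort_id <- x$cohort_id
  }
  out <- lapply(spectra, preprocess_spectrum, params = params)
  res <- list(peaklists = lapply(out, `[[`, "peaks"),
              labels = labels, sample_ids = ids, cohort_id = cohort_id)
  if (keep_spectra) res$spectra <- lapply(out, `[[`, "spectrum")
  res
}
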