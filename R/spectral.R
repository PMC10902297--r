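#' IAF-anchored frequency band scheme
#'
#' Builds the five canonical band definitions anchored to a subject's
#' individual alpha frequency (IAF): delta = (IAF-8, IAF-6), theta =
#' (IAF-6, IAF-2), alpha = (IAF-2, IAF+2), beta = (IAF+2, IAF+14),
#' gamma = (IAF+15, IAF+80).  Note the deliberate 1-Hz gap between the
#' beta upper edge and the gamma lower edge: no band covers
#' (IAF+14, IAF+15).
#'
#' @param iaf_hz Individual alpha frequency in Hz; must exceed 8 so the
#'   delta lower edge stays positive.
#' @return A `band_scheme`: list with `iaf_hz` and `bands`, a named list
#'   of `c(low_hz, high_hz)` pairs.
#' @export
#' @examples
#' define_bands(10)$bands$alpha  # c(8, 12)
define_bands <- function(iaf_hz) {
  if (!is.numeric(iaf_hz) || length(iaf_hz) != 1 || !is.finite(iaf_hz)) {
    stop("iaf_hz must be a single finite number")
  }
  if (iaf_hz <= 8) stop("iaf_hz must exceed 8 Hz (delta edge would be <= 0)")
  bands <- list(
    delta = c(iaf_hz - 8, iaf_hz - 6),
    theta = c(iaf_hz - 6, iaf_hz - 2),
    alpha = c(iaf_hz - 2, iaf_hz + 2),
    beta  = c(iaf_hz + 2, iaf_hz + 14),
    gamma = c(iaf_hz + 15, iaf_hz + 80)
  )
  structure(list(iaf_hz = iaf_hz, bands = bands), class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> IAF = %.2f Hz\n", x$iaf_hz))
  for (nm in names(x$bands)) {
    cat(sprintf("  %-5s %6.2f - %6.2f Hz\n", nm, x$bands[[nm]][1],
                x$bands[[nm]][2]))
  }
  invisible(x)
}

# Welch-averaged periodogram: Hann-tapered overlapping segments.
# resolution_hz caps the frequency bin width (segment length >=
# fs / resolution_hz, truncated to the record length).
welch_psd <- function(x, fs_hz, resolution_hz = 0.25, overlap = 0.5) {
  n <- length(x)
  seg <- min(n, ceiling(fs_hz / resolution_hz))
  step <- max(1L, floor(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  u <- sum(w^2)
  acc <- numeric(seg %/% 2 + 1)
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)]
    xs <- (xs - mean(xs)) * w
    p <- Mod(fft(xs))^2 / (u * fs_hz)
    acc <- acc + p[seq_along(acc)]
  }
  list(freq = (seq_along(acc) - 1) * fs_hz / seg, psd = acc / length(starts))
}

#' Detect the individual alpha frequency
#'
#' Finds, per ROI in `roi_subset`, the frequency of the largest spectral
#' peak inside `search_range` on a Welch-averaged periodogram, and
#' returns the mean across ROIs.  A peak must be a strict local maximum
#' of the spectrum inside the range and stand clearly above the in-range
#' background (ratio to the median in-range power >= `min_peak_ratio`);
#' ROIs with no qualifying peak are flagged, and if no ROI has one the
#' function errors with "no alpha peak".
#'
#' @param ts A [roi_ts()].
#' @param roi_subset Labels of the ROIs to average over; default the
#'   occipitoparietal subset intersected with the available labels (all
#'   ROIs if the intersection is empty).
#' @param search_range Frequency range in Hz, default `c(7, 13)`.
#' @param resolution_hz Target spectral resolution, default 0.25 Hz.
#' @param min_peak_ratio Minimum peak power over in-range median power,
#'   default 2.
#' @return IAF estimate in Hz (scalar).
#' @export
detect_iaf <- function(ts, roi_subset = NULL, search_range = c(7, 13),
                       resolution_hz = 0.25, min_peak_ratio = 2) {
  stopifnot(inherits(ts, "roi_ts"))
  if (is.null(roi_subset)) {
    roi_subset <- intersect(occipitoparietal_labels(), ts$labels)
    if (length(roi_subset) == 0) roi_subset <- ts$labels
  }
  if (length(roi_subset) == 0) stop("empty ROI subset")
  missing <- setdiff(roi_subset, ts$labels)
  if (length(missing)) stop("unknown ROI labels: ", paste(missing, collapse = ", "))
  if (search_range[2] >= ts$fs_hz / 2) stop("search range exceeds Nyquist")
  peaks <- vapply(roi_subset, function(lab) {
    sp <- welch_psd(ts$data[, lab], ts$fs_hz, resolution_hz)
    inr <- which(sp$freq >= search_range[1] & sp$freq <= search_range[2])
    if (length(inr) < 3) return(NA_real_)
    p <- sp$psd
    i <- inr[which.max(p[inr])]
    # strict local maximum, not pinned to a range edge
    if (i <= 1 || i >= length(p)) return(NA_real_)
    if (!(p[i] > p[i - 1] && p[i] > p[i + 1])) return(NA_real_)
    if (i == inr[1] || i == inr[length(inr)]) return(NA_real_)
    if (p[i] < min_peak_ratio * median(p[inr])) return(NA_real_)
    sp$freq[i]
  }, numeric(1))
  if (all(is.na(peaks))) stop("no alpha peak found in the search range")
  mean(peaks, na.rm = TRUE)
}

#' Reduce within-ROI source time courses to one representative series
#'
#' First principal component of the within-ROI source signals, preserving
#' phase better than the plain mean.  The component sign is fixed so its
#' correlation with the mean source signal is nonnegative.
#'
#' @param source_signals Numeric matrix, rows = samples, columns =
#'   sources within one ROI (a vector is accepted for a single source).
#' @return Numeric vector of first-PC scores (length = samples).
#' @export
reduce_roi <- function(source_signals) {
  x <- as.matrix(source_signals)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (all(apply(x, 2, stats::var) < .Machine$double.eps)) {
    stop("zero-variance input: no principal component defined")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  m <- rowMeans(x)
  if (stats::var(m) > 0 && stats::cor(scores, m) < 0) scores <- -scores
  unname(scores)
}

# Analytic signal by the one-sided FFT construction: zero negative
# frequencies, double strictly positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Band-limited analytic ROI signals
#'
#' Band-pass filters every ROI series with a zero-phase forward-backward
#' FIR (Hamming-windowed, order ~3 cycles of the low band edge) and
#' extracts the analytic (Hilbert) signal.  Filter transients are trimmed
#' symmetrically: 3 cycles of `band[1]` at each end, recorded in
#' `discarded_edge_samples`.
#'
#' @param ts A [roi_ts()].
#' @param band `c(low_hz, high_hz)`, inside (0, Nyquist).
#' @param band_name Optional band tag carried through to connectivity.
#' @return An `analytic_roi` object: complex samples x ROI matrix
#'   `signals`, plus `fs_hz`, `band`, `band_name`,
#'   `discarded_edge_samples`.
#' @export
analytic_band <- function(ts, band, band_name = "band") {
  stopifnot(inherits(ts, "roi_ts"))
  nyq <- ts$fs_hz / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
    stop("band must lie strictly inside (0, Nyquist)")
  }
  n <- nrow(ts$data)
  cycles_low <- ts$fs_hz / band[1]
  if (n < 10 * cycles_low) {
    stop("record shorter than 10 cycles of the low band edge")
  }
  ord <- 2L * ceiling(1.5 * cycles_low)     # even order, ~3 cycles long
  fir <- signal::fir1(ord, band / nyq, type = "pass")
  trim <- ceiling(3 * cycles_low)
  filt <- apply(ts$data, 2, function(x) signal::filtfilt(fir, x))
  keep <- (trim + 1L):(n - trim)
  if (length(keep) < 2) stop("record too short after transient trimming")
  analytic <- apply(filt[keep, , drop = FALSE], 2, analytic_signal)
  colnames(analytic) <- ts$labels
  structure(
    list(signals = analytic, fs_hz = ts$fs_hz, band = band,
         band_name = band_name, labels = ts$labels,
         discarded_edge_samples = trim),
    class = "analytic_roi"
  )
}

#' @export
print.analytic_roi <- function(x, ...) {
  cat(sprintf(
    "<analytic_roi> %s (%.2f-%.2f Hz), %d ROIs x %d samples, trim %d\n",
    x$band_name, x$band[1], x$band[2], ncol(x$signals), nrow(x$signals),
    x$discarded_edge_samples))
  invisible(x)
}
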