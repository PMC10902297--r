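#' Phase-locking value
#'
#' Modulus of the time-averaged unit phasor of the phase difference
#' between two analytic signals.  1 means the phase difference is
#' constant over the record; independent phases give values near 0
#' (null expectation ~ sqrt(pi / (4 N))).
#'
#' @param x,y Complex analytic signals of equal length, or numeric phase
#'   vectors (radians).
#' @param max_zero_amplitude Tolerated fraction of zero-amplitude samples
#'   (phase undefined there); default 0.01.
#' @return PLV in \[0, 1\].
#' @export
plv <- function(x, y, max_zero_amplitude = 0.01) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (length(x) < 2) stop("need at least 2 samples")
  px <- to_phasor(x, max_zero_amplitude)
  py <- to_phasor(y, max_zero_amplitude)
  min(1, Mod(mean(px * Conj(py))))
}

# unit phasor of a signal; numeric input is interpreted as phase
to_phasor <- function(x, max_zero_amplitude = 0.01) {
  if (is.complex(x)) {
    a <- Mod(x)
    bad <- a < .Machine$double.eps
    if (mean(bad) > max_zero_amplitude) {
      stop("phase undefined: too many zero-amplitude samples")
    }
    p <- x
    p[!bad] <- x[!bad] / a[!bad]
    p[bad] <- 0
    p
  } else {
    exp(1i * x)
  }
}

#' Weighted phase-lag index
#'
#' `|mean(Im S_xy)| / mean(|Im S_xy|)` with `S_xy = x * Conj(y)` the
#' per-sample cross-spectrum.  Interactions at exactly zero (or pi) phase
#' lag contribute no imaginary part, so instantaneous volume-conduction
#' -like mixing of one common source yields 0 while a true 90-degree lag
#' yields 1.  When every imaginary part is zero the index is defined as 0
#' and a "zero-lag only" warning is raised.
#'
#' @param x,y Complex analytic signals of equal length.
#' @return wPLI in \[0, 1\].
#' @export
wpli <- function(x, y) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (!is.complex(x) || !is.complex(y)) {
    stop("wpli requires complex analytic signals")
  }
  im <- Im(x * Conj(y))
  denom <- mean(abs(im))
  if (denom < .Machine$double.eps) {
    warning("zero-lag only: all cross-spectral imaginary parts are 0")
    return(0)
  }
  min(1, abs(mean(im)) / denom)
}

# uniform amplitude binning over the observed range
bin_uniform <- function(x, n_bins) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(rep(1L, length(x)))
  b <- floor((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L
  pmin(b, n_bins)
}

# plug-in Shannon entropy (bits) of a joint discrete sample given as a
# matrix of integer codes (one row per observation)
plugin_entropy <- function(codes) {
  key <- apply(as.matrix(codes), 1, paste, collapse = "\r")
  p <- table(key) / length(key)
  -sum(p * log2(p))
}

#' Transfer entropy (plug-in, amplitude-binned)
#'
#' Directed information transfer from `source` to `target`:
#' `TE = H(target_future | target_past) -
#'  H(target_future | target_past, source_past)`, estimated with plug-in
#' entropies on uniformly amplitude-binned signals (bits).  Past states
#' are `history` consecutive samples ending `lag` samples before the
#' future sample.  Nonnegative up to estimator bias; the plug-in bias for
#' independent series is about `(n_bins^2 - n_bins) / (2 N ln 2)` bits.
#'
#' @param source,target Numeric time series of equal length (the real
#'   part is taken for complex input).
#' @param history Past-state length in samples (default 1).
#' @param lag Prediction lag in samples (default 1).
#' @param n_bins Number of amplitude bins (default 4).
#' @return Transfer entropy in bits (>= 0 up to estimator noise).
#' @export
transfer_entropy <- function(source, target, history = 1L, lag = 1L,
                             n_bins = 4L) {
  if (length(source) != length(target)) stop("series must have equal length")
  if (history < 1 || lag < 1) stop("history and lag must be >= 1")
  source <- Re(source); target <- Re(target)
  n <- length(target)
  n_states <- n - lag - history + 1L
  if (n_states < 5 * n_bins^(2 * history + 1)) {
    stop("underdetermined estimate: series too short for n_bins/history")
  }
  bs <- bin_uniform(source, n_bins)
  bt <- bin_uniform(target, n_bins)
  idx <- seq_len(n_states)
  fut <- bt[idx + history + lag - 1L]
  past_t <- sapply(seq_len(history), function(h) bt[idx + h - 1L])
  past_s <- sapply(seq_len(history), function(h) bs[idx + h - 1L])
  h_ft <- plugin_entropy(cbind(fut, past_t))
  h_t <- plugin_entropy(past_t)
  h_fts <- plugin_entropy(cbind(fut, past_t, past_s))
  h_ts <- plugin_entropy(cbind(past_t, past_s))
  max(0, (h_ft - h_t) - (h_fts - h_ts))
}

#' Assemble a pairwise connectivity matrix
#'
#' Computes the chosen estimator over all ROI pairs of a band-limited
#' analytic signal set.  PLV/wPLI give symmetric matrices (k(k-1)/2
#' pairwise computations); TE is computed for all k(k-1) ordered pairs
#' on the real part of the band-limited signals.
#'
#' @param signals An `analytic_roi` from [analytic_band()].
#' @param modality `"PLV"`, `"wPLI"`, or `"TE"`.
#' @param ... Passed to the pairwise estimator ([transfer_entropy()]
#'   parameters, `max_zero_amplitude`, ...).
#' @return A [conn_matrix()] tagged with the signal set's band name.
#' @export
connectivity_matrix <- function(signals, modality = c("PLV", "wPLI", "TE"),
                                ...) {
  modality <- match.arg(modality)
  stopifnot(inherits(signals, "analytic_roi"))
  s <- signals$signals
  k <- ncol(s)
  if (k < 2) stop("need at least 2 ROIs")
  m <- matrix(0, k, k)
  if (modality == "TE") {
    re <- Re(s)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) m[i, j] <- transfer_entropy(re[, i], re[, j], ...)
    }
  } else {
    f <- if (modality == "PLV") plv else wpli
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- f(s[, i], s[, j], ...)
    }
  }
  conn_matrix(m, modality = modality, band = signals$band_name,
              labels = signals$labels, directed = modality == "TE")
}

#' Inward / outward nodal profiles of a directed matrix
#'
#' Collapses a directed (TE) connectivity matrix into two nodal vectors:
#' `inward[i]` sums couplings directed from the network toward node i
#' (column sums) and `outward[i]` sums couplings from node i toward the
#' network (row sums), diagonal excluded.  On a symmetric matrix the two
#' coincide.  This is the receiver/sender simplification applied to TE
#' before multiplex construction.
#'
#' @param te A directed [conn_matrix()].
#' @return List with numeric vectors `inward` and `outward` (named by
#'   ROI label).
#' @export
directed_profiles <- function(te) {
  stopifnot(inherits(te, "conn_matrix"))
  if (!te$directed) stop("directed_profiles requires a directed matrix")
  v <- te$values
  diag(v) <- 0
  list(inward = colSums(v), outward = rowSums(v))
}
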