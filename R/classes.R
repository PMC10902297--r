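#' ROI time-series set
#'
#' Container for one subject's multichannel ROI time series: a samples x
#' ROI numeric matrix with ROI labels as column names, plus sampling rate
#' and optional per-subject metadata (true IAF, subject id).
#'
#' @param data Numeric matrix, rows = samples, columns = ROIs.
#' @param fs_hz Sampling rate in Hz.
#' @param labels ROI labels; defaults to the matrix column names.
#' @param iaf_hz Optional true individual alpha frequency (simulation
#'   ground truth).
#' @param subject_id Optional subject identifier.
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(data, fs_hz, labels = colnames(data), iaf_hz = NA_real_,
                   subject_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (is.null(labels)) labels <- make_roi_labels(ncol(data))
  if (length(labels) != ncol(data)) stop("one label per ROI required")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  colnames(data) <- labels
  structure(
    list(data = data, fs_hz = fs_hz, labels = labels, iaf_hz = iaf_hz,
         subject_id = subject_id),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d ROIs x %d samples @ %g Hz (%.1f s)",
              ncol(x$data), nrow(x$data), x$fs_hz,
              nrow(x$data) / x$fs_hz))
  if (!is.na(x$subject_id)) cat(", subject", x$subject_id)
  if (!is.na(x$iaf_hz)) cat(sprintf(", true IAF %.2f Hz", x$iaf_hz))
  cat("\n")
  invisible(x)
}

#' Connectivity matrix
#'
#' One weighted connectivity layer: an n x n matrix of nonnegative
#' weights tagged with its modality (`"FA"`, `"PLV"`, `"wPLI"`, `"TE"`),
#' frequency band, and directedness.  The diagonal is forced to zero:
#' auto-correlations between regions are excluded from all analyses.
#' PLV and wPLI layers must be symmetric with values in \[0, 1\]; only TE
#' layers may be directed.
#'
#' @param values Square numeric matrix of nonnegative weights.
#' @param modality One of `"FA"`, `"PLV"`, `"wPLI"`, `"TE"`.
#' @param band Band name, or `"broadband"` (the FA default).
#' @param labels ROI labels (defaults to dimnames or generated labels).
#' @param directed Logical; only TE layers may be directed.
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, modality = c("FA", "PLV", "wPLI", "TE"),
                        band = "broadband", labels = NULL,
                        directed = identical(modality, "TE")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  n <- nrow(values)
  if (n != ncol(values)) stop("connectivity matrix must be square")
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(values))) rownames(values)
              else make_roi_labels(n)
  }
  if (length(labels) != n) stop("one label per node required")
  if (anyNA(values) || any(values < 0)) {
    stop("connectivity weights must be nonnegative and finite")
  }
  diag(values) <- 0
  if (directed && modality != "TE") stop("only TE layers may be directed")
  if (modality %in% c("PLV", "wPLI")) {
    if (any(values > 1 + 1e-9)) stop(modality, " values must lie in [0, 1]")
    if (max(abs(values - t(values))) > 1e-9) {
      stop(modality, " matrix must be symmetric")
    }
  }
  if (modality == "FA" && max(abs(values - t(values))) > 1e-9) {
    stop("FA matrix must be symmetric")
  }
  dimnames(values) <- list(labels, labels)
  structure(
    list(values = values, modality = modality, band = band,
         directed = isTRUE(directed), labels = labels),
    class = "conn_matrix"
  )
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s / %s, %d nodes, %s\n",
              x$modality, x$band, nrow(x$values),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Two-layer multiplex network
#'
#' Binary adjacency layers over a shared node set, all binarized to the
#' same density.  Layer 1 is conventionally structural, layer 2
#' functional.  For a directed functional (TE) layer, `direction_mode`
#' records whether nodal functional degree counts suprathreshold
#' couplings directed toward each node (`"inward"`) or away from it
#' (`"outward"`).
#'
#' @param layers List of >= 2 binary adjacency matrices (same dimension).
#' @param layer_tags Character tags, e.g. `c("FA", "PLV.alpha")`.
#' @param density Edge density the layers were matched to.
#' @param direction_mode `"undirected"`, `"inward"`, or `"outward"`.
#' @param labels Node labels.
#' @return An object of class `multiplex_net`.
#' @export
multiplex_net <- function(layers, layer_tags, density,
                          direction_mode = c("undirected", "inward", "outward"),
                          labels = NULL) {
  direction_mode <- match.arg(direction_mode)
  if (length(layers) < 2) stop("a multiplex network needs at least 2 layers")
  n <- nrow(layers[[1]])
  for (l in layers) {
    l <- as.matrix(l)
    if (nrow(l) != n || ncol(l) != n) stop("all layers must share one node set")
    if (any(l != 0 & l != 1)) stop("layers must be binary")
    if (any(diag(l) != 0)) stop("layer diagonals must be zero")
  }
  if (length(layer_tags) != length(layers)) stop("one tag per layer")
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(layers[[1]]))) rownames(layers[[1]])
              else make_roi_labels(n)
  }
  layers <- lapply(layers, function(l) {
    l <- as.matrix(l); dimnames(l) <- list(labels, labels); l
  })
  names(layers) <- layer_tags
  structure(
    list(layers = layers, layer_tags = layer_tags, density = density,
         direction_mode = direction_mode, labels = labels),
    class = "multiplex_net"
  )
}

#' @export
print.multiplex_net <- function(x, ...) {
  cat(sprintf("<multiplex_net> %d layers (%s), %d nodes, density %.3f, %s\n",
              length(x$layers), paste(x$layer_tags, collapse = " | "),
              length(x$labels), x$density, x$direction_mode))
  invisible(x)
}

# internal: n x n check with shared labels
stopifnot_same_nodes <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop("matrices must share one node set")
  }
  if (!identical(a$labels, b$labels)) stop("node label mismatch")
  invisible(TRUE)
}
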