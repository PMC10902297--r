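#' Edge density of a weighted matrix
#'
#' Fraction of possible edges whose weight exceeds `presence_threshold`,
#' diagonal excluded: the denominator is n(n-1)/2 for undirected
#' matrices and n(n-1) for directed ones.
#'
#' @param w A [conn_matrix()].
#' @param presence_threshold Weight above which an edge counts as
#'   present; default 0.
#' @return Density in \[0, 1\].
#' @export
matrix_density <- function(w, presence_threshold = 0) {
  stopifnot(inherits(w, "conn_matrix"))
  v <- w$values
  n <- nrow(v)
  if (n < 2) return(0)
  diag(v) <- -Inf
  if (w$directed) {
    sum(v > presence_threshold) / (n * (n - 1))
  } else {
    sum(v[upper.tri(v)] > presence_threshold) / (n * (n - 1) / 2)
  }
}

#' Minimum density over a group of matrices
#'
#' The density floor used for matched-density binarization: in the
#' reference study the minimum structural (DWI) density observed in the
#' older group, 22%, set the threshold for every layer.
#'
#' @param matrices List of [conn_matrix()] of identical shape.
#' @param presence_threshold Passed to [matrix_density()].
#' @return Minimum density (scalar).
#' @export
min_group_density <- function(matrices, presence_threshold = 0) {
  if (length(matrices) == 0) stop("empty matrix list")
  n <- nrow(matrices[[1]]$values)
  dens <- vapply(matrices, function(m) {
    if (nrow(m$values) != n) stop("matrices differ in shape")
    matrix_density(m, presence_threshold)
  }, numeric(1))
  min(dens)
}

# deterministic ranking of off-diagonal entries: by decreasing weight,
# ties broken by lexicographic node-pair order (row, then column)
rank_edges <- function(v, directed) {
  n <- nrow(v)
  if (directed) {
    idx <- which(row(v) != col(v))
  } else {
    idx <- which(upper.tri(v))
  }
  i <- row(v)[idx]; j <- col(v)[idx]
  ord <- order(-v[idx], i, j)
  cbind(i = i[ord], j = j[ord], w = v[idx][ord])
}

#' Binarize a weighted matrix to a target density
#'
#' Keeps exactly `floor(density * E_max)` strongest edges, where `E_max`
#' is n(n-1)/2 (undirected) or n(n-1) (directed); ties at the cut are
#' broken by lexicographic node-pair order, so the result is
#' deterministic and invariant to rescaling all weights by a positive
#' constant.  Zero-weight entries never become edges: if fewer nonzero
#' weights than the target edge count exist the function errors rather
#' than returning a silently sparser layer.
#'
#' @param w A [conn_matrix()].
#' @param density Target density in (0, 1\].
#' @return Binary adjacency matrix (0/1, dimnames = labels).
#' @export
binarize_to_density <- function(w, density) {
  stopifnot(inherits(w, "conn_matrix"))
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  v <- w$values
  n <- nrow(v)
  e_max <- if (w$directed) n * (n - 1) else n * (n - 1) / 2
  e <- floor(density * e_max)
  if (e < 1) stop("density too low: no edges would survive")
  edges <- rank_edges(v, w$directed)
  if (sum(edges[, "w"] > 0) < e) {
    stop("matrix too sparse for target density")
  }
  a <- matrix(0, n, n, dimnames = list(w$labels, w$labels))
  sel <- edges[seq_len(e), , drop = FALSE]
  a[sel[, c("i", "j"), drop = FALSE]] <- 1
  if (!w$directed) a[sel[, c("j", "i"), drop = FALSE]] <- 1
  a
}

#' Build a two-layer structure-function multiplex network
#'
#' Binarizes the structural and functional matrices to the same density
#' and stacks them as the two layers of a multiplex network (same node
#' set, inter-layer links only node-to-itself).  With an undirected
#' functional layer both layers threshold the strongest n(n-1)/2-pair
#' weights.  With a directed TE layer and `direction_mode = "inward"`
#' (or `"outward"`), the TE matrix is thresholded over its n(n-1)
#' ordered pairs first, and nodal functional degree subsequently counts
#' suprathreshold couplings directed toward (column entries) or away
#' from (row entries) each node.
#'
#' @param structural Undirected [conn_matrix()] (FA layer).
#' @param functional [conn_matrix()]; directed only when
#'   `direction_mode` is not `"undirected"`.
#' @param density Matched density; default 0.22, the reference minimum
#'   structural density.
#' @param direction_mode `"undirected"`, `"inward"`, or `"outward"`.
#' @return A [multiplex_net()] with layer 1 structural, layer 2
#'   functional.
#' @export
build_multiplex <- function(structural, functional, density = 0.22,
                            direction_mode = c("undirected", "inward",
                                               "outward")) {
  direction_mode <- match.arg(direction_mode)
  stopifnot(inherits(structural, "conn_matrix"),
            inherits(functional, "conn_matrix"))
  stopifnot_same_nodes(structural, functional)
  if (structural$directed) stop("structural layer must be undirected")
  if (functional$directed && direction_mode == "undirected") {
    stop("a directed functional layer needs direction_mode inward/outward")
  }
  if (!functional$directed && direction_mode != "undirected") {
    stop("direction_mode ", direction_mode,
         " requires a directed functional layer")
  }
  a_str <- binarize_to_density(structural, density)
  a_fun <- binarize_to_density(functional, density)
  multiplex_net(
    layers = list(a_str, a_fun),
    layer_tags = c(paste0(structural$modality, ".", structural$band),
                   paste0(functional$modality, ".", functional$band)),
    density = density, direction_mode = direction_mode,
    labels = structural$labels
  )
}

#' Per-node degrees of one multiplex layer
#'
#' Number of connections of each node in the given layer, diagonal
#' excluded.  For a directed layer the degree respects the network's
#' `direction_mode`: inward counts column entries (couplings toward the
#' node), outward counts row entries.
#'
#' @param mx A [multiplex_net()].
#' @param layer Layer index (1 = structural, 2 = functional by
#'   convention).
#' @return Named integer-valued numeric vector of degrees.
#' @export
layer_degree <- function(mx, layer) {
  stopifnot(inherits(mx, "multiplex_net"))
  if (layer < 1 || layer > length(mx$layers)) stop("layer index out of range")
  a <- mx$layers[[layer]]
  sym <- max(abs(a - t(a))) == 0
  if (sym || mx$direction_mode == "outward") rowSums(a) else colSums(a)
}

#' Multiplex participation coefficient and degree metrics
#'
#' For every node i computes the per-layer degrees `k[i, l]`, the
#' overlapping degree `o_i = sum_l k[i, l]`, the per-layer total degree
#' `d`, and the multiplex participation coefficient
#' \deqn{p_i = \frac{M}{M-1}\Big[1 - \sum_{\alpha=1}^{M}
#'       \big(k_i^{[\alpha]}/o_i\big)^2\Big]}
#' which is 1 when the node's degree is spread equally over the layers
#' and 0 when a single layer holds all of its edges.  Isolated nodes
#' (o_i = 0, a 0/0 in the formula) are assigned p_i = 0: a node with no
#' edges participates in no layer.
#'
#' @param mx A [multiplex_net()].
#' @return A `participation_result`: list with matrix `k` (nodes x
#'   layers), vectors `o`, `p`, per-layer totals `d`, and `labels`.
#' @export
participation <- function(mx) {
  stopifnot(inherits(mx, "multiplex_net"))
  m_layers <- length(mx$layers)
  k <- vapply(seq_len(m_layers), function(l) layer_degree(mx, l),
              numeric(length(mx$labels)))
  dimnames(k) <- list(mx$labels, mx$layer_tags)
  o <- rowSums(k)
  ratio2 <- (k / ifelse(o > 0, o, 1))^2
  p <- m_layers / (m_layers - 1) * (1 - rowSums(ratio2))
  p[o == 0] <- 0
  p <- pmin(pmax(p, 0), 1)
  structure(
    list(k = k, o = o, p = setNames(p, mx$labels),
         d = colSums(k), labels = mx$labels),
    class = "participation_result"
  )
}

#' @export
print.participation_result <- function(x, ...) {
  cat(sprintf("<participation_result> %d nodes, %d layers; mean p = %.3f\n",
              length(x$p), ncol(x$k), mean(x$p)))
  invisible(x)
}
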