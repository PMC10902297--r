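# Shared fixtures, built in code.  All randomized fixtures take an
# explicit seed so every test is reproducible.

# small weighted symmetric matrix with distinct weights
fix_weighted_sym <- function(n, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- sample(seq_len(n * (n - 1) / 2)) / (n * n)
  w <- w + t(w)
  conn_matrix(w, modality = "FA")
}

# random binary 2-layer multiplex at a common edge count
fix_random_multiplex <- function(n, n_edges, seed = 1) {
  set.seed(seed)
  one_layer <- function() {
    a <- matrix(0, n, n)
    idx <- sample(which(upper.tri(a)), n_edges)
    a[idx] <- 1
    a + t(a)
  }
  multiplex_net(list(one_layer(), one_layer()), c("FA", "PLV.alpha"),
                density = n_edges / (n * (n - 1) / 2))
}

# brute-force multiplex participation straight from the printed formula
brute_participation <- function(layers) {
  m <- length(layers)
  n <- nrow(layers[[1]])
  k <- sapply(layers, function(a) {
    vapply(seq_len(n), function(i) sum(a[i, -i]), numeric(1))
  })
  vapply(seq_len(n), function(i) {
    o <- sum(k[i, ])
    if (o == 0) return(0)
    m / (m - 1) * (1 - sum((k[i, ] / o)^2))
  }, numeric(1))
}

# brute-force Benjamini-Hochberg step-up adjustment:
# adj(i) = min over ranks k >= rank(i) of m * p_(k) / k, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[ord[i]] <- min(1, min(m * p[ord[i:m]] / (i:m)))
  }
  adj
}

# analytic signal of a pure sinusoid for estimator fixtures
fix_sinusoid_analytic <- function(freq_hz, fs_hz, n, phase = 0) {
  t <- (seq_len(n) - 1) / fs_hz
  exp(1i * (2 * pi * freq_hz * t + phase))
}
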