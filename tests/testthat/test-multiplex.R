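test_that("matrix density counts suprathreshold off-diagonal pairs", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.2
  w[2, 4] <- w[4, 2] <- 0.9
  m <- conn_matrix(w, "FA")
  expect_equal(matrix_density(m), 0.5)
  expect_equal(matrix_density(conn_matrix(matrix(0, 4, 4), "FA")), 0)
  full <- matrix(1, 4, 4); diag(full) <- 0
  expect_equal(matrix_density(conn_matrix(full, "FA")), 1)
  # threshold excludes weights at or below it
  expect_equal(matrix_density(m, presence_threshold = 0.5), 1 / 6)
})

test_that("group minimum density picks the sparsest matrix", {
  n <- 25  # 300 node pairs: densities representable exactly
  make <- function(n_edges, seed) {
    set.seed(seed)
    w <- matrix(0, n, n)
    idx <- sample(which(upper.tri(w)), n_edges)
    w[idx] <- runif(n_edges, 0.2, 1)
    conn_matrix(w + t(w), "FA")
  }
  ms <- list(make(93, 1), make(66, 2), make(120, 3))
  expect_equal(vapply(ms, matrix_density, numeric(1)),
               c(0.31, 0.22, 0.40))
  expect_equal(min_group_density(ms), 0.22)
  expect_equal(min_group_density(ms[1]), 0.31)
  expect_error(min_group_density(list()), "empty")
  bad <- conn_matrix(matrix(0, 5, 5), "FA")
  expect_error(min_group_density(c(ms, list(bad))), "shape")
})

test_that("density binarization keeps exactly the strongest edges", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.9, 0.1, 0.5, 0.7, 0.3, 0.2)
  m <- conn_matrix(w + t(w), "FA")
  a <- binarize_to_density(m, 0.5)
  expect_equal(sum(a[upper.tri(a)]), 3)
  kept <- which(a[upper.tri(a)] == 1)
  expect_setequal(w[upper.tri(w)][kept], c(0.9, 0.7, 0.5))
  expect_error(binarize_to_density(m, 0), "\\(0, 1\\]")
  sparse <- matrix(0, 4, 4); sparse[1, 2] <- sparse[2, 1] <- 1
  expect_error(binarize_to_density(conn_matrix(sparse, "FA"), 0.9),
               "too sparse")
})

test_that("a dense 68-node matrix at 22% keeps exactly 501 edges", {
  m <- fix_weighted_sym(68, seed = 6)
  a <- binarize_to_density(m, 0.22)
  expect_equal(sum(a[upper.tri(a)]), 501)
  expect_equal(sum(a) %% 2, 0)   # symmetric
})

test_that("binarization is scale invariant and tie-deterministic", {
  m <- fix_weighted_sym(12, seed = 9)
  a1 <- binarize_to_density(m, 0.3)
  m2 <- m; m2$values <- m$values * 17.3
  expect_identical(a1, binarize_to_density(m2, 0.3))
  # exact ties broken by lexicographic pair order, reproducibly
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  tie <- conn_matrix(w + t(w), "FA")
  a <- binarize_to_density(tie, 0.5)
  expect_equal(a[1, 2] + a[1, 3] + a[1, 4], 3)  # first pairs win
})

test_that("multiplex layers share one density by construction", {
  s <- fix_weighted_sym(16, seed = 2)
  f <- fix_weighted_sym(16, seed = 3)
  f$modality <- "PLV"; f$band <- "alpha"
  f$values <- f$values / max(f$values)
  mx <- build_multiplex(s, f, density = 0.25)
  e1 <- sum(mx$layers[[1]]) / 2
  e2 <- sum(mx$layers[[2]]) / 2
  expect_equal(e1, e2)
  expect_equal(e1, floor(0.25 * 16 * 15 / 2))

  mx_id <- build_multiplex(s, conn_matrix(s$values, "PLV", band = "alpha"),
                           density = 0.25)
  p <- participation(mx_id)$p
  connected <- rowSums(mx_id$layers[[1]]) > 0
  expect_true(all(p[connected] == 1))

  empty <- conn_matrix(matrix(0, 16, 16), "PLV", band = "alpha")
  expect_error(build_multiplex(s, empty, 0.25), "too sparse")
})

test_that("inward thresholding of TE concentrates degree on strong columns", {
  set.seed(30)
  v <- matrix(runif(144, 0, 0.2), 12, 12); diag(v) <- 0
  v[, 7] <- 0.9            # node 7 receives strongly from everyone
  diag(v) <- 0
  te <- conn_matrix(v, "TE", band = "alpha", directed = TRUE)
  s <- fix_weighted_sym(12, seed = 4)
  mx <- build_multiplex(s, te, density = 0.2, direction_mode = "inward")
  kf <- layer_degree(mx, 2)
  expect_equal(unname(which.max(kf)), 7)
  expect_equal(unname(kf[7]), 11)
  expect_error(build_multiplex(s, te, 0.2), "direction_mode")
})

test_that("participation matches the printed formula's closed forms", {
  # M = 2, k = (2, 2): p = 2 (1 - 1/4 - 1/4) = 1
  l1 <- matrix(0, 5, 5); l1[1, 2] <- l1[2, 1] <- l1[1, 3] <- l1[3, 1] <- 1
  l2 <- matrix(0, 5, 5); l2[1, 4] <- l2[4, 1] <- l2[1, 5] <- l2[5, 1] <- 1
  mx <- multiplex_net(list(l1, l2), c("a", "b"), density = 0.2)
  expect_equal(unname(participation(mx)$p[1]), 1)

  # k = (3, 0): single-layer node, p = 0
  l3 <- matrix(0, 5, 5)
  l3[1, 2:4] <- 1; l3[2:4, 1] <- 1
  l4 <- matrix(0, 5, 5); l4[2, 3] <- l4[3, 2] <- 1
  mx2 <- multiplex_net(list(l3, l4), c("a", "b"), density = 0.3)
  expect_equal(unname(participation(mx2)$p[1]), 0)

  # k = (3, 1): p = 2 (1 - 9/16 - 1/16) = 0.75
  l5 <- matrix(0, 6, 6); l5[1, 2] <- l5[2, 1] <- 1
  mx3 <- multiplex_net(list(rbind(cbind(l3, 0), 0)[1:6, 1:6], l5),
                       c("a", "b"), density = 0.2)
  expect_equal(unname(participation(mx3)$p[1]), 0.75)

  # isolated node: o = 0 handled as p = 0, and o is the exact degree sum
  pr <- participation(mx2)
  expect_equal(unname(pr$o), unname(rowSums(pr$k)))
  expect_equal(unname(pr$p[5]), 0)
})

test_that("participation equals brute force on random multiplexes", {
  set.seed(55)
  for (r in 1:200) {
    n <- sample(5:14, 1)
    e <- sample(2:(n * (n - 1) / 4), 1)
    mx <- fix_random_multiplex(n, e, seed = r)
    pr <- participation(mx)
    expect_equal(unname(pr$p), brute_participation(mx$layers),
                 tolerance = 1e-12)
    expect_true(all(pr$p >= 0 & pr$p <= 1))
    expect_equal(unname(pr$d), unname(vapply(mx$layers, sum, numeric(1))))
  }
})

test_that("node relabelling permutes participation identically", {
  mx <- fix_random_multiplex(10, 12, seed = 77)
  perm <- sample(10)
  permuted <- multiplex_net(lapply(mx$layers, function(a) a[perm, perm]),
                            mx$layer_tags, mx$density)
  expect_equal(unname(participation(permuted)$p),
               unname(participation(mx)$p[perm]))
})

test_that("layer degree equals the brute-force row sums", {
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  pad <- function(a, n) { m <- matrix(0, n, n); m[1:3, 1:3] <- a; m }
  mx <- multiplex_net(list(pad(tri, 5), matrix(0, 5, 5)), c("a", "b"),
                      density = 0.3)
  expect_equal(unname(layer_degree(mx, 1)), c(2, 2, 2, 0, 0))
  expect_equal(unname(layer_degree(mx, 2)), rep(0, 5))
  expect_error(layer_degree(mx, 3), "out of range")
  rnd <- fix_random_multiplex(9, 10, seed = 5)
  expect_equal(unname(layer_degree(rnd, 2)),
               unname(rowSums(rnd$layers[[2]])))
})
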