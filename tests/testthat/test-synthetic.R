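test_that("generators are pure functions of their spec", {
  sp <- oscillator_spec(6, duration_s = 12, seed = 31)
  a <- gen_oscillators(sp)
  b <- gen_oscillators(sp)
  expect_identical(a$data, b$data)

  cs <- cohort_spec(n_young = 4, n_old = 4, n_rois = 12,
                    effect_size_d = 1, seed = 9)
  os <- oscillator_spec(12, duration_s = 12, seed = 9)
  g1 <- gen_cohort(os, cs, generate_signals = FALSE)
  g2 <- gen_cohort(os, cs, generate_signals = FALSE)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$functional[[3]]$values, g2$functional[[3]]$values)
  expect_identical(g1$truth$p_target, g2$truth$p_target)
})

test_that("oscillator spec rejects degenerate input", {
  expect_error(oscillator_spec(4, duration_s = -1), "positive")
  expect_error(oscillator_spec(4, fs_hz = 0), "positive")
  cm <- matrix(0, 4, 4); cm[1, 2] <- 0.5
  expect_error(oscillator_spec(4, coupling = cm), "symmetric")
})

test_that("uncoupled oscillators have null-level pairwise phase locking", {
  sp <- oscillator_spec(8, duration_s = 120, noise_sd = 0, seed = 101)
  ts <- gen_oscillators(sp, keep_phases = TRUE)
  ph <- attr(ts, "truth")$phases
  for (i in 1:7) for (j in (i + 1):8) {
    expect_lt(plv(ph[, i], ph[, j]), 0.1)
  }
})

test_that("full coupling yields perfect phase locking", {
  cm <- matrix(0, 4, 4); cm[1, 2] <- cm[2, 1] <- 1
  sp <- oscillator_spec(4, coupling = cm, noise_sd = 0, duration_s = 15,
                        seed = 5)
  ph <- attr(gen_oscillators(sp, keep_phases = TRUE), "truth")$phases
  expect_equal(plv(ph[, 1], ph[, 2]), 1, tolerance = 1e-9)
  # constant phase offsets do not change PLV
  sp2 <- sp; sp2$phase_lag <- matrix(0, 4, 4)
  sp2$phase_lag[1, 2] <- pi / 3; sp2$phase_lag[2, 1] <- -pi / 3
  ph2 <- attr(gen_oscillators(sp2, keep_phases = TRUE), "truth")$phases
  expect_equal(plv(ph2[, 1], ph2[, 2]), 1, tolerance = 1e-9)
})

test_that("lagged directed influence creates asymmetric transfer entropy", {
  di <- matrix(0, 3, 3); di[1, 2] <- 0.9
  sp <- oscillator_spec(3, directed_influence = di, noise_sd = 0.1,
                        duration_s = 40, seed = 17)
  ts <- gen_oscillators(sp)
  te_ab <- transfer_entropy(ts$data[, 1], ts$data[, 2])
  te_ba <- transfer_entropy(ts$data[, 2], ts$data[, 1])
  expect_gt(te_ab, te_ba)
})

test_that("structural generator honours the overlap parameter", {
  os <- oscillator_spec(24, seed = 3)
  set.seed(3)
  w <- matrix(0, 24, 24)
  w[upper.tri(w)] <- runif(sum(upper.tri(w)))
  w <- w + t(w)
  fun <- conn_matrix(w, modality = "PLV", band = "alpha")

  cs1 <- cohort_spec(n_rois = 24, structural_overlap = 1, seed = 3)
  s1 <- gen_structural(os, cs1, fun)
  b_fun <- binarize_to_density(fun, 0.22)
  b_str <- binarize_to_density(s1, 0.22)
  expect_identical(b_fun, b_str)
  p1 <- participation(build_multiplex(s1, fun, 0.22))$p
  connected <- rowSums(b_str) > 0
  expect_true(all(p1[connected] == 1))

  cs0 <- cohort_spec(n_rois = 24, structural_overlap = 0, seed = 3)
  s0 <- gen_structural(os, cs0, fun)
  b0 <- binarize_to_density(s0, 0.22)
  expect_equal(sum(b0 * b_fun), 0)      # disjoint suprathreshold sets
  p0 <- participation(build_multiplex(s0, fun, 0.22))$p
  # degrees rarely match when edge sets are disjoint
  expect_gt(mean(p0 < 1), 0.5)
  expect_lt(mean(p0), 0.97)

  expect_error(cohort_spec(n_rois = 24, structural_overlap = -0.2),
               "\\[0, 1\\]")
})

test_that("cohort spec validates target nodes and sizes", {
  expect_error(cohort_spec(n_rois = 10, target_nodes = c(5, 11)),
               "out of range")
  expect_error(cohort_spec(n_young = 1), "n >= 2")
})

test_that("planted participation effect matches its calibration", {
  os <- oscillator_spec(20, seed = 5)
  cs <- cohort_spec(effect_size_d = 1.2, seed = 3)
  young <- c(); old <- c()
  set.seed(77)
  for (r in 1:60) {
    cs$seed <- sample.int(1e6, 1)
    g <- gen_cohort(os, cs, generate_signals = FALSE)
    pt <- g$truth$p_target
    isold <- g$truth$group == "old"
    young <- c(young, pt[!isold, ]); old <- c(old, pt[isold, ])
  }
  pooled <- sqrt((var(young) + var(old)) / 2)
  d_hat <- (mean(young) - mean(old)) / pooled
  expect_equal(d_hat, 1.2, tolerance = 0.12)
})

test_that("planted cognition slope is recoverable in the old group", {
  os <- oscillator_spec(20, seed = 5)
  cs <- cohort_spec(effect_size_d = 1.2, cognition_slope = 30, seed = 21)
  hits <- 0; signs <- 0
  set.seed(13)
  for (r in 1:20) {
    cs$seed <- sample.int(1e6, 1)
    g <- gen_cohort(os, cs, generate_signals = FALSE)
    isold <- g$cohort$group == "old"
    fit <- lm(g$cohort$Cattell[isold] ~ g$truth$p_bar[isold])
    est <- coef(fit)[[2]]; se <- sqrt(diag(vcov(fit)))[[2]]
    hits <- hits + (abs(est - 30) < 2 * se)
    signs <- signs + (est > 0)
  }
  expect_gte(signs, 19)
  expect_gte(hits / 20, 0.8)
})

test_that("signal-path cohorts carry the decoupling plant in their truth", {
  os <- oscillator_spec(15, duration_s = 20, seed = 2)
  cs <- cohort_spec(n_young = 2, n_old = 2, n_rois = 15,
                    target_nodes = 13:15, effect_size_d = 1, seed = 8)
  g <- gen_cohort(os, cs, generate_signals = TRUE)
  expect_length(g$timeseries, 4)
  expect_s3_class(g$timeseries[[1]], "roi_ts")
  isold <- g$truth$group == "old"
  # old targets lose their module edges in the functional truth
  expect_true(all(g$truth$kf[isold, ] == 0))
  expect_true(all(g$truth$kf[!isold, ] > 0))
  # structural scaffold keeps target degrees in both groups
  expect_true(all(g$truth$ks > 0))
})
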