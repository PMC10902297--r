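make_cohort <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%02d", 1:(2 * n_per)),
    group = factor(rep(c("young", "old"), each = n_per),
                   levels = c("young", "old")),
    education = rnorm(2 * n_per, 20, 3),
    grey_matter_volume = rnorm(2 * n_per, 600, 40),
    stringsAsFactors = FALSE
  )
}

test_that("group contrast without covariates is the classical pooled t", {
  co <- make_cohort(15, seed = 2)
  set.seed(3)
  y <- rnorm(30) + rep(c(0, 0.8), each = 15)
  res <- group_contrast(y, co)
  g1 <- y[co$group == "young"]; g2 <- y[co$group == "old"]
  sp <- sqrt(((14) * var(g1) + 14 * var(g2)) / 28)
  t_oracle <- (mean(g1) - mean(g2)) / (sp * sqrt(2 / 15))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 28)

  # identical group distributions: exactly zero contrast
  y0 <- rep(rnorm(15), 2)
  res0 <- group_contrast(y0, co)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_raw, 1, tolerance = 1e-12)
})

test_that("covariate-adjusted contrast matches the linear-model group term", {
  co <- make_cohort(20, seed = 4)
  set.seed(5)
  y <- 0.05 * co$education + rnorm(40) + ifelse(co$group == "old", -1, 0)
  res <- group_contrast(y, co, covariates = "education")
  fit <- lm(y ~ group + education, data = co)
  expect_equal(res$statistic, -summary(fit)$coefficients["groupold", 3],
               tolerance = 1e-12)
  expect_equal(res$covariates, "education")
  expect_error(group_contrast(rep(1, 40), co), "constant")
})

test_that("summary t-test reproduces the printed demographics contrast", {
  expect_equal(summary_ttest(10, 2, 20, 10, 2, 20), 0)
  t_age <- summary_ttest(26.5, 2.01, 46, 64.5, 2.85, 46)
  expect_equal(t_age, -73.887, tolerance = 0.005 * 73.887)
  expect_equal(summary_ttest(64.5, 2.85, 46, 26.5, 2.01, 46), -t_age)
  expect_error(summary_ttest(1, 0, 10, 2, 1, 10), "positive")
})

test_that("median split trims the median band and balances subgroups", {
  a <- median_split(1:46, n_remove_per_side = 4)
  expect_equal(sum(a == "low"), 19)
  expect_equal(sum(a == "high"), 19)
  expect_equal(sum(a == "removed"), 8)
  expect_true(all(which(a == "low") %in% 1:19))
  expect_true(all(which(a == "removed") %in% 20:27))
  expect_true(all(which(a == "high") %in% 28:46))
  expect_error(median_split(1:45, 4), "odd-sized")
  expect_error(median_split(rep(2, 20), 4), "identical")
  expect_error(median_split(1:10, 4), "too few")
})

test_that("median split is deterministic under ties and monotone maps", {
  # exhaustive tie patterns on 8 values with 3 distinct levels
  set.seed(6)
  grid <- expand.grid(rep(list(1:3), 8))
  ids <- letters[1:8]
  for (i in sample(nrow(grid), 300)) {
    v <- as.numeric(grid[i, ])
    if (sd(v) == 0) next
    a1 <- median_split(v, 1, subject_id = ids)
    a2 <- median_split(v, 1, subject_id = ids)
    expect_identical(a1, a2)
    expect_equal(sum(a1 == "low"), sum(a1 == "high"))
  }
  v <- c(3, 9, 1, 7, 12, 4, 6, 10)
  expect_identical(median_split(v, 1, subject_id = ids),
                   median_split(exp(v / 3), 1, subject_id = ids))
})

test_that("cognition regression reports exact and partial correlations", {
  set.seed(8)
  m <- rnorm(30)
  r <- cognition_regression(m, 2 * m)
  expect_equal(r$statistic, 1, tolerance = 1e-9)
  expect_lt(r$p_raw, 1e-20)

  # partial correlation: confound drives both, none left after control
  conf <- rnorm(40)
  x <- conf + rnorm(40, sd = 0.1)
  y <- 2 * conf + rnorm(40, sd = 0.1)
  d <- data.frame(conf = conf)
  raw <- cognition_regression(x, y)
  prt <- cognition_regression(x, y, data = d, covariates = "conf")
  expect_gt(raw$statistic, 0.9)
  expect_lt(abs(prt$statistic), 0.35)
  expect_error(cognition_regression(m, rep(1, 30)), "constant")
})

test_that("null cognition regressions keep nominal type-I error", {
  set.seed(9)
  p <- replicate(1500, {
    cognition_regression(rnorm(46), rnorm(46))$p_raw
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(fdr_bh(0.03)$p_fdr, 0.03)
  expect_false(any(fdr_bh(rep(1, 6))$rejected))
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))$p_fdr, rep(0.05, 5))
  expect_error(fdr_bh(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(10)
  for (r in 1:200) {
    p <- runif(sample(1:40, 1))
    f <- fdr_bh(p)
    expect_equal(f$p_fdr, brute_bh(p), tolerance = 1e-12)
    expect_true(all(f$p_fdr >= p - 1e-15))
  }
})

test_that("layer contribution contrasts the two layers' degrees", {
  mx_id <- lapply(1:8, function(s) fix_random_multiplex(10, 12, seed = s))
  same <- lapply(mx_id, function(m) {
    multiplex_net(list(m$layers[[1]], m$layers[[1]]), m$layer_tags,
                  m$density)
  })
  res <- layer_contribution(same, region = 3)
  expect_equal(res$statistic[1], 0)
  expect_equal(res$p_raw[1], 1)

  # structural layer denser at node 1 than the functional layer
  set.seed(11)
  planted <- lapply(1:12, function(s) {
    l1 <- matrix(0, 10, 10)
    l1[1, 2:9] <- 1; l1[2:9, 1] <- 1
    extra <- sample(3:10, 2)
    l1[2, extra] <- 1; l1[extra, 2] <- 1; diag(l1) <- 0
    l2 <- matrix(0, 10, 10)
    nb <- sample(2:10, 2 + (s %% 2))
    l2[1, nb] <- 1; l2[nb, 1] <- 1
    multiplex_net(list(l1, l2), c("FA", "PLV.alpha"), density = 0.2)
  })
  resp <- layer_contribution(planted, region = 1)
  expect_gt(resp$statistic[1], 0)
  expect_true(resp$significant[1])

  swapped <- lapply(planted, function(m) {
    multiplex_net(rev(m$layers), rev(m$layer_tags), m$density)
  })
  ress <- layer_contribution(swapped, region = 1)
  expect_equal(ress$statistic[1], -resp$statistic[1], tolerance = 1e-12)
  expect_error(layer_contribution(planted, region = "nowhere"), "missing")
})

test_that("unimodal baseline detects global structural deficits", {
  os <- oscillator_spec(20, seed = 5)
  cs <- cohort_spec(structural_deficit_d = 1.5, seed = 13)
  g <- gen_cohort(os, cs, generate_signals = FALSE)
  res <- unimodal_baseline(g$structural, g$cohort)
  gm <- res[res$effect == "global_mean_weight", ]
  expect_true(gm$significant)
  expect_gt(gm$statistic, 0)   # young minus old: old weights lower
  expect_error(unimodal_baseline(list(), g$cohort[0, ]), "empty")
})
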