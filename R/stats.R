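#' Group contrast on a nodal metric
#'
#' With no covariates this is the classical pooled two-sample t-test
#' (young minus old, i.e. first group level minus second).  With
#' covariates the group effect is the group-term t statistic of the
#' linear model `metric ~ group + covariates`, the operational form of a
#' covariate-controlled t-test.
#'
#' @param values Numeric vector of the per-subject metric, aligned with
#'   `cohort` rows.
#' @param cohort Data frame with a `group` factor (two levels) and any
#'   covariate columns.
#' @param covariates Character vector of covariate column names
#'   (default none).
#' @param effect_name Label carried into the result row.
#' @return One-row data frame: `effect`, `statistic`, `df`, `p_raw`,
#'   `n`, `covariates`.
#' @export
group_contrast <- function(values, cohort, covariates = character(),
                           effect_name = "group") {
  if (length(values) != nrow(cohort)) stop("one value per cohort row required")
  g <- factor(cohort$group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  if (any(table(g) < 2)) stop("both groups need n >= 2")
  if (stats::sd(values) < .Machine$double.eps) stop("constant metric")
  keep <- if (length(covariates) == 0) !is.na(values) else
    complete.cases(values, cohort[, covariates, drop = FALSE])
  values <- values[keep]; g <- droplevels(g[keep])
  if (length(covariates) == 0) {
    tt <- t.test(values[g == levels(g)[1]], values[g == levels(g)[2]],
                 var.equal = TRUE)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  } else {
    dat <- data.frame(.y = values, .g = g,
                      cohort[keep, covariates, drop = FALSE])
    fit <- lm(.y ~ ., data = dat)
    sm <- summary(fit)$coefficients
    row <- grep("^\\.g", rownames(sm))
    if (length(row) != 1) stop("singular covariate design")
    # model codes the second level; flip so the contrast is level1 - level2
    stat <- -sm[row, "t value"]; p <- sm[row, "Pr(>|t|)"]
    df <- fit$df.residual
  }
  data.frame(effect = effect_name, statistic = stat, df = df, p_raw = p,
             n = length(values),
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Pooled two-sample t from summary statistics
#'
#' The classical equal-variance two-sample t computed from group means,
#' spreads and sizes (group 1 minus group 2), as used for demographic
#' tables where only summaries are printed.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return t statistic (df = n1 + n2 - 2).
#' @export
#' @examples
#' summary_ttest(26.5, 2.01, 46, 64.5, 2.85, 46)  # ~ -73.9
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
}

#' Median split with median trimming
#'
#' Dichotomizes a within-group metric at its sample median and removes
#' the `n_remove_per_side` subjects nearest the median on each side, the
#' trimming that reduces misclassification at the boundary (with 46
#' subjects and four removals per side, 19 remain per subgroup).  Ties
#' are resolved deterministically by ordering on (value, subject_id).
#'
#' @param values Numeric metric for one group.
#' @param n_remove_per_side Number of median-adjacent subjects to drop
#'   from each side (default 4).
#' @param subject_id Identifiers (default names of `values`, else
#'   1..n); used for deterministic tie-breaking and naming.
#' @return A `subgroup_assignment`: factor with levels `low`, `removed`,
#'   `high`, named by subject.
#' @export
median_split <- function(values, n_remove_per_side = 4,
                         subject_id = NULL) {
  n <- length(values)
  if (is.null(subject_id)) {
    subject_id <- if (!is.null(names(values))) names(values)
                  else as.character(seq_len(n))
  }
  if (n %% 2 == 1) {
    stop("odd-sized group: the median subject belongs to neither side; ",
         "use an even-sized group or drop one subject explicitly")
  }
  if (n <= 2 * n_remove_per_side + 2) stop("too few subjects for this split")
  if (stats::sd(values) < .Machine$double.eps) stop("all values identical")
  ord <- order(values, subject_id)     # deterministic under ties
  half <- n / 2
  lab <- rep("low", n)
  lab[ord[(half + 1):n]] <- "high"
  if (n_remove_per_side > 0) {
    lab[ord[(half - n_remove_per_side + 1):(half + n_remove_per_side)]] <-
      "removed"
  }
  structure(factor(lab, levels = c("low", "removed", "high")),
            names = subject_id, class = c("subgroup_assignment", "factor"))
}

#' Regression of cognition on a nodal metric
#'
#' Association between a per-subject network metric and a cognition
#' score, optionally controlling covariates.  `method = "parametric"`
#' reports the partial Pearson correlation of metric and score given the
#' covariates; `method = "spearman"` (for non-continuous scores such as
#' the MMSE) reports the Spearman rank correlation of the
#' covariate-residualized values.
#'
#' @param metric,score Numeric vectors, one value per subject.
#' @param data Optional data frame holding the covariate columns.
#' @param covariates Character vector of covariate column names in
#'   `data`.
#' @param method `"parametric"` or `"spearman"`.
#' @param effect_name Label carried into the result row.
#' @return One-row data frame: `effect`, `statistic` (r), `df`, `p_raw`,
#'   `n`, `covariates`.
#' @export
cognition_regression <- function(metric, score, data = NULL,
                                 covariates = character(),
                                 method = c("parametric", "spearman"),
                                 effect_name = "cognition") {
  method <- match.arg(method)
  if (length(metric) != length(score)) stop("metric/score length mismatch")
  if (length(covariates) > 0 && is.null(data)) {
    stop("covariates given without a data frame")
  }
  covs <- if (length(covariates)) data[, covariates, drop = FALSE]
          else data.frame(row.names = seq_along(metric))
  keep <- if (length(covariates) == 0) !is.na(metric) & !is.na(score)
          else complete.cases(metric, score, covs)
  metric <- metric[keep]; score <- score[keep]
  covs <- covs[keep, , drop = FALSE]
  nk <- length(metric)
  if (nk < 4 + length(covariates)) stop("too few complete observations")
  if (stats::sd(score) < .Machine$double.eps) stop("constant score")
  if (length(covariates) > 0) {
    x <- residuals(lm(metric ~ ., data = covs))
    y <- residuals(lm(score ~ ., data = covs))
  } else {
    x <- metric; y <- score
  }
  if (method == "parametric") {
    r <- cor(x, y)
    df <- nk - 2 - length(covariates)
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    r <- unname(ct$estimate); p <- ct$p.value
    df <- nk - 2 - length(covariates)
  }
  data.frame(effect = effect_name, statistic = r, df = df, p_raw = p,
             n = nk, covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values and the rejection set at level `q`,
#' applied within one analysis family (one step of the workflow:
#' regions x bands of one contrast type).
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `p_fdr` (adjusted values, same order) and
#'   `rejected` (logical).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  list(p_fdr = adj, rejected = !is.na(adj) & adj <= q)
}

#' Layer-contribution analysis at a region
#'
#' Which layer drives a multiplex effect: paired contrast of the two
#' layers' degrees at one region across subjects (structural vs
#' functional), plus each layer's own between-group contrast, FDR
#' corrected as one family.
#'
#' @param mx_list List of per-subject [multiplex_net()] (consistent
#'   node sets).
#' @param region Node label or index.
#' @param cohort Optional data frame with a two-level `group` column for
#'   the per-layer group contrasts.
#' @param q FDR level.
#' @return Data frame of effects with `statistic`, `p_raw`, `p_fdr`,
#'   `significant`.
#' @export
layer_contribution <- function(mx_list, region, cohort = NULL, q = 0.05) {
  if (length(mx_list) < 2) stop("need at least 2 subjects")
  labels <- mx_list[[1]]$labels
  if (is.character(region)) {
    if (!region %in% labels) stop("region missing from node set")
    region <- match(region, labels)
  }
  if (region < 1 || region > length(labels)) stop("region missing")
  k1 <- vapply(mx_list, function(m) layer_degree(m, 1)[region], numeric(1))
  k2 <- vapply(mx_list, function(m) layer_degree(m, 2)[region], numeric(1))
  rows <- list()
  if (stats::sd(k1 - k2) < .Machine$double.eps) {
    rows$paired <- data.frame(effect = "structural_vs_functional_degree",
                              statistic = 0, df = length(k1) - 1, p_raw = 1,
                              n = length(k1), covariates = "",
                              stringsAsFactors = FALSE)
  } else {
    tt <- t.test(k1, k2, paired = TRUE)
    rows$paired <- data.frame(effect = "structural_vs_functional_degree",
                              statistic = unname(tt$statistic),
                              df = unname(tt$parameter), p_raw = tt$p.value,
                              n = length(k1), covariates = "",
                              stringsAsFactors = FALSE)
  }
  if (!is.null(cohort)) {
    rows$g1 <- tryCatch(
      group_contrast(k1, cohort, effect_name = "structural_degree_group"),
      error = function(e) NULL)
    rows$g2 <- tryCatch(
      group_contrast(k2, cohort, effect_name = "functional_degree_group"),
      error = function(e) NULL)
  }
  res <- do.call(rbind, rows)
  fdr <- fdr_bh(res$p_raw, q)
  res$p_fdr <- fdr$p_fdr
  res$significant <- fdr$rejected
  rownames(res) <- NULL
  res
}

#' Unimodal baseline contrasts
#'
#' The single-modality comparison quantifying the added value of the
#' multiplex analysis: between-group contrasts of (a) the global mean
#' connectivity weight and (b) each node's binarized degree, in one
#' modality alone, FDR corrected as one family.
#'
#' @param matrices List of per-subject [conn_matrix()] of one modality.
#' @param cohort Data frame with a two-level `group` column, rows
#'   aligned with `matrices`.
#' @param density Density at which nodal degrees are computed (default
#'   0.22).
#' @param covariates Covariate column names passed to the contrasts.
#' @param q FDR level.
#' @return Data frame of effects (`global_mean_weight` plus one
#'   `degree.<label>` row per node) with `p_fdr` and `significant`.
#' @export
unimodal_baseline <- function(matrices, cohort, density = 0.22,
                              covariates = character(), q = 0.05) {
  if (length(matrices) == 0 || nrow(cohort) == 0) stop("empty cohort")
  if (length(matrices) != nrow(cohort)) {
    stop("one matrix per cohort row required")
  }
  off_mean <- function(m) {
    v <- m$values; diag(v) <- NA; mean(v, na.rm = TRUE)
  }
  gm <- vapply(matrices, off_mean, numeric(1))
  deg <- vapply(matrices, function(m) {
    a <- binarize_to_density(m, density)
    if (m$directed) colSums(a) else rowSums(a)
  }, numeric(length(matrices[[1]]$labels)))
  rows <- list(group_contrast(gm, cohort, covariates,
                              effect_name = "global_mean_weight"))
  for (i in seq_len(nrow(deg))) {
    rows[[i + 1]] <- tryCatch(
      group_contrast(deg[i, ], cohort, covariates,
                     effect_name = paste0("degree.",
                                          matrices[[1]]$labels[i])),
      error = function(e) NULL)   # constant-degree nodes carry no test
  }
  res <- do.call(rbind, rows)
  fdr <- fdr_bh(res$p_raw, q)
  res$p_fdr <- fdr$p_fdr
  res$significant <- fdr$rejected
  rownames(res) <- NULL
  res
}
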