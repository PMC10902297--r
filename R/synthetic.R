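# Synthetic cohorts with planted ground truth.
#
# The generator family emulates the three inputs of the real analysis:
# source-level oscillatory ROI time series with a per-subject alpha peak,
# FA-like weighted structural matrices with controllable edge overlap
# against the functional coupling pattern, and a cohort table whose
# cognition scores carry a planted linear dependence on regional
# participation.  All generators are pure functions of their spec (seed
# included).

# run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Oscillator specification
#'
#' Parameters of the phase-oscillator model behind [gen_oscillators()]:
#' unit-amplitude oscillators at the subject's alpha frequency whose
#' phases are correlated Wiener processes (increment correlation =
#' `coupling`), with optional fixed pairwise phase offsets, lagged linear
#' directed influences, and additive white observation noise.
#'
#' @param n_rois Number of ROIs.
#' @param iaf_hz Subject alpha peak frequency (Hz), default 10.
#' @param coupling Symmetric n x n matrix of pairwise phase-coupling
#'   strengths in \[0, 1\], zero diagonal (default all zero).
#' @param phase_lag Antisymmetric n x n matrix of imposed phase offsets
#'   (radians); offsets are realised as per-node phases solved by
#'   coupling-weighted least squares, so an inconsistent pairwise lag
#'   pattern is satisfied only approximately.
#' @param directed_influence n x n matrix: entry (i, j) adds
#'   `directed_influence[i, j] * carrier_i(t - influence_lag)` to ROI j,
#'   zero diagonal.
#' @param influence_lag Influence lag in samples (default 1).
#' @param noise_sd Additive observation noise SD (default 0.2; carrier
#'   amplitude is 1).
#' @param fs_hz Sampling rate (default 250 Hz).
#' @param duration_s Record length in seconds (default 60; at least 10).
#' @param phase_diffusion Phase diffusion coefficient in rad^2/s
#'   (default 20); sets the oscillators' spectral linewidth and how fast
#'   uncoupled phases decorrelate.
#' @param seed Integer RNG seed.
#' @return An `oscillator_spec` list.
#' @export
oscillator_spec <- function(n_rois, iaf_hz = 10,
                            coupling = matrix(0, n_rois, n_rois),
                            phase_lag = matrix(0, n_rois, n_rois),
                            directed_influence = matrix(0, n_rois, n_rois),
                            influence_lag = 1L, noise_sd = 0.2,
                            fs_hz = 250, duration_s = 60,
                            phase_diffusion = 20, seed = 1L) {
  if (fs_hz <= 0) stop("sampling rate must be positive")
  if (duration_s <= 0) stop("duration must be positive")
  if (duration_s < 10) stop("record must be at least 10 s long")
  coupling <- as.matrix(coupling)
  if (max(abs(coupling - t(coupling))) > 1e-12) {
    stop("coupling must be symmetric")
  }
  if (any(coupling < 0 | coupling > 1)) stop("coupling must lie in [0, 1]")
  diag(coupling) <- 0
  directed_influence <- as.matrix(directed_influence)
  diag(directed_influence) <- 0
  structure(
    list(n_rois = n_rois, iaf_hz = iaf_hz, coupling = coupling,
         phase_lag = as.matrix(phase_lag),
         directed_influence = directed_influence,
         influence_lag = as.integer(influence_lag), noise_sd = noise_sd,
         fs_hz = fs_hz, duration_s = duration_s,
         phase_diffusion = phase_diffusion, seed = as.integer(seed)),
    class = "oscillator_spec"
  )
}

# nearest-correlation fix for indefinite input: clip eigenvalues and
# restore the unit diagonal.  Merely singular matrices (e.g. a fully
# coupled pair) are left untouched so exact coupling stays exact.
pd_correlation <- function(r, eps = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) > -1e-10) return(r)
  v <- pmax(e$values, eps)
  r2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(r2))
  r2 / tcrossprod(d)
}

# connected components of a thresholded coupling graph
coupling_components <- function(c, tol = 1e-10) {
  n <- nrow(c)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      if (comp[i] > 0) next
      comp[i] <- cur
      queue <- c(queue, which(c[i, ] > tol & comp == 0L))
    }
  }
  comp
}

# per-node phase offsets realising (approximately) the pairwise lag
# matrix: coupling-weighted least squares through the graph Laplacian
solve_phase_offsets <- function(coupling, phase_lag) {
  n <- nrow(coupling)
  if (max(abs(phase_lag)) < 1e-15 || max(coupling) < 1e-15) {
    return(numeric(n))
  }
  lap <- diag(rowSums(coupling)) - coupling
  b <- rowSums(coupling * phase_lag)
  alpha <- tryCatch(
    solve(lap + matrix(1 / n, n, n), b),
    error = function(e) numeric(n))
  as.numeric(alpha)
}

#' Generate oscillatory ROI time series
#'
#' Simulates `n_rois` unit-amplitude oscillators at the spec's alpha
#' frequency.  Phases are Wiener processes whose increments are
#' correlated according to `coupling` (so a fully coupled pair keeps an
#' exactly constant phase difference and an uncoupled pair decorrelates
#' at the phase-diffusion rate), shifted by the least-squares phase
#' offsets implied by `phase_lag`.  Lagged directed influences add
#' `directed_influence[i, j] * carrier_i(t - lag)` to ROI j, and white
#' observation noise is added last.  Identical spec (seed included)
#' gives identical output.
#'
#' @param spec An [oscillator_spec()].
#' @param keep_phases Attach the true phase matrix as attribute
#'   `"truth"` (default FALSE; useful for estimator tests).
#' @return A [roi_ts()] of dimension (fs_hz * duration_s) x n_rois.
#' @export
gen_oscillators <- function(spec, keep_phases = FALSE) {
  stopifnot(inherits(spec, "oscillator_spec"))
  n <- spec$n_rois
  nt <- round(spec$fs_hz * spec$duration_s)
  with_seed(spec$seed, {
    r <- spec$coupling
    diag(r) <- 1
    r <- pd_correlation(r)
    lt <- tryCatch(t(chol(r)), error = function(e) {
      e2 <- eigen(r, symmetric = TRUE)
      e2$vectors %*% diag(sqrt(pmax(e2$values, 0)))
    })
    z <- matrix(rnorm(n * nt), n, nt)
    innov <- (lt %*% z) * sqrt(spec$phase_diffusion / spec$fs_hz)
    walk <- t(apply(innov, 1, cumsum))            # n x nt
    comp <- coupling_components(spec$coupling)
    base <- runif(max(comp), 0, 2 * pi)[comp]
    alpha <- solve_phase_offsets(spec$coupling, spec$phase_lag)
    tvec <- (seq_len(nt) - 1) / spec$fs_hz
    phases <- sweep(walk, 2, 2 * pi * spec$iaf_hz * tvec, "+") +
      base + alpha                                 # recycled by row
    carrier <- cos(t(phases))                      # nt x n
    x <- carrier
    infl <- spec$directed_influence
    if (any(infl != 0)) {
      lag <- spec$influence_lag
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (infl[i, j] != 0) {
          x[(lag + 1):nt, j] <- x[(lag + 1):nt, j] +
            infl[i, j] * carrier[1:(nt - lag), i]
        }
      }
    }
    if (spec$noise_sd > 0) x <- x + rnorm(length(x), sd = spec$noise_sd)
    out <- roi_ts(x, fs_hz = spec$fs_hz, labels = make_roi_labels(n),
                  iaf_hz = spec$iaf_hz)
    if (keep_phases) attr(out, "truth") <- list(phases = t(phases))
    out
  })
}

#' Cohort specification
#'
#' Parameters of the synthetic cohort generator [gen_cohort()]: group
#' sizes, which nodes carry the planted group effect, its size in SD
#' units on the participation scale, the planted cognition slope, and
#' the structural/functional edge-overlap level.
#'
#' The planted participation effect works on the degree imbalance
#' between the two layers at the target nodes: each subject carries a
#' node-level "hubness" factor (SD `hub_sd`) shifting both layers'
#' target degree together (it cancels in the imbalance, inflating only
#' unimodal degree variance), plus layer-specific noise (SD
#' `degree_sd`); the old group receives opposite half-shifts of the two
#' layers' target degrees, sized by numerical calibration so the
#' expected participation difference equals `effect_size_d` young-group
#' SDs.
#'
#' @param n_young,n_old Group sizes (default 46 each, the reference
#'   cohort size).
#' @param n_rois Number of ROIs (default 20).
#' @param target_nodes Node indices carrying the planted effect
#'   (default the last 3 nodes).
#' @param effect_size_d Standardized old-minus-young participation
#'   deficit at target nodes (default 0 = null cohort).
#' @param cognition_slope Linear coefficient tying `cognition_score` to
#'   mean target-node participation in the old group (default 0).
#' @param cognition_score Which score carries the slope (default
#'   `"Cattell"`, a continuous score).
#' @param structural_overlap Fraction in \[0, 1\] of functional
#'   suprathreshold edges forced to coincide with structural
#'   suprathreshold edges (default 0.6).
#' @param density Suprathreshold edge density of both layers (default
#'   0.22).
#' @param target_degree_base Mean structural target-node degree;
#'   default 1.5x the mean degree implied by `density`.
#' @param baseline_imbalance Young-group mean functional-minus-
#'   structural target degree (default 2; keeps the participation
#'   response away from its ceiling at equal degrees).
#' @param hub_sd Node-hubness SD in degree units (default 2.4).
#' @param degree_sd Layer-specific degree noise SD (default 0.9).
#' @param structural_deficit_d Standardized old-group global deficit of
#'   structural edge weights (default 0); a purely unimodal effect.
#' @param effect_mode `"degree_shift"` (default): the old group receives
#'   calibrated opposite half-shifts of the two layers' target degrees.
#'   `"alignment"`: a multiplex-only plant — the layer-specific degree
#'   noises are correlated `+alignment_rho` in the young group and
#'   `-alignment_rho` in the old group, so each layer's marginal degree
#'   distribution is identical across groups (unimodal contrasts are
#'   exactly null) while the between-layer degree imbalance, hence
#'   participation, differs; `effect_size_d` is ignored in this mode.
#' @param alignment_rho Magnitude of the layer-noise correlation used by
#'   the alignment mode (default 0.9).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list (with the calibrated degree shift and
#'   expected participation moments attached).
#' @export
cohort_spec <- function(n_young = 46, n_old = 46, n_rois = 20,
                        target_nodes = (n_rois - 2):n_rois,
                        effect_size_d = 0, cognition_slope = 0,
                        cognition_score = "Cattell",
                        structural_overlap = 0.6, density = 0.22,
                        target_degree_base = NULL,
                        baseline_imbalance = 2, hub_sd = 2.4,
                        degree_sd = 0.9, structural_deficit_d = 0,
                        effect_mode = c("degree_shift", "alignment"),
                        alignment_rho = 0.9, seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  if (alignment_rho < 0 || alignment_rho > 1) {
    stop("alignment_rho must lie in [0, 1]")
  }
  if (n_young < 2 || n_old < 2) stop("both groups need n >= 2")
  if (structural_overlap < 0 || structural_overlap > 1) {
    stop("structural_overlap must lie in [0, 1]")
  }
  if (any(target_nodes < 1 | target_nodes > n_rois)) {
    stop("target node index out of range")
  }
  e_total <- floor(density * n_rois * (n_rois - 1) / 2)
  mean_deg <- 2 * e_total / n_rois
  k_max <- min(n_rois - 1 - length(target_nodes),
               floor((e_total - 2) / length(target_nodes)))
  if (is.null(target_degree_base)) {
    target_degree_base <- max(2, min(round(1.5 * mean_deg),
                                     k_max - baseline_imbalance))
  }
  if (k_max < target_degree_base + baseline_imbalance) {
    stop("target degrees infeasible at this density/ROI count")
  }
  sp <- structure(
    list(n_young = n_young, n_old = n_old, n_rois = n_rois,
         target_nodes = as.integer(target_nodes),
         effect_size_d = effect_size_d,
         cognition_slope = cognition_slope,
         cognition_score = cognition_score,
         structural_overlap = structural_overlap, density = density,
         e_total = e_total, target_degree_base = target_degree_base,
         baseline_imbalance = baseline_imbalance, hub_sd = hub_sd,
         degree_sd = degree_sd, k_max = k_max,
         structural_deficit_d = structural_deficit_d,
         effect_mode = effect_mode, alignment_rho = alignment_rho,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  if (effect_mode == "alignment") {
    sp$degree_shift <- 0
    spz <- sp; spz$effect_size_d <- 0
    cal <- calibrate_target_shift(spz)  # null moments for reference
    sp$expected_p <- cal$expected_p
  } else {
    cal <- calibrate_target_shift(sp)
    sp$degree_shift <- cal$shift
    sp$expected_p <- cal$expected_p
  }
  sp
}

# distribution of a rounded, clamped N(mu, sd) degree on 1..k_max
degree_pmf <- function(mu, sd, k_max) {
  k <- seq_len(k_max)
  lo <- pnorm(k - 0.5, mu, sd)
  hi <- pnorm(k + 0.5, mu, sd)
  p <- hi - lo
  p[1] <- hi[1]                     # mass below rounds up to 1
  p[k_max] <- 1 - lo[k_max]         # mass above clamps to k_max
  p
}

# Numerical calibration of the old-group degree shift: solves
#   E[p_young] - E[p_old(shift)] = d * SD[p_young]
# by quadrature over the hubness factor and exact enumeration of the
# rounded/clamped degree pair, using p = 4 kf ks / (kf + ks)^2.
calibrate_target_shift <- function(sp) {
  k <- seq_len(sp$k_max)
  pmat <- outer(k, k, function(kf, ks) 4 * kf * ks / (kf + ks)^2)
  hgrid <- seq(-4, 4, by = 0.2)
  hw <- exp(-hgrid^2 / 2)
  hw <- hw / sum(hw)
  moments <- function(shift_f, shift_s) {
    m1 <- 0; m2 <- 0
    for (a in seq_along(hgrid)) {
      h <- hgrid[a] * sp$hub_sd
      pf <- degree_pmf(sp$target_degree_base + sp$baseline_imbalance +
                         h + shift_f, sp$degree_sd, sp$k_max)
      ps <- degree_pmf(sp$target_degree_base + h + shift_s,
                       sp$degree_sd, sp$k_max)
      ep <- as.numeric(pf %*% pmat %*% ps)
      ep2 <- as.numeric(pf %*% (pmat^2) %*% ps)
      m1 <- m1 + hw[a] * ep
      m2 <- m2 + hw[a] * ep2
    }
    c(mean = m1, sd = sqrt(max(0, m2 - m1^2)))
  }
  young <- moments(0, 0)
  if (sp$effect_size_d == 0) {
    return(list(shift = 0,
                expected_p = c(young = young[["mean"]],
                               old = young[["mean"]],
                               sd_pooled = young[["sd"]])))
  }
  # Cohen's d convention: gap standardized by the pooled SD of the
  # two groups' participation distributions
  gap <- function(s) {
    old <- moments(s / 2, -s / 2)
    pooled <- sqrt((young[["sd"]]^2 + old[["sd"]]^2) / 2)
    (young[["mean"]] - old[["mean"]]) - sp$effect_size_d * pooled
  }
  upper <- 6 * sp$degree_sd + abs(sp$effect_size_d) * 4
  shift <- uniroot(gap, c(0, upper), extendInt = "upX")$root
  old <- moments(shift / 2, -shift / 2)
  list(shift = shift,
       expected_p = c(young = young[["mean"]], old = old[["mean"]],
                      sd_pooled = sqrt((young[["sd"]]^2 +
                                          old[["sd"]]^2) / 2)))
}

# sample an edge set with prescribed target-node degrees; target edges
# attach to non-target partners, optionally reusing a reference
# partner/edge set with probability `overlap`
sample_layer_edges <- function(n, e_total, targets, tdeg,
                               overlap = NULL, ref = NULL) {
  a <- matrix(FALSE, n, n)
  nontarg <- setdiff(seq_len(n), targets)
  for (ix in seq_along(targets)) {
    tn <- targets[ix]
    k <- min(tdeg[ix], length(nontarg))
    partners <- integer(0)
    if (!is.null(ref)) {
      refp <- intersect(which(ref[tn, ]), nontarg)
      n_shared <- min(round(overlap * k), length(refp))
      if (n_shared > 0) {
        partners <- refp[sample.int(length(refp), n_shared)]
      }
    }
    pool <- setdiff(nontarg, partners)
    extra <- k - length(partners)
    if (extra > 0) partners <- c(partners, pool[sample.int(length(pool), extra)])
    a[tn, partners] <- TRUE
    a[partners, tn] <- TRUE
  }
  used <- sum(a[upper.tri(a)])
  rem <- e_total - used
  if (rem < 0) stop("target degrees exceed the edge budget")
  ut <- upper.tri(a)
  eligible <- ut & !a &
    !(matrix(row(a) %in% targets, n, n) | matrix(col(a) %in% targets, n, n))
  cand <- which(eligible)
  if (rem > 0) {
    pick <- integer(0)
    if (!is.null(ref)) {
      refcand <- intersect(cand, which(ref & eligible))
      n_shared <- min(round(overlap * rem), length(refcand))
      if (n_shared > 0) pick <- refcand[sample.int(length(refcand), n_shared)]
    }
    pool <- setdiff(cand, pick)
    extra <- rem - length(pick)
    if (extra > length(pool)) stop("not enough room for the edge budget")
    if (extra > 0) pick <- c(pick, pool[sample.int(length(pool), extra)])
    a[pick] <- TRUE
    a[cbind(col(a)[pick], row(a)[pick])] <- TRUE
  }
  a
}

# weight a binary edge set: on-edges and off-edges drawn from disjoint
# uniform bands so density thresholding recovers the planted set exactly
weight_edges <- function(a, on_range, off_range, offset = 0) {
  n <- nrow(a)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(a))
  on <- ut[a[ut]]
  off <- ut[!a[ut]]
  w[on] <- runif(length(on), on_range[1], on_range[2]) + offset
  w[off] <- runif(length(off), off_range[1], off_range[2])
  w <- pmax(w, 1e-4)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}

#' Generate an FA-like structural matrix against a functional reference
#'
#' Builds a symmetric nonnegative weighted matrix whose suprathreshold
#' (top-density) edge set shares a `structural_overlap` fraction of
#' edges with the functional reference's suprathreshold set: shared
#' edges are copied from the reference's top-density set, the remainder
#' drawn from its complement, and FA-like weights assigned so that the
#' planted set is exactly the top-density set.
#'
#' @param spec An [oscillator_spec()] (provides the node count and
#'   seed offset).
#' @param cohort A [cohort_spec()] (provides `structural_overlap` and
#'   `density`).
#' @param functional_reference Undirected [conn_matrix()] with the same
#'   node count.
#' @return An FA [conn_matrix()].
#' @export
gen_structural <- function(spec, cohort, functional_reference) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(functional_reference, "conn_matrix"))
  if (functional_reference$directed) {
    stop("functional reference must be undirected")
  }
  n <- nrow(functional_reference$values)
  if (n != spec$n_rois) stop("node-count mismatch between spec and reference")
  e_total <- floor(cohort$density * n * (n - 1) / 2)
  fun_bin <- binarize_to_density(functional_reference, cohort$density) > 0
  with_seed(spec$seed + 104729L, {
    ut <- which(upper.tri(fun_bin))
    fun_edges <- ut[fun_bin[ut]]
    n_shared <- round(cohort$structural_overlap * e_total)
    shared <- if (n_shared > 0) {
      fun_edges[sample.int(length(fun_edges), min(n_shared, length(fun_edges)))]
    } else integer(0)
    pool <- setdiff(ut, fun_edges)
    extra <- e_total - length(shared)
    if (extra > length(pool)) stop("not enough non-overlapping pairs")
    own <- if (extra > 0) pool[sample.int(length(pool), extra)] else integer(0)
    a <- matrix(FALSE, n, n)
    a[c(shared, own)] <- TRUE
    a <- a | t(a)
    w <- weight_edges(a, c(0.35, 0.75), c(0.005, 0.12))
    conn_matrix(w, modality = "FA", band = "broadband",
                labels = functional_reference$labels, directed = FALSE)
  })
}

# Table-1-like score moments: list(name = c(mean_y, sd_y, mean_o, sd_o))
score_moments <- function() {
  list(
    MMSE = c(29.5, 0.863, 28.9, 1.173),
    VSTM = c(0.5, 0.088, 0.4, 0.069),
    Cattell = c(37.8, 3.628, 30.5, 6.285),
    Hotel_Num_rows = c(4.7, 0.585, 4.3, 1.008),
    Hotel_Time = c(227.7, 119.796, 326.9, 194.305)
  )
}

#' Generate a full synthetic cohort with planted ground truth
#'
#' For every subject draws the two layers' planted suprathreshold edge
#' sets (structural target-node degrees around `target_degree_base`,
#' functional degrees offset by `baseline_imbalance`, both moved by the
#' node hubness factor, the old group additionally by the calibrated
#' opposite half-shifts), assigns FA-like and coupling-like weights so
#' density thresholding recovers the planted sets, derives each
#' subject's true participation at the target nodes, and builds a
#' demographics/cognition table whose planted score depends linearly on
#' that participation in the old group.  Optionally simulates the
#' oscillatory time series whose phase-coupling pattern follows the
#' functional weights.
#'
#' @param ospec An [oscillator_spec()] used as the per-subject signal
#'   template (its coupling matrix is replaced by each subject's
#'   functional pattern; its `n_rois` must match `cspec`).
#' @param cspec A [cohort_spec()].
#' @param generate_signals Simulate ROI time series per subject
#'   (default TRUE; matrix-only cohorts are much faster for replicated
#'   calibration studies).
#'
#' @details
#' The two paths plant their effect differently.  The matrix path
#' (`generate_signals = FALSE`) uses the graded, calibrated degree
#' machinery described under [cohort_spec()].  The signal path cannot:
#' phase synchronization is transitive, so an arbitrary suprathreshold
#' edge pattern is not realisable as a phase-increment correlation
#' structure, and graded couplings below ~0.99 wash out over a minute of
#' phase diffusion.  Signal-level cohorts therefore use a module
#' design — ROIs partitioned into near-clique coupling modules of ~5
#' nodes (within-module increment correlation 0.995, between-module 0),
#' which PLV recovers cleanly — and the planted effect is a decoupling
#' of the target nodes from their module in the old group (active
#' whenever `effect_size_d > 0`; the deficit is all-or-none at each
#' target, a deliberately strong demonstration effect rather than a
#' calibrated one).  The structural layer keeps the target nodes'
#' module edges in both groups, so old-group target participation
#' collapses while young stays near 1.
#' @return List with `timeseries` (list of [roi_ts()] or NULL),
#'   `structural` / `functional` (lists of [conn_matrix()]), `cohort`
#'   (data frame), and `truth` (planted parameters, per-subject target
#'   degrees and participation).
#' @export
gen_cohort <- function(ospec, cspec, generate_signals = TRUE) {
  stopifnot(inherits(ospec, "oscillator_spec"),
            inherits(cspec, "cohort_spec"))
  if (ospec$n_rois != cspec$n_rois) stop("n_rois mismatch between specs")
  n <- cspec$n_rois
  labels <- make_roi_labels(n)
  n_sub <- cspec$n_young + cspec$n_old
  group <- rep(c("young", "old"), c(cspec$n_young, cspec$n_old))
  targets <- cspec$target_nodes
  n_t <- length(targets)
  shift <- cspec$degree_shift
  with_seed(cspec$seed, {
    is_old <- group == "old"
    gamma <- rnorm(n_sub, 0, 0.02)
    gamma[is_old] <- gamma[is_old] - cspec$structural_deficit_d * 0.02
    structural <- vector("list", n_sub)
    functional <- vector("list", n_sub)
    timeseries <- if (generate_signals) vector("list", n_sub) else NULL
    subj_seeds <- sample.int(.Machine$integer.max %/% 2, n_sub)
    iafs <- pmin(pmax(rnorm(n_sub, 10, 0.8), 8.6), 11.4)

    if (!generate_signals) {
      # graded degree-machinery plant (calibrated effect size)
      hub <- matrix(rnorm(n_sub * n_t, 0, cspec$hub_sd), n_sub, n_t)
      eps_f <- matrix(rnorm(n_sub * n_t, 0, cspec$degree_sd), n_sub, n_t)
      if (cspec$effect_mode == "alignment") {
        # group-dependent correlation of the two layers' degree noise:
        # marginals untouched, only the between-layer alignment moves
        rho <- ifelse(is_old, -cspec$alignment_rho, cspec$alignment_rho)
        eps_s <- rho * eps_f + sqrt(1 - rho^2) *
          matrix(rnorm(n_sub * n_t, 0, cspec$degree_sd), n_sub, n_t)
      } else {
        eps_s <- matrix(rnorm(n_sub * n_t, 0, cspec$degree_sd), n_sub, n_t)
      }
      kf <- round(cspec$target_degree_base + cspec$baseline_imbalance +
                    hub + eps_f + ifelse(is_old, shift / 2, 0))
      ks <- round(cspec$target_degree_base + hub + eps_s -
                    ifelse(is_old, shift / 2, 0))
      kf <- pmin(pmax(kf, 1), cspec$k_max)
      ks <- pmin(pmax(ks, 1), cspec$k_max)
      p_true <- 4 * kf * ks / (kf + ks)^2
      for (s in seq_len(n_sub)) {
        a_f <- sample_layer_edges(n, cspec$e_total, targets, kf[s, ])
        a_s <- sample_layer_edges(n, cspec$e_total, targets, ks[s, ],
                                  overlap = cspec$structural_overlap,
                                  ref = a_f)
        w_f <- weight_edges(a_f, c(0.45, 0.85), c(0.01, 0.12))
        w_s <- weight_edges(a_s, c(0.35, 0.75), c(0.005, 0.12),
                            offset = gamma[s])
        functional[[s]] <- conn_matrix(w_f, modality = "PLV",
                                       band = "alpha", labels = labels,
                                       directed = FALSE)
        structural[[s]] <- conn_matrix(w_s, modality = "FA",
                                       labels = labels, directed = FALSE)
      }
    } else {
      # module (clique) design: realisable phase-coupling structure
      module <- sort(rep_len(seq_len(ceiling(n / 5)), n))  # near-equal sizes
      within <- outer(module, module, "==")
      diag(within) <- FALSE
      clique_edges <- which(upper.tri(within) & within)
      decouple <- cspec$effect_size_d > 0
      kf <- matrix(0, n_sub, n_t)
      ks <- matrix(0, n_sub, n_t)
      for (s in seq_len(n_sub)) {
        drop_t <- decouple && is_old[s]
        a_f <- within
        if (drop_t) {
          a_f[targets, ] <- FALSE
          a_f[, targets] <- FALSE
        }
        coup <- matrix(0, n, n)
        coup[within] <- 0.995
        if (drop_t) {
          coup[targets, ] <- 0
          coup[, targets] <- 0
        }
        # structural layer: full module scaffold for everyone, plus a
        # little per-subject rewiring away from non-target module edges
        a_s <- within
        movable <- setdiff(clique_edges,
                           which((matrix(row(a_s) %in% targets, n, n) |
                                  matrix(col(a_s) %in% targets, n, n)) &
                                 upper.tri(a_s)))
        n_rw <- min(length(movable), max(1L, round(0.08 * cspec$e_total)))
        drop_e <- movable[sample.int(length(movable), n_rw)]
        a_s[drop_e] <- FALSE
        a_s[cbind(col(a_s)[drop_e], row(a_s)[drop_e])] <- FALSE
        free <- which(upper.tri(a_s) & !a_s & !within)
        need <- cspec$e_total - sum(a_s[upper.tri(a_s)])
        if (need > 0) {
          add <- free[sample.int(length(free), min(need, length(free)))]
          a_s[add] <- TRUE
          a_s[cbind(col(a_s)[add], row(a_s)[add])] <- TRUE
        }
        kf[s, ] <- vapply(targets, function(t) sum(a_f[t, -t]), numeric(1))
        ks[s, ] <- vapply(targets, function(t) sum(a_s[t, -t]), numeric(1))
        w_f <- weight_edges(a_f, c(0.45, 0.85), c(0.01, 0.12))
        w_s <- weight_edges(a_s, c(0.35, 0.75), c(0.005, 0.12),
                            offset = gamma[s])
        functional[[s]] <- conn_matrix(w_f, modality = "PLV",
                                       band = "alpha", labels = labels,
                                       directed = FALSE)
        structural[[s]] <- conn_matrix(w_s, modality = "FA",
                                       labels = labels, directed = FALSE)
        sspec <- ospec
        sspec$coupling <- coup
        sspec$iaf_hz <- iafs[s]
        sspec$seed <- subj_seeds[s]
        timeseries[[s]] <- gen_oscillators(sspec)
        timeseries[[s]]$subject_id <- sprintf("sub%03d", s)
      }
      o <- kf + ks
      p_true <- ifelse(o > 0, 4 * kf * ks / pmax(o, 1)^2, 0)
    }
    p_bar <- rowMeans(p_true)
    cohort <- data.frame(
      subject_id = sprintf("sub%03d", seq_len(n_sub)),
      group = factor(group, levels = c("young", "old")),
      age = ifelse(is_old, pmin(pmax(rnorm(n_sub, 64.5, 2.85), 60), 69),
                   pmin(pmax(rnorm(n_sub, 26.5, 2.01), 22), 29)),
      sex = sample(c("F", "M"), n_sub, replace = TRUE, prob = c(29, 17)),
      education = ifelse(is_old, rnorm(n_sub, 19.1, 3.262),
                         rnorm(n_sub, 22.2, 2.873)),
      grey_matter_volume = ifelse(is_old, rnorm(n_sub, 560, 45),
                                  rnorm(n_sub, 620, 45)),
      total_intracranial_volume = rnorm(n_sub, 1500, 120),
      stringsAsFactors = FALSE
    )
    for (nm in names(score_moments())) {
      m <- score_moments()[[nm]]
      base <- ifelse(is_old, rnorm(n_sub, m[3], m[4]), rnorm(n_sub, m[1], m[2]))
      if (nm == cspec$cognition_score && cspec$cognition_slope != 0) {
        centre <- cspec$expected_p[["old"]]
        base[is_old] <- base[is_old] +
          cspec$cognition_slope * (p_bar[is_old] - centre)
      }
      if (nm == "MMSE") base <- pmin(round(base), 30)
      if (nm == "Hotel_Num_rows") base <- pmin(pmax(base, 0), 5)
      if (nm == "Hotel_Time") base <- pmax(base, 30)
      cohort[[nm]] <- base
    }
    list(
      timeseries = timeseries, structural = structural,
      functional = functional, cohort = cohort,
      truth = list(target_nodes = targets, degree_shift = shift,
                   expected_p = cspec$expected_p, kf = kf, ks = ks,
                   p_target = p_true, p_bar = p_bar, iaf_hz = iafs,
                   group = group)
    )
  })
}
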