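---
title: "Methods: multiplex structure-function connectome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex structure-function connectome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplexconn)
```

## The analysis in one paragraph

`mplexconn` studies how the brain's anatomical wiring (white-matter
tracts, weighted by fractional anisotropy, FA) and its fast functional
coupling (estimated from source-level electrophysiology) relate to each
other, per region. For each subject, one structural and one functional
connectivity matrix over the same cortical parcellation (canonically the
68-region Desikan-Killiany atlas) are binarized at a common edge
density and stacked as the two layers of a multiplex network. The
per-node summary is the multiplex participation coefficient

$$p_i = \frac{M}{M-1}\left[1 - \sum_{\alpha=1}^{M}
\left(\frac{k_i^{[\alpha]}}{o_i}\right)^2\right],
\qquad o_i = \sum_\alpha k_i^{[\alpha]},$$

with $M = 2$ layers and $k_i^{[\alpha]}$ the degree of node $i$ in layer
$\alpha$: $p_i = 1$ when a node has equal degree in both layers,
$p_i = 0$ when one layer holds all of its edges. Nodal participation is
then compared between groups (young vs old), regressed against
cognition within the old group, and dichotomized by a trimmed median
split, with Benjamini-Hochberg FDR control within each analysis family.

An important subtlety, which shapes the whole synthetic-data design: for
$M = 2$ the formula reduces to $p_i = 4 k_f k_s / (k_f + k_s)^2$, a
function of the two layer *degrees* only. Two layers with completely
disjoint edge sets but equal degrees still give $p_i = 1$. The
coefficient measures degree balance across layers, not edge-wise
overlap, and planted effects must therefore act on the degree imbalance
$k_f - k_s$.

## Functional connectivity estimators

Three estimators are provided, all computed on band-limited analytic
signals:

* **PLV** (phase-locking value): $\left|\,\mathrm{mean}_t\,
  e^{i(\phi_x(t) - \phi_y(t))}\right|$. 1 for a constant phase
  difference; the null expectation for independent phases is
  $\approx\sqrt{\pi/4N}$.
* **wPLI** (weighted phase-lag index):
  $|\mathrm{mean}(\Im S_{xy})| / \mathrm{mean}(|\Im S_{xy}|)$ with
  $S_{xy}$ the per-sample cross-spectrum. Zero-lag (volume-conduction
  -like) coupling contributes no imaginary part, so instantaneous
  mixtures of one common source score 0 while a true quarter-cycle lag
  scores 1. It serves as the control analysis for PLV findings.
* **TE** (transfer entropy):
  $H(y_{t+\ell} \mid y_t) - H(y_{t+\ell} \mid y_t, x_t)$ in bits,
  estimated by plug-in entropies on uniformly amplitude-binned signals.
  Defaults: 4 bins, history 1, lag 1 — the smallest defensible
  parameterisation, all config-exposed. TE is computed on the
  band-limited real signal (not phase alone), because information
  transfer here is meant at the signal level. The plug-in estimator is
  biased upward by roughly $(B-1)^2 B / (2N\ln 2)$ bits for independent
  series; tests compare against a permutation null rather than absolute
  zero. The directed TE matrix is reduced to nodal *inward* (column)
  and *outward* (row) profiles — receiver vs sender roles.

## Spectral pipeline

The individual alpha frequency (IAF) anchors all band edges: delta
(IAF−8, IAF−6), theta (IAF−6, IAF−2), alpha (IAF−2, IAF+2), beta
(IAF+2, IAF+14), gamma (IAF+15, IAF+80). The printed beta/gamma gap
(IAF+14 to IAF+15) is kept verbatim; no band covers it. The IAF itself
is detected as the mean, over a configurable occipital-plus-parietal ROI
subset, of the largest Welch-periodogram peak in a 7-13 Hz search
range; a peak must be a strict local maximum at least twice the
in-range median power, and input with no qualifying peak raises a "no
alpha peak" error rather than returning the range edge. Sensor-level
peak detection (as performed on magnetometers and gradiometers in the
original acquisition setting) is out of scope, so the ROI-subset rule is
a documented surrogate with the same physiological target. Welch
segments are sized for at most 0.25 Hz resolution.

Within-ROI source time courses are reduced to the first principal
component (sign-aligned with the mean signal) rather than the mean, to
limit signal leakage. Band-pass filtering uses a zero-phase
forward-backward Hamming-windowed FIR of order ≈ 3 cycles of the low
band edge; 3 cycles are trimmed from each end before the FFT-based
analytic signal is taken. A per-frequency cycle table is deliberately
not reproduced; the fixed FIR design replaces it.

## Multiplex construction

Weighted matrices are binarized by retaining exactly
$\lfloor \rho \cdot E_{max} \rfloor$ strongest edges ($E_{max}$ =
unordered pairs for undirected, ordered pairs for directed matrices),
with ties broken by lexicographic node-pair order — deterministic and
scale invariant. The default density is 22%, the minimum structural
density observed in the reference older cohort (for 68 nodes:
$\lfloor 0.22 \cdot 2278\rfloor = 501$ edges); a run can instead
recompute the minimum from a designated group's structural layers,
using a tract-presence threshold (default FA > 0.2) to decide which
entries count. Flooring never exceeds the observed minimum. Both
layers of every multiplex share one density; isolated nodes
($o_i = 0$, a 0/0 in the formula) are assigned $p_i = 0$ — an isolated
node participates in no layer.

For a directed TE layer the matrix is thresholded over its $n(n-1)$
ordered pairs first, then nodal functional degree counts suprathreshold
couplings toward (inward) or from (outward) each node, against the
undirected structural degree — threshold-then-split. The alternative
order (split first) was considered; threshold-then-split was chosen
because it keeps the matched-density constraint defined on one object
(the full directed matrix) and is isolated behind `direction_mode` so
the sensitivity of any result to this choice can be checked directly.

## Statistical workflow

"t-tests controlling covariates" is operationalized as the group term
of `metric ~ group + covariates` (a t-test cannot carry covariates);
with no covariates this reduces exactly to the classical pooled
two-sample t. Summary-statistic t-tests reproduce printed demographic
contrasts. Cognition regressions in the old group report the partial
Pearson correlation given covariates, or a Spearman correlation on
covariate-residualized values for non-continuous scores (MMSE). The
trimmed median split removes the `n_remove_per_side` subjects nearest
the median on each side (4 per side for a 46-subject group, leaving 19
per subgroup); ties resolve deterministically by (value, subject id),
and odd-sized groups are refused rather than silently imbalanced.
Young-group subgroups are computed but excluded from inference by
default (they were treated as a single group in the reference
analysis). BH-FDR is applied within each analysis family — regions of
one contrast type, scores of one regression step — at q = 0.05.

## What the synthetic-data generator emulates

The generator exists because the real inputs (10-min eyes-closed
resting MEG at 1 kHz, FA matrices from diffusion imaging, neuropsych
scores) are restricted-access; no generative model is given by the
reference analysis, so every choice here is a documented stand-in.

**Signals.** Unit-amplitude oscillators at a per-subject alpha
frequency (drawn N(10, 0.8) Hz, clamped to 8.6-11.4) whose phases are
correlated Wiener processes: increment correlation = the coupling
matrix, phase diffusion 20 rad²/s (a realistic single-digit-Hz
linewidth; uncoupled pairs decorrelate within seconds, fully coupled
pairs keep an exactly constant phase difference, so PLV ground truth is
analytic in the coupling). Pairwise phase-lag targets are realised as
per-node offsets solved by coupling-weighted least squares — an
inconsistent pairwise lag pattern is satisfied only in the least-squares
sense. Directed influence adds a lagged linear term
$\beta\,x_i(t-\ell)$ to the receiver, so TE ground truth is nonzero
exactly where influence is planted. White observation noise is added
last. Default test scale is 20 ROIs, 60 s at 250 Hz (the full
68-ROI/10-min/1-kHz setting is supported but not exercised routinely).

**Matrices and planted effects.** Both layers' suprathreshold edge sets
are constructed directly with controlled target-node degrees, then
weighted in disjoint on/off bands (FA-like 0.35-0.75 vs < 0.12 noise
floor) so density thresholding recovers the planted sets exactly. Three
effect mechanisms are available:

* *degree_shift* (default): the old group receives opposite half-shifts
  of functional and structural target degree. The shift is calibrated
  numerically (quadrature over a per-node "hubness" factor shared by
  both layers × exact enumeration of the rounded, clamped degree
  distributions) so that the expected participation difference equals
  `effect_size_d` pooled SDs — Cohen's d convention. The hubness factor
  cancels in the degree imbalance but inflates unimodal degree
  variance.
* *alignment*: the two layers' degree noises are correlated
  `+alignment_rho` in young and `-alignment_rho` in old. Each layer's
  marginal degree distribution is then *identical* across groups, so
  unimodal contrasts are null by construction, while the imbalance
  variance — hence participation — differs: a strictly multiplex-only
  effect. The achievable standardized effect is bounded near 1, so this
  mode is parameterised by the correlation, not by `effect_size_d`.
* *structural_deficit_d*: a global old-group shift of structural edge
  weights, a purely unimodal effect that the single-modality baseline
  should (and does) detect.

Cognition scores are Gaussian with group means/SDs mimicking the
printed cohort table (MMSE rounded and capped at 30); the planted score
adds `cognition_slope ×` (mean target participation, centred) in the
old group only.

**Signal-level cohorts** cannot carry the graded plant: phase
synchronization is transitive, so an arbitrary suprathreshold edge
pattern is not realisable as a phase-increment correlation structure
(it is not positive semi-definite), and couplings much below 0.99 wash
out over a minute of phase diffusion. Signal cohorts therefore use a
module design — ROIs partitioned into near-clique coupling modules of
about 5 nodes (within-module increment correlation 0.995), which PLV
recovers cleanly at 22% density — and the planted deficit decouples the
old group's target nodes from their module entirely. This is an
all-or-none demonstration effect; decoupling also lowers the module
partners' functional degree, so detections are expected within the
whole target module.

**What passing tests do and do not show.** The replicated calibration
suites (type-I after FDR, power at d = 1.2, slope recovery,
multiplex-only invisibility; 200/200/25/40 replicates at 46+46 subjects
and 20 ROIs) run on the matrix path — they validate the multiplex and
statistical machinery against planted truth, with estimator calibration
(PLV/wPLI/TE on controlled inputs) and one full signal-to-statistics
run tested separately. Replicating the signal chain inside the
calibration loops would cost hours of compute for no additional
inferential content; the problem sizes above are the package's chosen
test scale. None of this shows that real MEG/DWI data meet the
generator's assumptions (stationary narrowband oscillators, exact
planted edge sets, Gaussian scores); results on real cohorts depend on
preprocessing choices that are out of scope here.

## Numerical choices and degenerate inputs

* Edge-count rounding: floor, never exceeding the target density; ties
  at the cut broken lexicographically.
* `p_i` clipped to [0, 1] against floating-point drift; `o_i = 0` gives
  `p_i = 0`.
* PLV refuses inputs with more than 1% zero-amplitude samples (phase
  undefined); wPLI returns 0 with a "zero-lag only" warning when every
  imaginary cross-spectral part vanishes.
* TE refuses series shorter than 5 states per cell of its
  `(bins)^(2·history+1)` contingency table ("underdetermined
  estimate"); identical constant series give exactly 0.
* The coupling matrix is eigenvalue-clipped to the nearest correlation
  matrix only when truly indefinite; merely singular structures (fully
  coupled pairs) are kept exact.
* Odd-sized groups, constant metrics, rank-deficient covariate designs
  and out-of-Nyquist bands raise immediate errors naming the problem.

## Known limitations

* The participation coefficient's blindness to edge identity (degrees
  only) is inherited from its definition; an edge-overlap statistic
  would be a different metric and is not provided.
* The inward/outward aggregation rule for TE and the
  binarize-before-or-after-split order are not uniquely determined by
  the reference description; defaults are stated above and both knobs
  are exposed.
* IAF detection on source-space ROI subsets approximates, but is not,
  sensor-space peak averaging.
* No wavelet/multitaper spectral alternatives, no >2-layer multiplexes,
  no weighted multiplex metrics, no permutation-based network
  statistics.
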