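Package: mplexconn
Title: Multiplex Structure-Function Brain Connectome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing two-layer multiplex brain
    networks that fuse structural connectivity (white-matter fractional
    anisotropy) with band-limited functional connectivity estimated from
    source-level electrophysiological time series.  Provides individual
    alpha frequency (IAF) detection and IAF-anchored band definitions,
    analytic-signal extraction, phase-locking value (PLV), weighted
    phase-lag index (wPLI) and transfer entropy (TE) estimators,
    density-matched binarization, the multiplex participation coefficient
    and layer-degree metrics, and the accompanying group/subgroup
    statistical workflow (covariate-adjusted contrasts, median-split
    subgrouping, cognition regressions, Benjamini-Hochberg FDR).  A
    synthetic-data module generates oscillatory cohorts with planted
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
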