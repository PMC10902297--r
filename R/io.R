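# Text-based file formats: square tab-separated matrices with label
# header row and column, comma-separated cohort and results tables,
# YAML run configuration.  All numeric output uses 12 significant
# digits so round-trips are lossless at analysis precision.

#' Write a connectivity matrix as a tab-separated file
#'
#' Square TSV with the ROI labels as both header row and first column;
#' modality, band and directedness are stored in `#`-prefixed comment
#' lines so the file round-trips through [read_conn_matrix()].
#'
#' @param m A [conn_matrix()].
#' @param path Output path.
#' @export
write_conn_matrix <- function(m, path) {
  stopifnot(inherits(m, "conn_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# modality: %s", m$modality), con)
  writeLines(sprintf("# band: %s", m$band), con)
  writeLines(sprintf("# directed: %s", if (m$directed) "true" else "false"),
             con)
  writeLines(paste(c("label", m$labels), collapse = "\t"), con)
  v <- format(m$values, digits = 12, scientific = FALSE, trim = TRUE)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(c(m$labels[i], v[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a connectivity matrix from a tab-separated file
#'
#' Counterpart of [write_conn_matrix()].  Also accepts plain labelled
#' TSV matrices without comment headers (modality then defaults to
#' `"FA"`).  Errors on non-square tables, mismatched row/column labels,
#' and non-numeric cells.
#'
#' @param path Input path.
#' @param modality,band,directed Overrides for files without metadata
#'   comments.
#' @return A [conn_matrix()].
#' @export
read_conn_matrix <- function(path, modality = NULL, band = NULL,
                             directed = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getmeta <- function(key, default) {
    hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
    else default
  }
  if (is.null(modality)) modality <- getmeta("modality", "FA")
  if (is.null(band)) band <- getmeta("band", "broadband")
  if (is.null(directed)) directed <- identical(getmeta("directed", "false"),
                                               "true")
  body <- lines[!grepl("^#", lines)]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  row_labels <- tab[[1]]
  col_labels <- colnames(tab)[-1]
  if (length(row_labels) != length(col_labels)) {
    stop("non-square matrix: ", length(row_labels), " rows vs ",
         length(col_labels), " columns")
  }
  if (!identical(row_labels, col_labels)) {
    stop("label mismatch between header row and label column")
  }
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1])), nrow = length(row_labels)))
  if (anyNA(vals)) stop("non-numeric cells in matrix body")
  conn_matrix(vals, modality = modality, band = band, labels = row_labels,
              directed = directed)
}

#' Write one subject's ROI time series
#'
#' Tab-separated samples x ROI table (header = ROI labels) plus a small
#' YAML sidecar `<path>.meta.yaml` with sampling rate, subject id and
#' the simulation's true IAF when known.
#'
#' @param ts A [roi_ts()].
#' @param path Output path for the TSV.
#' @export
write_roi_ts <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  write.table(format(ts$data, digits = 12, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = ts$labels)
  meta <- list(fs_hz = ts$fs_hz, subject_id = ts$subject_id,
               iaf_hz_true = if (is.na(ts$iaf_hz)) NULL else ts$iaf_hz)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read one subject's ROI time series
#'
#' @param path TSV path written by [write_roi_ts()]; the sidecar
#'   `<path>.meta.yaml` must exist (it carries the sampling rate).
#' @return A [roi_ts()].
#' @export
read_roi_ts <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  roi_ts(as.matrix(tab), fs_hz = meta$fs_hz,
         iaf_hz = if (is.null(meta$iaf_hz_true)) NA_real_
                  else meta$iaf_hz_true,
         subject_id = if (is.null(meta$subject_id)) NA_character_
                      else meta$subject_id)
}

#' Write / read the cohort table
#'
#' Comma-separated with one row per subject; the column dictionary is
#' documented in the package vignette.
#'
#' @param cohort Data frame as produced by [gen_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the data frame with `group` restored
#'   as a young/old factor.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if ("group" %in% names(tab)) {
    tab$group <- factor(tab$group, levels = c("young", "old"))
  }
  tab
}

#' Run configuration
#'
#' Assembles and validates the configuration consumed by
#' [run_pipeline()]: every analysis decision (band scheme, modality,
#' TE parameters, density rule, direction mode, covariates, FDR level,
#' seeds) is a named field, and configurations round-trip through YAML
#' (`load(save(c)) = c`).
#'
#' @param simulate List of simulation parameters (passed to
#'   [oscillator_spec()] / [cohort_spec()]), or NULL to read inputs
#'   from `input_dir`.
#' @param modality Functional modality: `"PLV"`, `"wPLI"`, or `"TE"`.
#' @param band Band to analyse (default `"alpha"`).
#' @param iaf_search IAF search range (default c(7, 13)).
#' @param te_params List: `history`, `lag`, `n_bins`.
#' @param density_rule `"fixed"` (use `density`) or `"min_old_structural"`
#'   (recompute the minimum structural density of the old group, the
#'   reference study's rule).
#' @param density Fixed density value (default 0.22).
#' @param density_threshold FA weight above which a tract counts as
#'   present when recomputing the group minimum density (default 0.2).
#' @param direction_mode `"undirected"`, `"inward"`, or `"outward"`.
#' @param covariates Covariate column names for the group contrasts.
#' @param fdr_q FDR level (default 0.05).
#' @param seed Master seed.
#' @param input_dir,output_dir Paths (output_dir NULL = keep results in
#'   memory only).
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = list(), modality = "PLV", band = "alpha",
                       iaf_search = c(7, 13),
                       te_params = list(history = 1, lag = 1, n_bins = 4),
                       density_rule = c("fixed", "min_old_structural"),
                       density = 0.22, density_threshold = 0.2,
                       direction_mode = c("undirected", "inward", "outward"),
                       covariates = character(), fdr_q = 0.05, seed = 1L,
                       input_dir = NULL, output_dir = NULL) {
  density_rule <- match.arg(density_rule)
  direction_mode <- match.arg(direction_mode)
  if (!modality %in% c("PLV", "wPLI", "TE")) stop("unknown modality")
  if (modality != "TE" && direction_mode != "undirected") {
    stop("direction_mode applies to TE only")
  }
  structure(
    list(simulate = simulate, modality = modality, band = band,
         iaf_search = iaf_search, te_params = te_params,
         density_rule = density_rule, density = density,
         density_threshold = density_threshold,
         direction_mode = direction_mode, covariates = covariates,
         fdr_q = fdr_q, seed = as.integer(seed),
         input_dir = input_dir, output_dir = output_dir),
    class = "run_config"
  )
}

#' Save / load a run configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$iaf_search <- as.numeric(unlist(raw$iaf_search))
  raw$covariates <- as.character(unlist(raw$covariates))
  do.call(run_config, raw)
}
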