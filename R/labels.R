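#' Desikan-Killiany cortical ROI labels
#'
#' The 68 cortical region labels of the Desikan-Killiany atlas (34 per
#' hemisphere, prefixed `lh.` / `rh.`), the parcellation used for the
#' source-level connectome.
#'
#' @return Character vector of length 68.
#' @export
#' @examples
#' head(dk_labels())
dk_labels <- function() {
  regions <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal"
  )
  c(paste0("lh.", regions), paste0("rh.", regions))
}

#' Occipital and parietal ROI labels
#'
#' Subset of [dk_labels()] covering occipital and parietal cortex; the
#' default region set over which the individual alpha frequency is
#' detected (the alpha rhythm is strongest over occipitoparietal cortex).
#'
#' @return Character vector (both hemispheres).
#' @export
occipitoparietal_labels <- function() {
  regions <- c(
    "cuneus", "lateraloccipital", "lingual", "pericalcarine",
    "inferiorparietal", "superiorparietal", "supramarginal", "precuneus",
    "postcentral"
  )
  c(paste0("lh.", regions), paste0("rh.", regions))
}

# Generic labels for simulated parcellations smaller than the full atlas.
make_roi_labels <- function(n_rois) {
  if (n_rois == 68L) dk_labels() else sprintf("ROI%03d", seq_len(n_rois))
}
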