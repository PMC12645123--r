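#' Desikan-Killiany cortical parcellation with lobe assignments
#'
#' Returns the 68-region cortical parcellation (34 regions per hemisphere)
#' used as the default region-of-interest scheme, together with the lobe
#' each region is assigned to. The lobe allocation places 18 regions in the
#' temporal lobes, 14 in the parietal lobes (including the pre- and
#' paracentral cortex), 10 in the cingulate division (including the
#' insula), 8 in the occipital lobes, and 18 in the frontal lobes.
#'
#' @return A data.frame with columns `roi` (integer id, 1-68), `name`
#'   (e.g. `"lh.fusiform"`), `hemisphere` (`"lh"`/`"rh"`), and `lobe`.
#' @examples
#' table(dk_atlas()$lobe)
#' @export
dk_atlas <- function() {
  regions <- c(
    bankssts = "temporal",
    caudalanteriorcingulate = "cingulate",
    caudalmiddlefrontal = "frontal",
    cuneus = "occipital",
    entorhinal = "temporal",
    frontalpole = "frontal",
    fusiform = "temporal",
    inferiorparietal = "parietal",
    inferiortemporal = "temporal",
    insula = "cingulate",
    isthmuscingulate = "cingulate",
    lateraloccipital = "occipital",
    lateralorbitofrontal = "frontal",
    lingual = "occipital",
    medialorbitofrontal = "frontal",
    middletemporal = "temporal",
    paracentral = "parietal",
    parahippocampal = "temporal",
    parsopercularis = "frontal",
    parsorbitalis = "frontal",
    parstriangularis = "frontal",
    pericalcarine = "occipital",
    postcentral = "parietal",
    posteriorcingulate = "cingulate",
    precentral = "parietal",
    precuneus = "parietal",
    rostralanteriorcingulate = "cingulate",
    rostralmiddlefrontal = "frontal",
    superiorfrontal = "frontal",
    superiorparietal = "parietal",
    superiortemporal = "temporal",
    supramarginal = "parietal",
    temporalpole = "temporal",
    transversetemporal = "temporal"
  )
  data.frame(
    roi = seq_len(68L),
    name = c(paste0("lh.", names(regions)), paste0("rh.", names(regions))),
    hemisphere = rep(c("lh", "rh"), each = 34L),
    lobe = rep(unname(regions), 2L),
    stringsAsFactors = FALSE
  )
}

#' Default region-to-lobe map
#'
#' @param n_rois Number of regions. For 68 the Desikan-Killiany lobe
#'   assignment of [dk_atlas()] is returned; otherwise regions are split
#'   into five contiguous lobes of proportional size (a configurable
#'   stand-in for reduced synthetic parcellations).
#' @return Character vector of length `n_rois`, lobe per region id.
#' @export
default_lobe_map <- function(n_rois = 68L) {
  if (n_rois == 68L) return(dk_atlas()$lobe)
  lobes <- c("temporal", "parietal", "cingulate", "occipital", "frontal")
  props <- c(18, 14, 10, 8, 18) / 68
  sizes <- diff(round(cumsum(c(0, props)) * n_rois))
  sizes[length(sizes)] <- n_rois - sum(sizes[-length(sizes)])
  rep(lobes, times = sizes)
}

#' Region ids of AD-vulnerable temporal regions
#'
#' The bilateral middle temporal, fusiform, parahippocampal, and entorhinal
#' cortices: the regions where early Alzheimer-type neurodegeneration is
#' expected and where the synthetic cohort concentrates its diffusivity
#' elevation by default.
#'
#' @return Integer vector of 8 region ids in the 68-region scheme.
#' @export
dk_ad_roi_ids <- function() {
  atlas <- dk_atlas()
  targets <- c("middletemporal", "fusiform", "parahippocampal", "entorhinal")
  sort(atlas$roi[sub("^(lh|rh)\\.", "", atlas$name) %in% targets])
}
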