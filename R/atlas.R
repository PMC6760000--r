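#' Neonatal white-matter region vocabulary
#'
#' The 99-region vocabulary used for regional DTI features: 48 bilateral
#' regions (each with a left and right label) plus the genu, splenium and
#' body of the corpus callosum. Region labels follow the JHU neonatal
#' parcellation naming; bilateral regions are prefixed `"L "` or `"R "`.
#'
#' @return A character vector of 99 region labels.
#' @export
#' @examples
#' length(dti_atlas())  # 99
dti_atlas <- function() {
  bilateral <- c(
    "Amygdala", "Angular gyrus", "Anterior corona radiata",
    "Anterior limb of the internal capsule", "Caudate nucleus",
    "Cingular part of cingulum", "Cingulum gyrus", "Cuneus",
    "External capsule", "Fornix", "Frontal medial orbital gyrus",
    "Fusiform gyrus", "Globus pallidus", "Gyrus rectus",
    "Hippocampal part of the cingulum", "Hippocampus",
    "Inferior frontal gyrus", "Inferior fronto-occipital fasciculus",
    "Inferior occipital gyrus", "Inferior temporal gyrus",
    "Insular cortex", "Lateral orbitofrontal gyrus", "Lingual gyrus",
    "Middle frontal gyrus", "Middle occipital gyrus",
    "Middle temporal gyrus", "Parahippocampal gyrus",
    "Postcentral gyrus", "Posterior corona radiata",
    "Posterior limb of the internal capsule",
    "Posterior thalamic radiation", "Precentral gyrus", "Precuneus",
    "Putamen", "Retrolenticular capsule", "Sagittal stratum",
    "Stria terminalis", "Superior corona radiata",
    "Superior frontal gyrus", "Superior longitudinal fasciculus",
    "Superior occipital gyrus", "Superior occipitofrontal fasciculus",
    "Superior parietal gyrus", "Superior temporal gyrus",
    "Supramarginal gyrus", "Tapetum", "Thalamus", "Uncinate fasciculus"
  )
  cc <- c(
    "Genu of the corpus callosum",
    "Splenium of the corpus callosum",
    "Body of corpus callosum"
  )
  c(as.vector(rbind(paste("L", bilateral), paste("R", bilateral))), cc)
}

#' DTI scalar metrics
#'
#' The four tensor-derived scalar metrics used as regional features:
#' fractional anisotropy (FA, dimensionless in \[0, 1\]), mean diffusivity
#' (MD), axial diffusivity (AD) and radial diffusivity (RD), the
#' diffusivities in mm^2/s.
#'
#' @return Character vector `c("FA", "MD", "AD", "RD")`.
#' @export
dti_metrics <- function() c("FA", "MD", "AD", "RD")

#' Build or parse feature identifiers
#'
#' Features are identified as `"<region>:<metric>"`, e.g.
#' `"R Inferior frontal gyrus:FA"`. `feature_id()` builds identifiers from
#' region and metric; `parse_feature_id()` splits them back into a tibble.
#'
#' @param region Character vector of region labels.
#' @param metric Character vector of metrics (recycled), each one of
#'   `dti_metrics()`.
#' @return `feature_id()`: a character vector of identifiers.
#'   `parse_feature_id()`: a tibble with columns `feature`, `region`,
#'   `metric`.
#' @export
#' @examples
#' feature_id("Genu of the corpus callosum", "MD")
feature_id <- function(region, metric) {
  bad <- setdiff(unique(metric), dti_metrics())
  if (length(bad) > 0) {
    abort(paste0("Unknown DTI metric(s): ", paste(bad, collapse = ", ")))
  }
  paste0(region, ":", metric)
}

#' @rdname feature_id
#' @param feature Character vector of `"<region>:<metric>"` identifiers.
#' @export
parse_feature_id <- function(feature) {
  has_colon <- grepl(":", feature, fixed = TRUE)
  if (any(!has_colon)) {
    abort(paste0(
      "Feature name(s) not of the form '<region>:<metric>': ",
      paste(feature[!has_colon], collapse = ", ")
    ))
  }
  region <- sub(":[^:]*$", "", feature)
  metric <- sub("^.*:", "", feature)
  tibble::tibble(feature = feature, region = region, metric = metric)
}

# Full region x metric feature grid, region-major (all four metrics of a
# region are adjacent), in canonical order.
feature_grid <- function(regions = dti_atlas(), metrics = dti_metrics()) {
  as.vector(vapply(
    regions,
    function(r) feature_id(r, metrics),
    character(length(metrics))
  ))
}
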