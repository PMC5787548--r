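# Closed taxonomy of measurement keys. A key identifies one measured quantity:
# atlas region, hemisphere, morphometric parameter and variant (raw values,
# head-size / scanner normalized values, or interhemispheric asymmetry index).

#' Morphometric parameter taxonomy
#'
#' The closed set of per-region parameters the pipeline models: the nine
#' surface-based cortical measures (mean/SD of thickness, surface area,
#' cortical gray-matter volume, mean and Gaussian curvature, curvature and
#' folding index, gray-white contrast), volume segmentations, whole-brain
#' partial volume estimates, lesion volume and clinical scores. Unknown
#' parameter names are rejected at load time.
#'
#' @return Character vector of valid parameter names.
#' @export
#' @examples
#' morph_parameters()
morph_parameters <- function() {
  c(
    "volume", "thickness_mean", "thickness_sd", "surface_area", "gm_volume",
    "curvature_mean", "curvature_gaussian", "curvature_index", "folding_index",
    "gw_contrast", "pve_gm", "pve_wm", "pve_csf", "pve_brain",
    "lesion_volume", "clinical_score"
  )
}

morph_hemispheres <- function() c("left", "right", "bilateral", "none")

morph_variants <- function() c("raw", "normalized", "asymmetry")

# FreeSurfer table-exporter measure suffixes -> taxonomy names
freesurfer_measure_aliases <- function() {
  c(
    thickness = "thickness_mean", thicknessstd = "thickness_sd",
    area = "surface_area", grayvol = "gm_volume", volume = "volume",
    meancurv = "curvature_mean", gauscurv = "curvature_gaussian",
    curvind = "curvature_index", foldind = "folding_index",
    pctmean = "gw_contrast"
  )
}

#' Geometric eTIV scaling exponent for a parameter
#'
#' Head-size normalization scales each parameter by a power of the ratio of
#' the reference (control-mean) estimated total intracranial volume to the
#' subject's eTIV. The exponents follow the geometric dimension of the
#' measure: volumes scale as eTIV^1, areas as eTIV^(2/3), thicknesses (radii)
#' as eTIV^(1/3); curvatures are inverse radii so the mean curvature and the
#' curvature index scale with exponent -1/3 and the Gaussian curvature and
#' folding index with -2/3. The gray-white contrast is not eTIV-scaled at all
#' but normalized to a common mean per scanner-sequence group (`NA` is
#' returned and [normalize_contrast()] applies); clinical scores are left
#' untouched (exponent 0).
#'
#' @param parameter Character vector of parameter names from
#'   [morph_parameters()].
#' @return Numeric vector of exponents (`NA` for `gw_contrast`).
#' @export
#' @examples
#' scaling_exponent("volume")        # 1
#' scaling_exponent("surface_area")  # 2/3
#' scaling_exponent("folding_index") # -2/3
scaling_exponent <- function(parameter) {
  table <- c(
    volume = 1, gm_volume = 1, pve_gm = 1, pve_wm = 1, pve_csf = 1,
    pve_brain = 1, lesion_volume = 1,
    surface_area = 2 / 3,
    thickness_mean = 1 / 3, thickness_sd = 1 / 3,
    curvature_mean = -1 / 3, curvature_index = -1 / 3,
    curvature_gaussian = -2 / 3, folding_index = -2 / 3,
    gw_contrast = NA_real_,
    clinical_score = 0
  )
  bad <- setdiff(unique(parameter), names(table))
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown morphometric parameter(s): ", paste(bad, collapse = ", "),
      ". Valid parameters: ", paste(morph_parameters(), collapse = ", ")
    ))
  }
  unname(table[parameter])
}

key_id <- function(region, hemisphere, parameter, variant) {
  paste(region, hemisphere, parameter, variant, sep = "|")
}

assert_taxonomy <- function(parameter, hemisphere = NULL) {
  bad <- setdiff(unique(parameter), morph_parameters())
  if (length(bad) > 0) {
    abort(paste0("Unknown morphometric parameter(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(hemisphere)) {
    badh <- setdiff(unique(hemisphere), morph_hemispheres())
    if (length(badh) > 0) {
      abort(paste0("Unknown hemisphere label(s): ",
                   paste(badh, collapse = ", ")))
    }
  }
  invisible(TRUE)
}
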