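# Assembly of the full 93-feature vector for one patch.

#' Feature computation settings
#'
#' @param bin_width Fixed gray-level bin width in intensity units (default 25).
#' @param n_bins Optional fixed bin count; overrides \code{bin_width}.
#' @param alpha GLDM dependence tolerance in gray levels (default 0).
#' @param voxel_volume Voxel volume in mm^3 (for firstorder.TotalEnergy).
#' @return A list of class \code{feature_settings}.
#' @export
feature_settings <- function(bin_width = 25, n_bins = NULL, alpha = 0,
                             voxel_volume = 1) {
  if (is.null(n_bins) && (!is.numeric(bin_width) || bin_width <= 0)) {
    stop("bin_width must be strictly positive")
  }
  structure(list(bin_width = bin_width, n_bins = n_bins, alpha = alpha,
                 voxel_volume = voxel_volume),
            class = "feature_settings")
}

#' Compute the full 93-feature vector of one patch
#'
#' Runs all six families on one rectangular voxel patch and concatenates the
#' values in fixed registry order. Texture families of a single-voxel patch
#' are \code{NaN}; degenerate (constant) patches yield their documented
#' conventions rather than errors.
#'
#' @param patch Numeric array (or vector) of voxel intensities.
#' @param settings A \code{\link{feature_settings}} object.
#' @return Named numeric vector of length 93, names per
#'   \code{\link{feature_registry}}.
#' @examples
#' fv <- compute_feature_vector(array(rnorm(16, 100, 20), c(4, 4, 1)))
#' length(fv)  # 93
#' @export
compute_feature_vector <- function(patch, settings = feature_settings()) {
  if (length(patch) == 0L) stop("empty patch")
  dsc <- discretize(patch, bin_width = settings$bin_width,
                    n_bins = settings$n_bins)
  c(
    stats::setNames(
      first_order_features(patch, dsc, voxel_volume = settings$voxel_volume),
      paste0("firstorder.", .FIRSTORDER_NAMES)),
    stats::setNames(glcm_features(dsc), paste0("glcm.", .GLCM_NAMES)),
    stats::setNames(gldm_features(dsc, alpha = settings$alpha),
                    paste0("gldm.", .GLDM_NAMES)),
    stats::setNames(glrlm_features(dsc), paste0("glrlm.", .GLRLM_NAMES)),
    stats::setNames(glszm_features(dsc), paste0("glszm.", .GLSZM_NAMES)),
    stats::setNames(ngtdm_features(dsc), paste0("ngtdm.", .NGTDM_NAMES))
  )
}
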