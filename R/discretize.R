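# Gray-level discretization. All texture families (and the histogram-based
# first-order features entropy/uniformity) operate on integer gray levels
# obtained by fixed-bin-width binning from the patch minimum:
#   level(x) = floor((x - min) / bin_width) + 1
# A fixed bin count mode is offered as an alternative.

#' Discretize a patch of intensities into gray levels
#'
#' Bins intensities with a fixed bin width anchored at the patch minimum
#' (default), or into a fixed number of equal-width bins spanning the patch
#' range. A constant patch always maps to the single level 1.
#'
#' @param patch Numeric vector or array of voxel intensities (non-empty, no
#'   missing values).
#' @param bin_width Positive bin width in intensity units. Ignored when
#'   \code{n_bins} is given.
#' @param n_bins Optional positive integer: discretize into exactly
#'   \code{n_bins} equal-width bins over the patch range instead.
#' @return An object of class \code{discretized_patch}: a list with
#'   \code{levels} (integer array, same shape as \code{patch}, values in
#'   \code{1..max_level}), \code{n_levels} (count of occupied levels),
#'   \code{max_level}, and \code{bin_width} (effective width used).
#' @examples
#' discretize(c(0, 24.9, 25, 50), bin_width = 25)$levels  # 1 1 2 3
#' @export
discretize <- function(patch, bin_width = 25, n_bins = NULL) {
  if (length(patch) == 0L) stop("cannot discretize an empty patch")
  if (anyNA(patch)) stop("patch contains missing intensities")
  lo <- min(patch)
  if (!is.null(n_bins)) {
    if (n_bins < 1) stop("n_bins must be a positive integer")
    rng <- max(patch) - lo
    bw <- if (rng > 0) rng / n_bins else 1
    lev <- pmin(floor((patch - lo) / bw) + 1L, as.integer(n_bins))
  } else {
    if (!is.numeric(bin_width) || bin_width <= 0) {
      stop("bin_width must be strictly positive")
    }
    bw <- bin_width
    lev <- floor((patch - lo) / bw) + 1L
  }
  lev <- as.integer(lev)
  dim(lev) <- dim(patch)
  structure(
    list(
      levels = lev,
      n_levels = length(unique(as.vector(lev))),
      max_level = max(lev),
      bin_width = bw
    ),
    class = "discretized_patch"
  )
}

#' @export
print.discretized_patch <- function(x, ...) {
  cat("<discretized_patch> ", length(x$levels), " voxels, ",
      x$n_levels, " occupied levels (max ", x$max_level,
      "), bin width ", format(x$bin_width), "\n", sep = "")
  invisible(x)
}
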