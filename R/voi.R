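# Transfer of a lesion VOI from voxel space into map (cell) space, and
# extraction of per-feature map means over the transferred VOI. A cell joins
# the VOI when at least `overlap_threshold` of its voxels are labeled; if no
# cell reaches the threshold the transfer falls back to any-overlap so a small
# lesion still yields a reading.

#' Transfer a segmentation mask onto the cell grid
#'
#' @param mask A \code{\link{segmentation_mask}} on the grid's source volume
#'   geometry.
#' @param grid The \code{\link{cell_grid}}.
#' @param overlap_threshold Minimum labeled-voxel fraction for a cell to be
#'   included (default 0.5).
#' @return An object of class \code{transferred_voi}: logical array over the
#'   cell grid with attributes \code{threshold} and \code{fallback}.
#' @export
transfer_voi <- function(mask, grid, overlap_threshold = 0.5) {
  if (!identical(dim(mask$data), grid$vol_dim)) {
    stop("mask geometry does not match the grid's source volume")
  }
  if (sum(mask$data) == 0) stop("empty mask: no VOI to transfer")
  cid <- .voxel_cell_id(grid)
  ncell <- prod(grid$dim)
  lab <- tabulate(cid[as.vector(mask$data)], nbins = ncell)
  tot <- tabulate(cid, nbins = ncell)
  frac <- lab / tot
  sel <- frac >= overlap_threshold
  fallback <- FALSE
  if (!any(sel)) {
    sel <- lab > 0
    fallback <- TRUE
  }
  voi <- array(sel, grid$dim)
  structure(voi, class = "transferred_voi",
            threshold = overlap_threshold, fallback = fallback)
}

#' @export
print.transferred_voi <- function(x, ...) {
  cat("<transferred_voi> ", sum(x), " cells (threshold ",
      attr(x, "threshold"),
      if (isTRUE(attr(x, "fallback"))) ", any-overlap fallback" else "",
      ")\n", sep = "")
  invisible(x)
}

#' Extract per-feature map means over a transferred VOI
#'
#' The arithmetic mean of each map over the VOI cells, skipping \code{NaN}
#' cells; a feature whose VOI cells are all \code{NaN} yields \code{NaN}.
#'
#' @param stack A \code{\link{compute_maps}} result.
#' @param voi A \code{\link{transfer_voi}} result on the same grid.
#' @return Named numeric vector of length 93 (registry order).
#' @export
extract_map_means <- function(stack, voi) {
  if (!identical(dim(stack$maps)[1:3], dim(unclass(voi)))) {
    stop("VOI grid does not match the map stack")
  }
  if (sum(voi) == 0) stop("empty VOI")
  sel <- as.vector(voi)
  flat <- matrix(stack$maps, nrow = prod(dim(stack$maps)[1:3]))
  vals <- flat[sel, , drop = FALSE]
  out <- colMeans(vals, na.rm = TRUE)
  out[!is.finite(out)] <- NaN       # all-NaN cells: mean over nothing
  stats::setNames(out, dimnames(stack$maps)[[4]])
}
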