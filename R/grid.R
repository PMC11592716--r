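# The cell grid: tiling of a volume into non-overlapping rectangular cells of
# a fixed physical size (default 2 x 2 x 3 mm). Original-resolution voxels are
# never resampled; each voxel is assigned to the cell containing its center,
# so every cell's voxel set is a contiguous box and the cells partition the
# volume exactly.

#' Build the cell grid of a volume
#'
#' @param volume An \code{\link{image_volume}}.
#' @param cell_size Physical cell size in mm, length-3; must be at least the
#'   voxel spacing componentwise.
#' @return An object of class \code{cell_grid}: grid dimensions, per-axis
#'   voxel-to-cell assignments, and per-axis voxel index ranges per cell.
#' @examples
#' v <- image_volume(array(0, c(64, 64, 10)), spacing = c(0.5, 0.5, 3))
#' g <- build_grid(v)         # 16 x 16 x 10 cells of 4 x 4 x 1 voxels
#' g$dim
#' @export
build_grid <- function(volume, cell_size = c(2, 2, 3)) {
  cell_size <- as.numeric(cell_size)
  if (length(cell_size) != 3L || any(cell_size <= 0)) {
    stop("cell_size must be three positive numbers (mm)")
  }
  sp <- volume$spacing
  if (any(cell_size < sp - 1e-9)) {
    stop("cell_size must be at least the voxel spacing on every axis")
  }
  vd <- dim(volume$data)
  gd <- integer(3)
  axis_cell <- vector("list", 3)   # cell index (1-based) per voxel, per axis
  axis_ranges <- vector("list", 3) # [start, end] voxel index per cell, per axis
  for (a in 1:3) {
    centers <- (seq_len(vd[a]) - 0.5) * sp[a]
    idx <- floor(centers / cell_size[a]) + 1L
    # grid extends to the last OCCUPIED cell: a trailing sliver of extent that
    # contains no voxel center spawns no (empty) cell
    gd[a] <- as.integer(max(idx))
    axis_cell[[a]] <- as.integer(idx)
    starts <- match(seq_len(gd[a]), idx)
    ends <- vd[a] + 1L - match(seq_len(gd[a]), rev(idx))
    axis_ranges[[a]] <- cbind(start = starts, end = ends)
  }
  structure(
    list(dim = gd, cell_size = cell_size, spacing = sp, origin = volume$origin,
         vol_dim = vd, axis_cell = axis_cell, axis_ranges = axis_ranges),
    class = "cell_grid"
  )
}

#' @export
print.cell_grid <- function(x, ...) {
  cat("<cell_grid> ", paste(x$dim, collapse = " x "), " cells of ",
      paste(format(x$cell_size), collapse = " x "), " mm over a ",
      paste(x$vol_dim, collapse = " x "), "-voxel volume\n", sep = "")
  invisible(x)
}

#' Extract the voxel patch of one grid cell
#'
#' @param volume The \code{image_volume} the grid was built from.
#' @param grid A \code{cell_grid}.
#' @param cell Length-3 integer cell index (1-based).
#' @return Numeric 3D array of the cell's original-resolution voxels.
#' @export
cell_patch <- function(volume, grid, cell) {
  r <- lapply(1:3, function(a) {
    rg <- grid$axis_ranges[[a]][cell[a], ]
    seq.int(rg[1], rg[2])
  })
  volume$data[r[[1]], r[[2]], r[[3]], drop = FALSE]
}

# linear cell id (1-based) of every voxel, as a vector over the volume
.voxel_cell_id <- function(grid) {
  gd <- grid$dim
  i <- grid$axis_cell[[1]]
  j <- grid$axis_cell[[2]]
  k <- grid$axis_cell[[3]]
  io <- rep(i, times = length(j) * length(k))
  jo <- rep(rep(j, each = length(i)), times = length(k))
  ko <- rep(k, each = length(i) * length(j))
  io + (jo - 1L) * gd[1] + (ko - 1L) * gd[1] * gd[2]
}
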