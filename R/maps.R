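# Parametric feature maps: one 3D map per registry feature on the cell grid.
# Each cell's value is the feature computed on that cell's original-resolution
# voxel patch, so a map is spatially registered with the source volume at the
# grid pitch.

#' Compute the 93 parametric feature maps of a volume
#'
#' Visits every grid cell, computes the full feature vector of its patch, and
#' assembles one map per feature. Cells where a feature is undefined (e.g.
#' texture features of a single-voxel border cell) hold \code{NaN}.
#'
#' @param volume An \code{\link{image_volume}}.
#' @param grid A \code{\link{build_grid}} result for this volume; built with
#'   defaults if omitted.
#' @param settings A \code{\link{feature_settings}} object. Its
#'   \code{voxel_volume} is overridden by the volume's true voxel volume.
#' @return An object of class \code{feature_map_stack}: a 4D array
#'   \code{[grid dims x 93]} with feature names on the 4th dimension, plus the
#'   grid and settings.
#' @export
compute_maps <- function(volume, grid = NULL, settings = feature_settings()) {
  if (is.null(grid)) grid <- build_grid(volume)
  if (!identical(dim(volume$data), grid$vol_dim)) {
    stop("grid was not built from this volume")
  }
  settings$voxel_volume <- prod(volume$spacing)
  gd <- grid$dim
  nms <- feature_names()
  maps <- array(NA_real_, c(gd, length(nms)),
                dimnames = list(NULL, NULL, NULL, nms))
  rx <- grid$axis_ranges[[1]]
  ry <- grid$axis_ranges[[2]]
  rz <- grid$axis_ranges[[3]]
  dat <- volume$data
  for (k in seq_len(gd[3])) {
    zs <- seq.int(rz[k, 1], rz[k, 2])
    for (j in seq_len(gd[2])) {
      ys <- seq.int(ry[j, 1], ry[j, 2])
      for (i in seq_len(gd[1])) {
        patch <- dat[seq.int(rx[i, 1], rx[i, 2]), ys, zs, drop = FALSE]
        maps[i, j, k, ] <- compute_feature_vector(patch, settings)
      }
    }
  }
  structure(list(maps = maps, grid = grid, settings = settings),
            class = "feature_map_stack")
}

#' @export
print.feature_map_stack <- function(x, ...) {
  cat("<feature_map_stack> ", dim(x$maps)[4], " maps on a ",
      paste(x$grid$dim, collapse = " x "), " cell grid (",
      paste(format(x$grid$cell_size), collapse = " x "), " mm)\n", sep = "")
  invisible(x)
}

#' Extract one named map from a stack
#'
#' @param stack A \code{feature_map_stack}.
#' @param feature Registry feature name (e.g. \code{"firstorder.Median"}).
#' @return 3D numeric array over the cell grid.
#' @export
get_map <- function(stack, feature) {
  if (!feature %in% dimnames(stack$maps)[[4]]) {
    stop("unknown feature: ", feature)
  }
  stack$maps[, , , feature]
}

#' Write a map stack as one NIfTI file per feature
#'
#' Filenames are the registry names; a JSON sidecar records the grid geometry
#' and feature settings.
#'
#' @param stack A \code{feature_map_stack}.
#' @param dir Output directory (created if missing).
#' @param gzip Write \code{.nii.gz} (default) or plain \code{.nii}.
#' @return Character vector of the files written, invisibly.
#' @export
write_maps <- function(stack, dir, gzip = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  g <- stack$grid
  files <- character(0)
  for (nm in dimnames(stack$maps)[[4]]) {
    mv <- image_volume(stack$maps[, , , nm], spacing = g$cell_size,
                       origin = g$origin)
    f <- file.path(dir, paste0(nm, ext))
    write_volume(mv, f)
    files <- c(files, f)
  }
  sidecar <- list(
    grid_dim = g$dim, cell_size_mm = g$cell_size, voxel_spacing_mm = g$spacing,
    origin_mm = g$origin, volume_dim = g$vol_dim,
    settings = list(bin_width = stack$settings$bin_width,
                    n_bins = stack$settings$n_bins,
                    alpha = stack$settings$alpha),
    features = dimnames(stack$maps)[[4]]
  )
  jf <- file.path(dir, "maps.json")
  jsonlite::write_json(sidecar, jf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, jf))
}

#' Read a map stack written by \code{\link{write_maps}}
#'
#' @param dir Directory holding the per-feature NIfTI files and sidecar.
#' @return A \code{feature_map_stack} (grid carries geometry only).
#' @export
read_maps <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "maps.json"),
                                 simplifyVector = TRUE)
  nms <- sidecar$features
  gd <- as.integer(sidecar$grid_dim)
  maps <- array(NA_real_, c(gd, length(nms)),
                dimnames = list(NULL, NULL, NULL, nms))
  ext <- if (file.exists(file.path(dir, paste0(nms[1], ".nii.gz"))))
    ".nii.gz" else ".nii"
  for (nm in nms) {
    maps[, , , nm] <- read_volume(file.path(dir, paste0(nm, ext)))$data
  }
  grid <- structure(
    list(dim = gd, cell_size = as.numeric(sidecar$cell_size_mm),
         spacing = as.numeric(sidecar$voxel_spacing_mm),
         origin = as.numeric(sidecar$origin_mm),
         vol_dim = as.integer(sidecar$volume_dim),
         axis_cell = NULL, axis_ranges = NULL),
    class = "cell_grid"
  )
  structure(list(maps = maps, grid = grid,
                 settings = feature_settings(
                   bin_width = sidecar$settings$bin_width,
                   n_bins = sidecar$settings$n_bins,
                   alpha = sidecar$settings$alpha)),
            class = "feature_map_stack")
}
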