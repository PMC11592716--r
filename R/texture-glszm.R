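# Gray-level size-zone matrix features. Zones are connected components of
# equal gray level under Chebyshev-1 connectivity (26-connected in 3D,
# 8-connected for single-slice patches). One matrix per patch (no direction
# dependence); the formula core is shared with the run-length family.

# connected components of equal gray level; returns zone label per voxel
.label_zones <- function(levels, geom) {
  n <- geom$n_voxels
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  ef <- geom$edge_from
  et <- geom$edge_to
  same <- which(levels[ef] == levels[et] & ef < et)
  for (e in same) {
    ra <- find(ef[e])
    rb <- find(et[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}

#' GLSZM features of a discretized patch
#'
#' Computes the 16 size-zone features from the matrix of (gray level, zone
#' size) counts, where a zone is a Chebyshev-connected component of equal
#' gray level.
#'
#' @param discretized A \code{discretized_patch}.
#' @return Named numeric vector of 16 features; all \code{NaN} for a
#'   single-voxel patch.
#' @export
glszm_features <- function(discretized) {
  lev <- discretized$levels
  d <- .patch_dims(lev)
  geom <- patch_geometry(d)
  if (geom$n_voxels < 2) {
    return(stats::setNames(rep(NaN, length(.GLSZM_NAMES)), .GLSZM_NAMES))
  }
  lab <- .label_zones(as.vector(lev), geom)
  zsize <- tabulate(lab)
  zidx <- which(zsize > 0)
  Z <- matrix(0, discretized$max_level, max(zsize))
  for (z in zidx) {
    g <- lev[z]                      # label root is a member voxel index
    Z[g, zsize[z]] <- Z[g, zsize[z]] + 1
  }
  .rl_features(Z, geom$n_voxels, .GLSZM_NAMES)
}
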