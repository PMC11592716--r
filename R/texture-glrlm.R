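# Gray-level run-length matrix features. Runs are maximal sequences of equal
# gray level along a lattice direction; one count matrix R(i, l) per direction,
# features computed per direction and averaged.

.glrlm_matrix <- function(levels, lines, n_levels, n_voxels) {
  # R[i, l]: number of runs of gray level i and length l
  vals <- integer(0)
  lens <- integer(0)
  for (ln in lines) {
    r <- rle(as.vector(levels[ln]))
    vals <- c(vals, r$values)
    lens <- c(lens, r$lengths)
  }
  matrix(tabulate(vals + (lens - 1L) * n_levels, nbins = n_levels * n_voxels),
         n_levels, n_voxels)
}

.rl_features <- function(R, n_voxels, prefix) {
  # shared formula core for run-length (GLRLM) and size-zone (GLSZM) matrices:
  # i indexes gray level, j run length / zone size
  Nr <- sum(R)
  iv <- seq_len(nrow(R))
  jv <- seq_len(ncol(R))
  rg <- rowSums(R)
  rj <- colSums(R)
  p <- R / Nr
  pg <- rg / Nr
  pj <- rj / Nr
  mug <- sum(iv * pg)
  muj <- sum(jv * pj)
  Wi2 <- outer(iv^2, rep(1, length(jv)))
  Wj2 <- outer(rep(1, length(iv)), jv^2)
  v <- c(
    sum(rj / jv^2) / Nr,                 # short emphasis
    sum(rj * jv^2) / Nr,                 # long emphasis
    sum(rg^2) / Nr,                      # gray-level non-uniformity
    sum(rg^2) / Nr^2,                    # ... normalized
    sum(rj^2) / Nr,                      # size non-uniformity
    sum(rj^2) / Nr^2,                    # ... normalized
    Nr / n_voxels,                       # percentage
    sum((iv - mug)^2 * pg),              # gray-level variance
    sum((jv - muj)^2 * pj),              # size variance
    .neg_plog2p(p),                      # entropy
    sum(rg / iv^2) / Nr,                 # low gray-level emphasis
    sum(rg * iv^2) / Nr,                 # high gray-level emphasis
    sum(R / (Wi2 * Wj2)) / Nr,           # short/small + low
    sum(R * Wi2 / Wj2) / Nr,             # short/small + high
    sum(R * Wj2 / Wi2) / Nr,             # long/large + low
    sum(R * Wi2 * Wj2) / Nr              # long/large + high
  )
  stats::setNames(v, prefix)
}

#' GLRLM features of a discretized patch
#'
#' Computes the 16 run-length features per direction and averages over
#' directions (all Chebyshev-1 directions that fit the patch by default).
#'
#' @param discretized A \code{discretized_patch}.
#' @param directions Optional integer matrix of directions (rows).
#' @return Named numeric vector of 16 features; all \code{NaN} for a
#'   single-voxel patch.
#' @export
glrlm_features <- function(discretized, directions = NULL) {
  lev <- discretized$levels
  d <- .patch_dims(lev)
  geom <- patch_geometry(d)
  lines_by_dir <- geom$lines
  if (!is.null(directions)) {
    lines_by_dir <- lapply(seq_len(nrow(directions)), function(r)
      .direction_lines(as.integer(directions[r, ]), d))
  }
  if (geom$n_voxels < 2 || length(lines_by_dir) == 0) {
    return(stats::setNames(rep(NaN, length(.GLRLM_NAMES)), .GLRLM_NAMES))
  }
  vals <- vapply(lines_by_dir, function(lns) {
    R <- .glrlm_matrix(lev, lns, discretized$max_level, geom$n_voxels)
    .rl_features(R, geom$n_voxels, .GLRLM_NAMES)
  }, numeric(length(.GLRLM_NAMES)))
  rowMeans(vals)
}
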