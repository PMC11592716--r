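# Gray-level dependence matrix features. The dependence of a voxel is the
# number of Chebyshev-1 neighbours whose gray level differs by at most alpha
# (default 0); border voxels simply have fewer neighbours. The matrix counts
# (gray level i, dependence d) pairs, indexed by j = d + 1.

#' GLDM features of a discretized patch
#'
#' Computes the 14 dependence features with dependence tolerance \code{alpha}.
#'
#' @param discretized A \code{discretized_patch}.
#' @param alpha Non-negative gray-level tolerance for a neighbour to count as
#'   dependent (default 0: equal levels only).
#' @return Named numeric vector of 14 features; all \code{NaN} for a
#'   single-voxel patch.
#' @export
gldm_features <- function(discretized, alpha = 0) {
  lev <- discretized$levels
  d <- .patch_dims(lev)
  geom <- patch_geometry(d)
  if (geom$n_voxels < 2) {
    return(stats::setNames(rep(NaN, length(.GLDM_NAMES)), .GLDM_NAMES))
  }
  ef <- geom$edge_from
  et <- geom$edge_to
  dep_edges <- ef[abs(lev[ef] - lev[et]) <= alpha]
  dep <- tabulate(dep_edges, nbins = geom$n_voxels)   # dependence per voxel
  jv_idx <- dep + 1L
  L <- discretized$max_level
  Jmax <- max(jv_idx)
  P <- matrix(tabulate(as.vector(lev) + (jv_idx - 1L) * L, nbins = L * Jmax),
              L, Jmax)

  N <- sum(P)
  iv <- seq_len(L)
  jv <- seq_len(Jmax)
  pg <- rowSums(P)
  pj <- colSums(P)
  p <- P / N
  mug <- sum(iv * pg / N)
  muj <- sum(jv * pj / N)
  Wi2 <- outer(iv^2, rep(1, Jmax))
  Wj2 <- outer(rep(1, L), jv^2)
  c(
    SmallDependenceEmphasis = sum(pj / jv^2) / N,
    LargeDependenceEmphasis = sum(pj * jv^2) / N,
    GrayLevelNonUniformity = sum(pg^2) / N,
    DependenceNonUniformity = sum(pj^2) / N,
    DependenceNonUniformityNormalized = sum(pj^2) / N^2,
    GrayLevelVariance = sum((iv - mug)^2 * pg / N),
    DependenceVariance = sum((jv - muj)^2 * pj / N),
    DependenceEntropy = .neg_plog2p(p),
    LowGrayLevelEmphasis = sum(pg / iv^2) / N,
    HighGrayLevelEmphasis = sum(pg * iv^2) / N,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (Wi2 * Wj2)) / N,
    SmallDependenceHighGrayLevelEmphasis = sum(P * Wi2 / Wj2) / N,
    LargeDependenceLowGrayLevelEmphasis = sum(P * Wj2 / Wi2) / N,
    LargeDependenceHighGrayLevelEmphasis = sum(P * Wi2 * Wj2) / N
  )
}
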