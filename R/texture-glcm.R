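# Gray-level co-occurrence matrix features. One symmetric, probability-
# normalized matrix per offset; the 24 feature values are computed per offset
# and averaged over offsets. Zero-variance conventions: Correlation = 1 on a
# single-level matrix; MCC = 1; log base 2 with 0*log(0) = 0.

# entropy helper: -sum p log2 p over positive entries (0 log 0 = 0)
.neg_plog2p <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# per-level-count constants reused by every GLCM evaluation of size L
.lvl_cache <- new.env(parent = emptyenv())
.lvl_const <- function(L) {
  key <- as.character(L)
  cc <- .lvl_cache[[key]]
  if (!is.null(cc)) return(cc)
  iv <- seq_len(L)
  Isum <- outer(iv, iv, "+")
  Idif <- abs(outer(iv, iv, "-"))
  # 0/1 aggregation matrices: difference / sum marginal distributions as a
  # single matrix-vector product with the flattened GLCM
  Md <- matrix(0, L, L * L)
  Md[cbind(as.vector(Idif) + 1L, seq_len(L * L))] <- 1
  Ms <- matrix(0, 2 * L - 1, L * L)
  Ms[cbind(as.vector(Isum) - 1L, seq_len(L * L))] <- 1
  cc <- list(
    iv = iv,
    IJ = outer(iv, iv),
    Isum = Isum,
    Dsq = outer(iv, iv, "-")^2,
    Md = Md,
    Ms = Ms
  )
  .lvl_cache[[key]] <- cc
  cc
}

#' Build one symmetric normalized GLCM
#'
#' Accumulates co-occurrence counts of gray levels over a single lattice
#' offset (both directions), then normalizes to probabilities.
#'
#' @param levels Integer array of gray levels (a \code{discretized_patch}'s
#'   \code{levels}).
#' @param pair List with integer index vectors \code{from}, \code{to}.
#' @param n_levels Matrix dimension (max gray level).
#' @return \code{n_levels x n_levels} matrix summing to 1.
#' @keywords internal
glcm_matrix <- function(levels, pair, n_levels) {
  a <- levels[pair$from]
  b <- levels[pair$to]
  cnt <- matrix(tabulate(a + (b - 1L) * n_levels, nbins = n_levels^2),
                n_levels, n_levels)
  cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

.glcm_one <- function(P) {
  L <- nrow(P)
  cc <- .lvl_const(L)
  iv <- cc$iv
  px <- rowSums(P)
  py <- colSums(P)
  Ng <- sum(px > 0)
  mux <- sum(iv * px)
  muy <- sum(iv * py)
  sigx2 <- sum((iv - mux)^2 * px)
  sigy2 <- sum((iv - muy)^2 * py)
  IJ <- cc$IJ
  Isum <- cc$Isum
  # difference distribution p_{x-y}(k), k = 0..L-1
  kd <- 0:(L - 1)
  Pv <- as.vector(P)
  pdv <- as.vector(cc$Md %*% Pv)
  # sum distribution p_{x+y}(k), k = 2..2L
  ks <- 2:(2 * L)
  psv <- as.vector(cc$Ms %*% Pv)

  auto <- sum(IJ * P)
  Mctr <- Isum - mux - muy
  da <- sum(kd * pdv)
  HX <- .neg_plog2p(px)
  HY <- .neg_plog2p(py)
  HXY <- .neg_plog2p(P)
  pxpy <- outer(px, py)
  pos <- P > 0
  HXY1 <- -sum(P[pos] * log2(pxpy[pos]))
  HXY2 <- .neg_plog2p(pxpy)
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))

  # maximal correlation coefficient: sqrt of second-largest eigenvalue of Q
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    Ps <- P[occ, occ, drop = FALSE]
    A <- Ps / px[occ]
    B <- sweep(Ps, 2, py[occ], "/")
    ev <- sort(Re(eigen(A %*% t(B), only.values = TRUE)$values),
               decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }

  c(
    Autocorrelation = auto,
    ClusterProminence = sum(Mctr^4 * P),
    ClusterShade = sum(Mctr^3 * P),
    ClusterTendency = sum(Mctr^2 * P),
    Contrast = sum(cc$Dsq * P),
    Correlation = if (sigx2 > 0 && sigy2 > 0)
      (auto - mux * muy) / sqrt(sigx2 * sigy2) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = .neg_plog2p(pdv),
    DifferenceVariance = sum((kd - da)^2 * pdv),
    Id = sum(pdv / (1 + kd)),
    Idm = sum(pdv / (1 + kd^2)),
    Idmn = sum(pdv / (1 + (kd / Ng)^2)),
    Idn = sum(pdv / (1 + kd / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (L > 1) sum(pdv[-1] / kd[-1]^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * psv),
    SumEntropy = .neg_plog2p(psv),
    SumSquares = sum((iv - mux)^2 * px)
  )
}

#' GLCM features of a discretized patch
#'
#' Computes the 24 co-occurrence features per lattice offset and averages the
#' per-offset values. Offsets default to every direction at Chebyshev distance
#' 1 that fits the patch (in-plane only for single-slice patches).
#'
#' @param discretized A \code{discretized_patch}.
#' @param offsets Optional integer matrix of offsets (rows = directions).
#' @return Named numeric vector of 24 features; all \code{NaN} when the patch
#'   admits no valid voxel pair.
#' @export
glcm_features <- function(discretized, offsets = NULL) {
  lev <- discretized$levels
  d <- .patch_dims(lev)
  geom <- patch_geometry(d)
  pairs <- geom$pairs
  if (!is.null(offsets)) {
    pairs <- lapply(seq_len(nrow(offsets)), function(r)
      .offset_pairs(as.integer(offsets[r, ]), d))
    pairs <- Filter(function(p) length(p$from) > 0, pairs)
  }
  if (length(pairs) == 0 || geom$n_voxels < 2) {
    return(stats::setNames(rep(NaN, length(.GLCM_NAMES)), .GLCM_NAMES))
  }
  L <- discretized$max_level
  vals <- vapply(pairs, function(p) .glcm_one(glcm_matrix(lev, p, L)),
                 numeric(length(.GLCM_NAMES)))
  rowMeans(vals)
}
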