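# Neighbouring gray tone difference matrix features. For each occupied gray
# level i: n_i voxels, p_i = n_i/N, and s_i = sum over those voxels of
# |i - mean(neighbour levels)|. Conventions for flat patches: Coarseness is
# capped at 1e6, Busyness and Strength use 0/0 = 0, Contrast is 0 when only
# one level is present.

#' NGTDM features of a discretized patch
#'
#' Computes Coarseness, Contrast, Busyness, Complexity and Strength from the
#' neighbouring gray tone difference matrix (Chebyshev-1 neighbourhood,
#' truncated at patch borders).
#'
#' @param discretized A \code{discretized_patch}.
#' @return Named numeric vector of 5 features; all \code{NaN} for a
#'   single-voxel patch.
#' @export
ngtdm_features <- function(discretized) {
  lev <- as.vector(discretized$levels)
  d <- .patch_dims(discretized$levels)
  geom <- patch_geometry(d)
  if (geom$n_voxels < 2) {
    return(stats::setNames(rep(NaN, length(.NGTDM_NAMES)), .NGTDM_NAMES))
  }
  n <- geom$n_voxels
  nb_sum <- rowsum(as.numeric(lev[geom$edge_to]), geom$edge_from,
                   reorder = FALSE)
  nb_n <- tabulate(geom$edge_from, nbins = n)
  abar <- numeric(n)
  abar[as.integer(rownames(nb_sum))] <- nb_sum[, 1]
  abar <- abar / nb_n
  diffs <- abs(lev - abar)

  L <- discretized$max_level
  ni <- tabulate(lev, nbins = L)
  si <- rowsum(diffs, lev, reorder = FALSE)
  s <- numeric(L)
  s[as.integer(rownames(si))] <- si[, 1]
  pi_ <- ni / n
  occ <- which(ni > 0)
  Ngp <- length(occ)
  iv <- seq_len(L)

  coarse_den <- sum(pi_ * s)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6

  if (Ngp > 1) {
    io <- iv[occ]
    po <- pi_[occ]
    so <- s[occ]
    D2 <- outer(io, io, "-")^2
    contrast <- sum(outer(po, po) * D2) / (Ngp * (Ngp - 1)) * sum(s) / n
    busy_den <- sum(abs(outer(io * po, io * po, "-")))
    busyness <- if (busy_den > 0) coarse_den / busy_den else 0
    ps_mat <- outer(po * so, po * so, "+") / outer(po, po, "+")
    complexity <- sum(abs(outer(io, io, "-")) * ps_mat) / n
    strength <- if (sum(s) > 0) sum(outer(po, po, "+") * D2) / sum(s) else 0
  } else {
    contrast <- 0
    busyness <- 0
    complexity <- 0
    strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
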