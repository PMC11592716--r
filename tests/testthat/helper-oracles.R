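# Independent brute-force oracles. Each reconstructs a texture matrix (or a
# statistic) by direct enumeration, deliberately sharing no code with the
# package internals it checks.

# coordinates of every voxel of a 3D array, one row per voxel
.oracle_coords <- function(d) {
  as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                        k = seq_len(d[3])))
}

# symmetric normalized GLCM by scanning all ordered voxel pairs for one offset
oracle_glcm <- function(levels, offset, n_levels) {
  d <- dim(levels)
  M <- matrix(0, n_levels, n_levels)
  co <- .oracle_coords(d)
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    q <- p + offset
    if (all(q >= 1) && all(q <= d)) {
      a <- levels[p[1], p[2], p[3]]
      b <- levels[q[1], q[2], q[3]]
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  M / sum(M)
}

# run-length counts by walking each start voxel along the direction
oracle_glrlm <- function(levels, direction, n_levels) {
  d <- dim(levels)
  R <- matrix(0, n_levels, prod(d))
  co <- .oracle_coords(d)
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    prev <- p - direction
    has_prev <- all(prev >= 1) && all(prev <= d) &&
      levels[prev[1], prev[2], prev[3]] == levels[p[1], p[2], p[3]]
    if (has_prev) next   # not a run start
    g <- levels[p[1], p[2], p[3]]
    len <- 0
    q <- p
    while (all(q >= 1) && all(q <= d) && levels[q[1], q[2], q[3]] == g) {
      len <- len + 1
      q <- q + direction
    }
    R[g, len] <- R[g, len] + 1
  }
  R
}

# recursive flood fill over equal-level Chebyshev-1 neighbours; returns the
# multiset of (gray level, zone size) pairs
oracle_zones <- function(levels) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  co <- .oracle_coords(d)
  zones <- list()
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    if (seen[p[1], p[2], p[3]]) next
    g <- levels[p[1], p[2], p[3]]
    stack <- list(p)
    seen[p[1], p[2], p[3]] <- TRUE
    size <- 0
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (s in seq_len(nrow(nb))) {
        q <- cur + nb[s, ]
        if (all(q >= 1) && all(q <= d) && !seen[q[1], q[2], q[3]] &&
            levels[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  do.call(rbind, zones)
}

# per-voxel dependence counts (neighbours within alpha gray levels)
oracle_dependence <- function(levels, alpha = 0) {
  d <- dim(levels)
  co <- .oracle_coords(d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  dep <- integer(nrow(co))
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    for (s in seq_len(nrow(nb))) {
      q <- p + nb[s, ]
      if (all(q >= 1) && all(q <= d) &&
          abs(levels[q[1], q[2], q[3]] - levels[p[1], p[2], p[3]]) <= alpha) {
        dep[r] <- dep[r] + 1L
      }
    }
  }
  dep
}

# per-voxel mean neighbour level (NGTDM A-bar)
oracle_neighbour_mean <- function(levels) {
  d <- dim(levels)
  co <- .oracle_coords(d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  out <- numeric(nrow(co))
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    vals <- c()
    for (s in seq_len(nrow(nb))) {
      q <- p + nb[s, ]
      if (all(q >= 1) && all(q <= d)) {
        vals <- c(vals, levels[q[1], q[2], q[3]])
      }
    }
    out[r] <- mean(vals)
  }
  out
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  u_of <- function(ix) {
    a <- vals[ix]
    b <- vals[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(length(vals), n1)
  us <- apply(combs, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# paired permutation test of the AUC difference (A/B swap per patient)
oracle_delong_permutation <- function(scores_a, scores_b, labels, n_perm,
                                      seed = 1) {
  auc_of <- function(s) {
    pos <- s[labels == "csPCa"]
    neg <- s[labels != "csPCa"]
    (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
  }
  d_obs <- auc_of(scores_a) - auc_of(scores_b)
  set.seed(seed)
  d_perm <- replicate(n_perm, {
    swap <- runif(length(scores_a)) < 0.5
    sa <- ifelse(swap, scores_b, scores_a)
    sb <- ifelse(swap, scores_a, scores_b)
    auc_of(sa) - auc_of(sb)
  })
  mean(abs(d_perm) >= abs(d_obs) - 1e-12)
}

# random integer-level patch for matrix-equality checks
random_level_patch <- function(dims, n_levels, seed) {
  set.seed(seed)
  array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
}

# small helper: a discretized_patch directly from integer levels
as_discretized <- function(levels) {
  structure(list(levels = levels, n_levels = length(unique(as.vector(levels))),
                 max_level = max(levels), bin_width = 1),
            class = "discretized_patch")
}
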