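# Lattice geometry of a rectangular patch, cached per shape. Texture families
# share three structures: ordered voxel-pair index vectors per offset (GLCM),
# maximal lines per direction (GLRLM), and the symmetric Chebyshev-1 neighbour
# edge list (GLSZM connectivity, GLDM dependence counts, NGTDM neighbourhoods).
# Offsets are all unique directions at Chebyshev distance 1 that fit the patch:
# axes of extent 1 are dropped, so single-slice cells degenerate to the in-plane
# 2D set (4 offset pairs / 4 run directions), matching the quasi-2D cells that
# a 2 x 2 x 3 mm grid produces on 3 mm slices.

.geom_cache <- new.env(parent = emptyenv())

# 13 unique 3D directions at Chebyshev distance 1 (one of each +/- pair)
.all_offsets_3d <- function() {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  keep <- apply(off, 1, function(o) {
    o[o != 0][1] > 0   # canonical representative of each +/- pair
  })
  as.matrix(off[keep, , drop = FALSE])
}

.patch_dims <- function(patch) {
  d <- dim(patch)
  if (is.null(d)) d <- c(length(patch), 1L, 1L)
  if (length(d) == 2L) d <- c(d, 1L)
  as.integer(d)
}

# offsets that connect at least one voxel pair inside a patch of dims d
.valid_offsets <- function(d) {
  off <- .all_offsets_3d()
  ok <- apply(off, 1, function(o) all(abs(o) < d))
  off[ok, , drop = FALSE]
}

.linidx <- function(i, j, k, d) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]

# all (from, to) linear-index pairs for one offset within dims d
.offset_pairs <- function(o, d) {
  lo <- pmax(1L, 1L - o)
  hi <- pmin(d, d - o)
  if (any(hi < lo)) return(list(from = integer(0), to = integer(0)))
  i <- seq.int(lo[1], hi[1])
  j <- seq.int(lo[2], hi[2])
  k <- seq.int(lo[3], hi[3])
  g <- expand.grid(i = i, j = j, k = k)
  from <- .linidx(g$i, g$j, g$k, d)
  to <- .linidx(g$i + o[1], g$j + o[2], g$k + o[3], d)
  list(from = as.integer(from), to = as.integer(to))
}

# maximal lines along direction o: list of integer vectors of voxel indices,
# ordered along the direction
.direction_lines <- function(o, d) {
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  co <- as.matrix(g)
  # steps back to the line start along each moving axis
  t_back <- rep(.Machine$integer.max, nrow(co))
  for (a in 1:3) {
    if (o[a] == 0) next
    ta <- if (o[a] > 0) co[, a] - 1L else d[a] - co[, a]
    t_back <- pmin(t_back, ta)
  }
  anchor <- co - t_back %o% o
  key <- .linidx(anchor[, 1], anchor[, 2], anchor[, 3], d)
  idx <- .linidx(co[, 1], co[, 2], co[, 3], d)
  ord <- order(key, t_back)
  unname(split(as.integer(idx[ord]), key[ord]))
}

#' @keywords internal
patch_geometry <- function(dims) {
  d <- as.integer(dims)
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  key <- paste(d, collapse = "x")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  off <- .valid_offsets(d)
  n_off <- nrow(off)
  pairs <- lapply(seq_len(n_off), function(r) .offset_pairs(off[r, ], d))
  lines <- lapply(seq_len(n_off), function(r) .direction_lines(off[r, ], d))
  # symmetric neighbour edges over all offsets
  ef <- unlist(lapply(pairs, `[[`, "from"))
  et <- unlist(lapply(pairs, `[[`, "to"))
  geom <- list(
    dims = d,
    n_voxels = prod(d),
    offsets = off,
    pairs = pairs,
    lines = lines,
    edge_from = c(ef, et),
    edge_to = c(et, ef)
  )
  .geom_cache[[key]] <- geom
  geom
}
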