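# Single-case phantom generator: a smoothed correlated Gaussian background
# field with an ellipsoidal lesion whose intensity distribution shifts and
# widens with the csPCa class, plus two raters' masks (the second a
# morphologically perturbed copy of the first). No MR physics is attempted;
# the phantom only needs the statistical structure the downstream analysis
# assumes.

# separable truncated-Gaussian smoothing along one axis via a band matrix
.smooth_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- exp(-((j - i)^2) / (2 * sigma^2))
    S[i, j] <- w / sum(w)
  }
  S
}

.smooth_field <- function(arr, sigma_xy = 1) {
  d <- dim(arr)
  Sx <- .smooth_matrix(d[1], sigma_xy)
  Sy <- .smooth_matrix(d[2], sigma_xy)
  for (k in seq_len(d[3])) {
    arr[, , k] <- Sx %*% arr[, , k] %*% t(Sy)
  }
  arr
}

# voxelize an ellipsoid given world-mm center and radii
.ellipsoid_mask <- function(dims, spacing, center, radii) {
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3]
  qx <- ((cx - center[1]) / radii[1])^2
  qy <- ((cy - center[2]) / radii[2])^2
  qz <- ((cz - center[3]) / radii[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

# boundary voxels: labeled with at least one unlabeled 6-neighbour (or the
# converse for unlabeled voxels adjacent to the mask)
.mask_boundary <- function(m) {
  d <- dim(m)
  shift_or <- function(x) {
    acc <- array(FALSE, d)
    idx <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
    for (o in idx) {
      src <- lapply(1:3, function(a) {
        s <- seq_len(d[a]) + o[a]
        s[s >= 1 & s <= d[a]]
      })
      dst <- lapply(1:3, function(a) {
        s <- seq_len(d[a])
        s[s + o[a] >= 1 & s + o[a] <= d[a]]
      })
      acc[dst[[1]], dst[[2]], dst[[3]]] <-
        acc[dst[[1]], dst[[2]], dst[[3]]] | x[src[[1]], src[[2]], src[[3]]]
    }
    acc
  }
  (m & shift_or(!m)) | (!m & shift_or(m))
}

#' Generate one phantom case
#'
#' Builds the T2w-like volume and the two raters' lesion masks for one patient
#' record. The background is a smoothed correlated noise field (rescaled to
#' the configured mean/SD); lesion voxels are transformed in place by the
#' class-dependent effect: every lesion is shifted down by \code{shift_all},
#' csPCa lesions additionally by \code{shift_cs} with local SD scaled by
#' \code{1 + contrast_cs}. With a null effect the lesion is statistically
#' indistinguishable from background. The rater-2 mask re-voxelizes a slightly
#' perturbed ellipsoid and randomly flips boundary voxels.
#'
#' @param record One-row data.frame as from \code{\link{generate_records}}
#'   (fields \code{zone}, \code{outcome}).
#' @param config A \code{\link{cohort_config}}.
#' @param seed Integer seed for this case.
#' @return An object of class \code{phantom_case}: \code{volume},
#'   \code{mask_rater1}, \code{mask_rater2}, \code{lesion_center} (mm),
#'   \code{lesion_radii} (mm).
#' @export
generate_phantom <- function(record, config, seed = 1L) {
  dims <- config$image_shape
  sp <- config$spacing
  extent <- dims * sp
  .with_seed(seed, {
    noise <- array(stats::rnorm(prod(dims)), dims)
    sm <- .smooth_field(noise, sigma_xy = 1)
    field <- config$bg_mean +
      (sm - mean(sm)) / stats::sd(sm) * config$bg_sd

    # lesion placement: PZ posterior, TZ central; jitter in-plane
    fy <- if (record$zone == "PZ") 0.68 else 0.5
    center <- c(extent[1] * (0.5 + stats::runif(1, -0.06, 0.06)),
                extent[2] * (fy + stats::runif(1, -0.05, 0.05)),
                extent[3] * 0.5)
    rr <- config$lesion_radii_mm
    radii <- c(stats::runif(2, rr[1], rr[2]),
               stats::runif(1, max(rr[1], 1.2 * sp[3]), max(rr)))
    if (any(radii > extent / 2)) {
      stop("lesion radii exceed the volume extent; shrink lesion_radii_mm ",
           "or enlarge image_shape")
    }

    m1 <- .ellipsoid_mask(dims, sp, center, radii)
    if (!any(m1)) stop("degenerate lesion: no voxel inside the ellipsoid")

    is_cs <- record$outcome == "csPCa"
    eff <- config$lesion_effect
    shift <- eff$shift_all + if (is_cs) eff$shift_cs else 0
    scale <- 1 + if (is_cs) eff$contrast_cs else 0
    field[m1] <- config$bg_mean +
      (field[m1] - config$bg_mean) * scale - shift

    # rater 2: perturbed ellipsoid + random boundary flips
    c2 <- center + stats::runif(3, -0.5, 0.5)
    r2 <- radii * stats::runif(3, 0.95, 1.05)
    m2 <- .ellipsoid_mask(dims, sp, c2, r2)
    bnd <- which(.mask_boundary(m2))
    flip <- bnd[stats::runif(length(bnd)) < config$rater2_flip_prob]
    m2[flip] <- !m2[flip]
    if (!any(m2)) m2 <- m1   # never emit an empty rater-2 mask

    structure(
      list(volume = image_volume(field, sp),
           mask_rater1 = segmentation_mask(m1, sp),
           mask_rater2 = segmentation_mask(m2, sp),
           lesion_center = center, lesion_radii = radii),
      class = "phantom_case"
    )
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> lesion radii ",
      paste(sprintf("%.1f", x$lesion_radii), collapse = " x "), " mm, ",
      sum(x$mask_rater1$data), "/", sum(x$mask_rater2$data),
      " voxels (rater 1/2)\n", sep = "")
  invisible(x)
}
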