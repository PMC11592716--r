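# Synthetic two-class phantom cohort. The default configuration mirrors the
# clinical cohort the analysis is designed for: 52 patients with a PI-RADS-3
# lesion — 25/8 no-PCa, 4/4 ciPCa and 8/3 csPCa split over the peripheral (PZ)
# and transition (TZ) zones — with log-normal PSA and prostate volume whose
# group medians match the published cohort table (PSA 6 / 7.45 / 9.7 ng/mL,
# volume 62 / 47 / 46 mL). csPCa is the positive class; no-PCa and ciPCa
# collapse to non-csPCa.

.OUTCOMES <- c("noPCa", "ciPCa", "csPCa")

#' Cohort configuration
#'
#' @param n_noPCa_PZ,n_noPCa_TZ,n_ciPCa_PZ,n_ciPCa_TZ,n_csPCa_PZ,n_csPCa_TZ
#'   Patient counts per outcome and zone (defaults 25/8, 4/4, 8/3).
#' @param psa_median_by_group Named medians (ng/mL) for noPCa/ciPCa/csPCa.
#' @param volume_median_by_group Named prostate-volume medians (mL).
#' @param psa_sdlog,volume_sdlog Log-scale SDs of the log-normal covariate
#'   models (chosen so the IQRs roughly match the published cohort table).
#' @param lesion_effect List of dimensionless lesion contrast parameters:
#'   \code{shift_all} (hypointensity of every lesion, intensity units),
#'   \code{shift_cs} (additional csPCa hypointensity), \code{contrast_cs}
#'   (relative csPCa variance inflation; the local SD is scaled by
#'   \code{1 + contrast_cs}). Use \code{lesion_effect_null()} for a
#'   null-effect cohort.
#' @param image_shape Voxel dimensions of each phantom volume.
#' @param spacing Voxel spacing in mm (default 0.5 x 0.5 x 3, T2w-like).
#' @param bg_mean,bg_sd Background field mean and SD (intensity units).
#' @param lesion_radii_mm Range the ellipsoid in-plane radii are drawn from.
#' @param rater2_flip_prob Probability that a boundary voxel of the rater-2
#'   mask is flipped (interrater perturbation).
#' @param seed Integer seed; every draw in the cohort derives from it.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_noPCa_PZ = 25, n_noPCa_TZ = 8,
                          n_ciPCa_PZ = 4, n_ciPCa_TZ = 4,
                          n_csPCa_PZ = 8, n_csPCa_TZ = 3,
                          psa_median_by_group =
                            c(noPCa = 6, ciPCa = 7.45, csPCa = 9.7),
                          volume_median_by_group =
                            c(noPCa = 62, ciPCa = 47, csPCa = 46),
                          psa_sdlog = 0.33, volume_sdlog = 0.30,
                          lesion_effect = lesion_effect_default(),
                          image_shape = c(64, 64, 10),
                          spacing = c(0.5, 0.5, 3),
                          bg_mean = 200, bg_sd = 40,
                          lesion_radii_mm = c(4, 12),
                          rater2_flip_prob = 0.1,
                          seed = 20240503) {
  counts <- c(n_noPCa_PZ, n_noPCa_TZ, n_ciPCa_PZ, n_ciPCa_TZ,
              n_csPCa_PZ, n_csPCa_TZ)
  if (any(counts < 0)) stop("patient counts must be non-negative")
  if (any(psa_median_by_group <= 0) || any(volume_median_by_group <= 0)) {
    stop("median parameters must be strictly positive")
  }
  canon <- function(v) {
    v <- unlist(v)
    if (length(v) != 3) stop("group medians need one value per outcome")
    if (!is.null(names(v)) && setequal(names(v), .OUTCOMES)) v <- v[.OUTCOMES]
    stats::setNames(as.numeric(v), .OUTCOMES)
  }
  psa_median_by_group <- canon(psa_median_by_group)
  volume_median_by_group <- canon(volume_median_by_group)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  structure(
    list(counts = matrix(counts, nrow = 3, byrow = TRUE,
                         dimnames = list(.OUTCOMES, c("PZ", "TZ"))),
         psa_median = psa_median_by_group,
         volume_median = volume_median_by_group,
         psa_sdlog = psa_sdlog, volume_sdlog = volume_sdlog,
         lesion_effect = lesion_effect,
         image_shape = as.integer(image_shape), spacing = as.numeric(spacing),
         bg_mean = bg_mean, bg_sd = bg_sd,
         lesion_radii_mm = lesion_radii_mm,
         rater2_flip_prob = rater2_flip_prob,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default and null lesion-effect parameters
#'
#' The default gives csPCa lesions a lower median, lower 10th percentile /
#' minimum, and higher local contrast than non-csPCa tissue; the null effect
#' makes lesions statistically indistinguishable from background.
#' @return Named list with \code{shift_all}, \code{shift_cs},
#'   \code{contrast_cs}.
#' @export
lesion_effect_default <- function() {
  list(shift_all = 15, shift_cs = 45, contrast_cs = 0.6)
}

#' @rdname lesion_effect_default
#' @export
lesion_effect_null <- function() {
  list(shift_all = 0, shift_cs = 0, contrast_cs = 0)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", sum(x$counts), " patients (",
      paste(apply(x$counts, 1, paste, collapse = "/"), collapse = ", "),
      " PZ/TZ by ", paste(rownames(x$counts), collapse = "/"),
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# run code under a private RNG stream without disturbing the caller's
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.case_seed <- function(seed, i) as.integer((as.double(seed) * 10007 + i) %% 2147483647)

#' Generate the patient records of a cohort
#'
#' Draws per-patient clinical covariates only (no images): PSA and prostate
#' volume from log-normal distributions with the configured group medians,
#' PSAD = PSA / volume, outcome and zone labels, and the binary csPCa /
#' non-csPCa label.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A data.frame with columns \code{id}, \code{zone}, \code{psa_ng_ml},
#'   \code{volume_ml}, \code{psad}, \code{outcome}, \code{label}.
#' @export
generate_records <- function(config) {
  cnt <- config$counts
  n <- sum(cnt)
  outcome <- rep(rep(rownames(cnt), times = 2), times = as.vector(cnt))
  zone <- rep(rep(colnames(cnt), each = 3), times = as.vector(cnt))
  ord <- order(match(outcome, .OUTCOMES), match(zone, c("PZ", "TZ")))
  outcome <- outcome[ord]
  zone <- zone[ord]
  .with_seed(config$seed, {
    psa <- stats::rlnorm(n, meanlog = log(config$psa_median[outcome]),
                         sdlog = config$psa_sdlog)
    vol <- stats::rlnorm(n, meanlog = log(config$volume_median[outcome]),
                         sdlog = config$volume_sdlog)
    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      zone = zone,
      psa_ng_ml = psa,
      volume_ml = vol,
      psad = psad(psa, vol),
      outcome = outcome,
      label = ifelse(outcome == "csPCa", "csPCa", "non-csPCa"),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a full phantom cohort
#'
#' Couples \code{\link{generate_records}} with one \code{\link{generate_phantom}}
#' call per patient. Deterministic given the config seed.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param with_images Generate phantom volumes and masks (\code{TRUE}) or
#'   records only?
#' @return A list of class \code{phantom_cohort}: \code{records} (data.frame)
#'   and \code{cases} (list of \code{phantom_case}, or \code{NULL}).
#' @export
generate_cohort <- function(config = cohort_config(), with_images = TRUE) {
  records <- generate_records(config)
  cases <- NULL
  if (with_images && nrow(records) > 0) {
    cases <- lapply(seq_len(nrow(records)), function(i) {
      generate_phantom(records[i, ], config,
                       seed = .case_seed(config$seed, i))
    })
    names(cases) <- records$id
  }
  structure(list(records = records, cases = cases, config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", nrow(x$records), " patients (",
      sum(x$records$label == "csPCa"), " csPCa), images: ",
      if (is.null(x$cases)) "no" else "yes", "\n", sep = "")
  invisible(x)
}

#' Write a cohort's records to CSV
#'
#' @param cohort A \code{phantom_cohort} or its records data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  rec <- if (inherits(cohort, "phantom_cohort")) cohort$records else cohort
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
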