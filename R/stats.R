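# Elementary statistics of the analysis: PSA density, Mann-Whitney U group
# comparison, AUC rating bands, minority-class upsampling, and ICC(3,1)
# interrater reliability.

#' PSA density
#'
#' PSAD = serum PSA / MRI-derived prostate volume, in (ng/mL)/cm^3 (1 mL =
#' 1 cm^3).
#'
#' @param psa PSA in ng/mL (vectorized).
#' @param volume Prostate volume in mL; must be strictly positive.
#' @return PSAD values.
#' @examples
#' round(psad(6, 62), 2)     # 0.10
#' round(psad(7.45, 47), 2)  # 0.16
#' @export
psad <- function(psa, volume) {
  if (any(volume <= 0)) stop("prostate volume must be strictly positive")
  psa / volume
}

#' Mann-Whitney U comparison of a feature between csPCa and non-csPCa
#'
#' Two-sided test. For small samples without ties (n1*n2 <= 400) the exact
#' permutation distribution is used; otherwise the normal approximation with
#' tie correction and continuity correction. If every value is identical
#' across both groups the test is degenerate and p = 1.
#'
#' @param values_cs Feature values of the csPCa group.
#' @param values_non Feature values of the non-csPCa group.
#' @param feature Optional feature name carried into the result.
#' @return A list of class \code{group_comparison}: \code{feature}, \code{U}
#'   (number of (cs, non) pairs with cs > non, ties counting 1/2), \code{p},
#'   and group medians/IQRs.
#' @export
mwu_test <- function(values_cs, values_non, feature = NA_character_) {
  if (length(values_cs) == 0 || length(values_non) == 0) {
    stop("both groups must be non-empty")
  }
  n1 <- length(values_cs)
  n2 <- length(values_non)
  ties <- anyDuplicated(c(values_cs, values_non)) > 0
  if (stats::var(c(values_cs, values_non)) == 0) {
    U <- n1 * n2 / 2
    p <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      values_cs, values_non,
      exact = (n1 * n2 <= 400) && !ties, correct = TRUE
    ))
    U <- unname(wt$statistic)
    p <- min(1, wt$p.value)
  }
  structure(
    list(feature = feature, U = U, p = p,
         median_cs = stats::median(values_cs),
         median_non = stats::median(values_non),
         iqr_cs = stats::IQR(values_cs), iqr_non = stats::IQR(values_non),
         n_cs = n1, n_non = n2),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", if (!is.na(x$feature)) x$feature else "",
      sprintf(" U = %.1f, p = %.4g (medians %.4g vs %.4g)\n",
              x$U, x$p, x$median_cs, x$median_non))
  invisible(x)
}

#' Rate an AUC
#'
#' Bands: below 0.70 poor, 0.70-0.80 acceptable, 0.80-0.90 excellent,
#' 0.90-1.00 outstanding (half-open at the upper edge except 1.0).
#'
#' @param auc AUC value(s) in [0, 1].
#' @return Character rating(s).
#' @examples
#' rate_auc(c(0.84, 0.70, 1.0))  # excellent, acceptable, outstanding
#' @export
rate_auc <- function(auc) {
  cut_band <- function(a) {
    if (is.na(a)) return(NA_character_)
    if (a < 0.70) "poor"
    else if (a < 0.80) "acceptable"
    else if (a < 0.90) "excellent"
    else "outstanding"
  }
  vapply(auc, cut_band, character(1))
}

#' Upsample the minority class
#'
#' Resamples minority-class rows with replacement (appended to the original
#' rows) until both classes have equal counts. Deterministic given the seed;
#' never introduces records absent from the input.
#'
#' @param records Data.frame with a class column.
#' @param label_col Name of the class column (default \code{"label"}).
#' @param seed Integer seed.
#' @return The balanced data.frame.
#' @export
upsample <- function(records, label_col = "label", seed = 1L) {
  tab <- table(records[[label_col]])
  if (length(tab) != 2) stop("upsampling requires exactly two classes")
  if (tab[1] == tab[2]) return(records)
  minority <- names(tab)[which.min(tab)]
  need <- as.integer(abs(diff(as.integer(tab))))
  idx <- which(records[[label_col]] == minority)
  extra <- .with_seed(seed,
                      idx[sample.int(length(idx), need, replace = TRUE)])
  out <- rbind(records, records[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' ICC(3,1): two-way mixed, single rater, consistency
#'
#' Shrout-Fleiss ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS) from the
#' two-way ANOVA mean squares (subjects x raters, no replication), with the
#' F-test p-value (F = BMS/EMS on (n-1) and (n-1)(k-1) df). Being a
#' consistency coefficient it is invariant to an additive rater offset.
#' Ratings follow the conventional bands: below 0.5 poor, 0.5-0.75 moderate,
#' 0.75-0.9 good, above 0.9 excellent.
#'
#' @param ratings_rater1,ratings_rater2 Numeric vectors, one value per
#'   subject, same length (at least 2 subjects).
#' @param feature Optional feature name carried into the result.
#' @return A list of class \code{icc_result}: \code{icc}, \code{p},
#'   \code{rating}, \code{n}.
#' @export
icc3 <- function(ratings_rater1, ratings_rater2, feature = NA_character_) {
  n <- length(ratings_rater1)
  if (length(ratings_rater2) != n) stop("rating vectors differ in length")
  if (n < 2) stop("ICC needs at least 2 subjects")
  X <- cbind(ratings_rater1, ratings_rater2)
  k <- ncol(X)
  grand <- mean(X)
  rm_ <- rowMeans(X)
  cm_ <- colMeans(X)
  ssb <- k * sum((rm_ - grand)^2)             # between subjects
  ssc <- n * sum((cm_ - grand)^2)             # between raters
  sst <- sum((X - grand)^2)
  sse <- sst - ssb - ssc
  bms <- ssb / (n - 1)
  ems <- sse / ((n - 1) * (k - 1))
  icc <- if (bms + (k - 1) * ems > 0) (bms - ems) / (bms + (k - 1) * ems)
  else NaN
  p <- if (ems > 0) {
    stats::pf(bms / ems, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else if (bms > 0) 0 else NaN
  rating <- if (is.nan(icc)) NA_character_
  else if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
  structure(list(feature = feature, icc = icc, p = p, rating = rating, n = n),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(3,1) = %.3f (%s), p = %.3g, n = %d\n",
              x$icc, x$rating, x$p, x$n))
  invisible(x)
}
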