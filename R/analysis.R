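# Full statistical analysis of an extracted cohort: Mann-Whitney screening,
# univariate ROC analysis and bivariate PSAD models per zone stratum
# (all / PZ / TZ), plus per-feature interrater ICC when a second rater's
# extractions are present. Output tables are joinable on feature name; the
# heatmap-style AUC matrices mirror the usual reporting layout.

#' Analysis configuration
#'
#' @param strata Zone strata to analyse; subset of \code{c("all","PZ","TZ")}.
#' @param psad_modes PSAD modes for the bivariate stage.
#' @param bootstrap_n Bootstrap replicates for bivariate odds ratios
#'   (default 1000).
#' @param lambda Ridge penalty of the bivariate models.
#' @param sig_level Screening significance level (raw p; default 0.05).
#' @param adjust_bh Add a Benjamini-Hochberg adjusted p column? Off by
#'   default: the screening across the 93 features is deliberately reported
#'   on raw p-values.
#' @param seed Integer seed for upsampling and bootstrap.
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(strata = c("all", "PZ", "TZ"),
                            psad_modes = c("continuous", "cutoff015",
                                           "cutoff020"),
                            bootstrap_n = 1000, lambda = 0.01,
                            sig_level = 0.05, adjust_bh = FALSE,
                            seed = 1L) {
  structure(list(strata = strata, psad_modes = psad_modes,
                 bootstrap_n = bootstrap_n, lambda = lambda,
                 sig_level = sig_level, adjust_bh = adjust_bh,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

.stratum_rows <- function(records, stratum) {
  if (stratum == "all") seq_len(nrow(records))
  else which(records$zone == stratum)
}

#' Run the full feature-level analysis
#'
#' @param records Data.frame with clinical columns (\code{label}, \code{zone},
#'   \code{psad}) and feature columns named per \code{\link{feature_registry}}
#'   (rater 1); optional rater-2 columns carry an \code{_r2} suffix.
#' @param config An \code{\link{analysis_config}}.
#' @param features Feature columns to analyse (defaults to every registry
#'   name present in \code{records}).
#' @return An object of class \code{radiomap_analysis} with data.frames
#'   \code{comparison}, \code{univariate}, \code{bivariate}, \code{icc}.
#' @export
run_full_analysis <- function(records, config = analysis_config(),
                              features = NULL) {
  if (is.null(features)) {
    features <- intersect(feature_names(), names(records))
  }
  if (length(features) == 0) stop("no feature columns found")
  comparison <- list()
  univariate <- list()
  bivariate <- list()

  for (st in config$strata) {
    rows <- .stratum_rows(records, st)
    rec <- records[rows, , drop = FALSE]
    two_class <- length(unique(rec$label)) == 2
    for (f in features) {
      v <- rec[[f]]
      ok <- two_class && all(is.finite(v))
      cmp <- if (ok) {
        mwu_test(v[rec$label == "csPCa"], v[rec$label != "csPCa"], feature = f)
      } else NULL
      comparison[[length(comparison) + 1]] <- data.frame(
        stratum = st, feature = f,
        U = if (ok) cmp$U else NA_real_, p = if (ok) cmp$p else NA_real_,
        median_cs = if (ok) cmp$median_cs else NA_real_,
        median_non = if (ok) cmp$median_non else NA_real_,
        iqr_cs = if (ok) cmp$iqr_cs else NA_real_,
        iqr_non = if (ok) cmp$iqr_non else NA_real_,
        n_cs = sum(rec$label == "csPCa"), n_non = sum(rec$label != "csPCa"))
      uni <- if (ok) fit_univariate(v, rec$label, feature = f) else NULL
      univariate[[length(univariate) + 1]] <- data.frame(
        stratum = st, feature = f,
        auc = if (ok) uni$roc$auc else NA_real_,
        sensitivity = if (ok) uni$roc$sensitivity else NA_real_,
        specificity = if (ok) uni$roc$specificity else NA_real_,
        ppv = if (ok) uni$roc$ppv else NA_real_,
        npv = if (ok) uni$roc$npv else NA_real_,
        rating = if (ok) uni$roc$rating else NA_character_,
        separable = if (ok) uni$separable else NA)
    }
  }
  comparison <- do.call(rbind, comparison)
  univariate <- do.call(rbind, univariate)
  if (config$adjust_bh) {
    comparison$p_bh <- stats::ave(comparison$p, comparison$stratum,
                                  FUN = function(p) stats::p.adjust(p, "BH"))
  }

  # bivariate stage: features passing the screen in each stratum
  for (st in config$strata) {
    rows <- .stratum_rows(records, st)
    rec <- records[rows, , drop = FALSE]
    if (length(unique(rec$label)) != 2) next
    psig <- comparison[comparison$stratum == st & !is.na(comparison$p) &
                         comparison$p < config$sig_level, "feature"]
    for (f in psig) {
      for (mode in config$psad_modes) {
        fit <- fit_bivariate(rec, f, psad_mode = mode,
                             lambda = config$lambda, seed = config$seed)
        bs <- bootstrap_model(rec, f, psad_mode = mode,
                              n_boot = config$bootstrap_n,
                              lambda = config$lambda, seed = config$seed)
        fr <- bs[bs$term == "feature", ]
        pr <- bs[bs$term == "psad", ]
        bivariate[[length(bivariate) + 1]] <- data.frame(
          stratum = st, feature = f, psad_mode = mode,
          auc = fit$roc$auc, rating = fit$roc$rating,
          or_feature = fr$or, ci_lower_feature = fr$ci_lower,
          ci_upper_feature = fr$ci_upper, p_feature = fr$p,
          or_psad = pr$or, ci_lower_psad = pr$ci_lower,
          ci_upper_psad = pr$ci_upper, p_psad = pr$p,
          low_power = fit$low_power)
      }
    }
  }
  bivariate <- if (length(bivariate)) do.call(rbind, bivariate) else
    data.frame(stratum = character(0), feature = character(0),
               psad_mode = character(0), auc = numeric(0),
               rating = character(0), or_feature = numeric(0),
               ci_lower_feature = numeric(0), ci_upper_feature = numeric(0),
               p_feature = numeric(0), or_psad = numeric(0),
               ci_lower_psad = numeric(0), ci_upper_psad = numeric(0),
               p_psad = numeric(0), low_power = logical(0))

  # interrater ICC over the whole cohort, when rater-2 extractions exist
  icc <- NULL
  r2 <- paste0(features, "_r2")
  if (all(r2 %in% names(records)) && nrow(records) >= 2) {
    icc <- do.call(rbind, lapply(seq_along(features), function(i) {
      v1 <- records[[features[i]]]
      v2 <- records[[r2[i]]]
      ok <- all(is.finite(v1)) && all(is.finite(v2))
      res <- if (ok) icc3(v1, v2, feature = features[i]) else NULL
      data.frame(feature = features[i],
                 icc = if (ok) res$icc else NA_real_,
                 p = if (ok) res$p else NA_real_,
                 rating = if (ok) res$rating else NA_character_)
    }))
  }

  structure(list(comparison = comparison, univariate = univariate,
                 bivariate = bivariate, icc = icc, config = config,
                 features = features),
            class = "radiomap_analysis")
}

#' @export
print.radiomap_analysis <- function(x, ...) {
  nsig <- sum(x$comparison$p < x$config$sig_level & x$comparison$stratum ==
                x$config$strata[1], na.rm = TRUE)
  cat("<radiomap_analysis> ", length(x$features), " features, strata: ",
      paste(x$config$strata, collapse = "/"), "; ", nsig,
      " significant in '", x$config$strata[1], "'\n", sep = "")
  invisible(x)
}

#' @export
summary.radiomap_analysis <- function(object, ...) {
  for (st in object$config$strata) {
    cmp <- object$comparison[object$comparison$stratum == st, ]
    uni <- object$univariate[object$univariate$stratum == st, ]
    sig <- cmp$feature[!is.na(cmp$p) & cmp$p < object$config$sig_level]
    cat(sprintf("stratum %-3s: %d/%d features significant", st,
                length(sig), nrow(cmp)))
    if (length(sig)) {
      aucs <- uni$auc[uni$feature %in% sig]
      cat(sprintf(" (univariate AUC %.2f-%.2f)", min(aucs), max(aucs)))
    }
    cat("\n")
  }
  if (!is.null(object$icc)) {
    cat(sprintf("ICC(3,1): %d features, min %.3f\n", nrow(object$icc),
                min(object$icc$icc, na.rm = TRUE)))
  }
  invisible(object)
}

#' Write the analysis report tables as CSV
#'
#' Emits \code{comparison.csv}, \code{univariate.csv}, \code{bivariate.csv},
#' \code{icc.csv} (when present), and heatmap-style AUC matrices:
#' \code{heatmap_univariate.csv} (significant features x strata) and one
#' \code{heatmap_bivariate_<stratum>.csv} per stratum (features x PSAD modes).
#'
#' @param analysis A \code{radiomap_analysis}.
#' @param dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    f
  }
  files <- c(wr(analysis$comparison, "comparison.csv"),
             wr(analysis$univariate, "univariate.csv"),
             wr(analysis$bivariate, "bivariate.csv"))
  if (!is.null(analysis$icc)) files <- c(files, wr(analysis$icc, "icc.csv"))

  sig <- unique(analysis$comparison$feature[
    !is.na(analysis$comparison$p) &
      analysis$comparison$p < analysis$config$sig_level])
  if (length(sig)) {
    hm <- data.frame(feature = sig)
    for (st in analysis$config$strata) {
      uni <- analysis$univariate[analysis$univariate$stratum == st, ]
      hm[[st]] <- uni$auc[match(sig, uni$feature)]
    }
    files <- c(files, wr(hm, "heatmap_univariate.csv"))
  }
  for (st in analysis$config$strata) {
    bv <- analysis$bivariate[analysis$bivariate$stratum == st, ]
    if (!nrow(bv)) next
    feats <- unique(bv$feature)
    hm <- data.frame(feature = feats)
    for (mode in analysis$config$psad_modes) {
      hm[[mode]] <- bv$auc[bv$psad_mode == mode][match(feats,
        bv$feature[bv$psad_mode == mode])]
    }
    files <- c(files, wr(hm, paste0("heatmap_bivariate_", st, ".csv")))
  }
  invisible(files)
}
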