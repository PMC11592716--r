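# Logistic models and ROC analysis. Univariate single-feature models are
# unpenalized; bivariate models combining a map feature with PSA density are
# ridge-penalized (glmnet, alpha = 0) and fitted on class-upsampled data.
# All performance is apparent (in-sample), matching the analysis design.

# population SD: standardization is a scaling constant, so replicating the
# data must not change it
.psd <- function(x) sqrt(mean((x - mean(x))^2))

.roc_of <- function(labels, scores) {
  pROC::roc(response = labels, predictor = scores,
            levels = c("non-csPCa", "csPCa"), direction = "<", quiet = TRUE)
}

# operating point at the Youden maximum; ties broken toward higher sensitivity
.roc_summary <- function(roc_obj) {
  co <- pROC::coords(roc_obj, "all", ret = c("threshold", "sensitivity",
                                             "specificity", "ppv", "npv"),
                     transpose = FALSE)
  youden <- co$sensitivity + co$specificity - 1
  best <- which(youden == max(youden))
  best <- best[which.max(co$sensitivity[best])]
  auc <- as.numeric(pROC::auc(roc_obj))
  structure(
    list(auc = auc, threshold = co$threshold[best],
         sensitivity = co$sensitivity[best], specificity = co$specificity[best],
         ppv = co$ppv[best], npv = co$npv[best], rating = rate_auc(auc)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f (%s); sens %.2f, spec %.2f, PPV %.2f, NPV %.2f\n",
    x$auc, x$rating, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Univariate logistic model of one feature
#'
#' Unpenalized logistic regression of the binary csPCa label on one
#' standardized feature (no upsampling), with in-sample ROC analysis at the
#' Youden operating point. Perfect separation is flagged but the ROC is still
#' computed (the AUC depends on ranks only).
#'
#' @param values Feature values, one per patient.
#' @param labels Character/factor labels, \code{"csPCa"} vs
#'   \code{"non-csPCa"}.
#' @param feature Optional feature name.
#' @return An object of class \code{univariate_fit}: \code{coefficients},
#'   \code{scores}, \code{roc} (a \code{roc_result}), \code{separable},
#'   \code{feature}.
#' @export
fit_univariate <- function(values, labels, feature = NA_character_) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) stop("both classes must be present")
  y <- as.integer(labels == "csPCa")
  s <- .psd(values)
  z <- if (s > 0) (values - mean(values)) / s else values * 0
  separable <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ z, family = stats::binomial()),
    warning = function(w) {
      if (grepl("numerically 0 or 1|did not converge", conditionMessage(w)))
        separable <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  scores <- stats::fitted(fit)
  if (all(abs(scores - y) < 1e-6) && s > 0) separable <- TRUE
  roc_obj <- .roc_of(labels, scores)
  structure(
    list(feature = feature, coefficients = stats::coef(fit), scores = scores,
         roc = .roc_summary(roc_obj), separable = separable,
         n = length(y)),
    class = "univariate_fit"
  )
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat("<univariate_fit>", if (!is.na(x$feature)) x$feature else "",
      sprintf(" AUC = %.3f (%s)%s\n", x$roc$auc, x$roc$rating,
              if (x$separable) " [separable]" else ""))
  invisible(x)
}

.psad_term <- function(psad_values, psad_mode) {
  switch(psad_mode,
         continuous = psad_values,
         cutoff015 = as.numeric(psad_values >= 0.15),
         cutoff020 = as.numeric(psad_values >= 0.20),
         stop("psad_mode must be continuous, cutoff015 or cutoff020"))
}

#' Bivariate ridge model: one map feature + PSA density
#'
#' Fits a ridge-penalized logistic model (glmnet, alpha = 0, fixed lambda) of
#' the csPCa label on a standardized map feature plus a PSAD term — PSAD as a
#' continuous (standardized) value or as a 0.15 / 0.20 (ng/mL)/cm^3 cutoff
#' indicator. The minority class is upsampled to balance before fitting;
#' scores and the ROC are computed on the original (non-upsampled) patients.
#' Strata with fewer than 2 events are fitted but flagged low-power.
#'
#' @param records Data.frame with columns \code{label}, \code{psad}, and the
#'   feature column.
#' @param feature Name of the feature column.
#' @param psad_mode \code{"continuous"}, \code{"cutoff015"} or
#'   \code{"cutoff020"}.
#' @param lambda Ridge penalty (default 0.01 on standardized predictors).
#' @param seed Seed for the upsampling draw.
#' @param compute_roc Compute the in-sample ROC (disabled inside bootstrap
#'   replicates, where only coefficients are needed)?
#' @return An object of class \code{bivariate_fit}: \code{coefficients}
#'   (intercept, feature, psad), \code{scores}, \code{roc}, \code{low_power},
#'   plus the fit metadata.
#' @export
fit_bivariate <- function(records, feature, psad_mode = "continuous",
                          lambda = 0.01, seed = 1L, compute_roc = TRUE) {
  if (!feature %in% names(records)) stop("unknown feature column: ", feature)
  if (length(unique(records$label)) != 2) stop("both classes must be present")
  up <- upsample(records, seed = seed)
  mu_f <- mean(up[[feature]])
  sd_f <- .psd(up[[feature]])
  if (sd_f == 0) sd_f <- 1
  zt <- .psad_term(up$psad, psad_mode)
  mu_p <- if (psad_mode == "continuous") mean(zt) else 0
  sd_p <- if (psad_mode == "continuous") .psd(zt) else 1
  if (sd_p == 0) sd_p <- 1
  X <- cbind(feature = (up[[feature]] - mu_f) / sd_f,
             psad = (zt - mu_p) / sd_p)
  y <- as.integer(up$label == "csPCa")
  # tiny strata are already surfaced via the low_power flag; glmnet's
  # small-class note would otherwise fire once per bootstrap replicate
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE, thresh = 1e-10),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  beta <- as.numeric(stats::coef(fit))
  names(beta) <- c("(Intercept)", "feature", "psad")
  X0 <- cbind((records[[feature]] - mu_f) / sd_f,
              (.psad_term(records$psad, psad_mode) - mu_p) / sd_p)
  eta <- beta[1] + X0 %*% beta[-1]
  scores <- as.vector(1 / (1 + exp(-eta)))
  roc <- if (compute_roc) .roc_summary(.roc_of(records$label, scores))
  else NULL
  structure(
    list(feature = feature, psad_mode = psad_mode, coefficients = beta,
         scores = scores, roc = roc, lambda = lambda,
         low_power = sum(records$label == "csPCa") < 2,
         standardization = c(mu_f = mu_f, sd_f = sd_f, mu_p = mu_p,
                             sd_p = sd_p),
         n = nrow(records)),
    class = "bivariate_fit"
  )
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("<bivariate_fit>", x$feature, "+ PSAD", sprintf("(%s)", x$psad_mode),
      sprintf(" AUC = %.3f (%s)%s\n", x$roc$auc, x$roc$rating,
              if (x$low_power) " [low power]" else ""))
  invisible(x)
}

#' Bootstrap odds ratios, CIs and p-values of a bivariate model
#'
#' Resamples patients with replacement, stratified by class so both classes
#' appear in every replicate, refits the model, and summarizes each term's
#' coefficient distribution: OR = exp(coefficient), percentile 95% CI, and a
#' two-sided sign-share p-value p = 2 * min(#\{b > 0\} + 1, #\{b < 0\} + 1) /
#' (B + 1), capped at 1.
#'
#' @param records Data.frame as for \code{\link{fit_bivariate}}.
#' @param feature Feature column name.
#' @param psad_mode PSAD mode (see \code{\link{fit_bivariate}}).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param lambda Ridge penalty.
#' @param seed Integer seed.
#' @return A data.frame of class \code{bootstrap_summary} with one row per
#'   model term: \code{or}, \code{ci_lower}, \code{ci_upper}, \code{p}.
#' @export
bootstrap_model <- function(records, feature, psad_mode = "continuous",
                            n_boot = 1000, lambda = 0.01, seed = 1L) {
  idx_cs <- which(records$label == "csPCa")
  idx_non <- which(records$label != "csPCa")
  if (length(idx_cs) == 0 || length(idx_non) == 0) {
    stop("both classes must be present")
  }
  coefs <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- c(idx_cs[sample.int(length(idx_cs), length(idx_cs),
                                  replace = TRUE)],
                idx_non[sample.int(length(idx_non), length(idx_non),
                                   replace = TRUE)])
      rs <- records[take, , drop = FALSE]
      up_seed <- .case_seed(seed, b)
      fit <- fit_bivariate(rs, feature, psad_mode, lambda = lambda,
                           seed = up_seed, compute_roc = FALSE)
      fit$coefficients
    }, numeric(3))
  })
  term <- rownames(coefs)
  summ <- data.frame(
    term = term,
    or = exp(rowMeans(coefs)),
    ci_lower = exp(apply(coefs, 1, stats::quantile, 0.025)),
    ci_upper = exp(apply(coefs, 1, stats::quantile, 0.975)),
    p = vapply(seq_along(term), function(r) {
      b <- coefs[r, ]
      min(1, 2 * min(sum(b > 0) + 1, sum(b < 0) + 1) / (n_boot + 1))
    }, numeric(1)),
    row.names = NULL
  )
  class(summ) <- c("bootstrap_summary", "data.frame")
  attr(summ, "n_boot") <- n_boot
  summ
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired DeLong test of the ROC curves of two score vectors on the same
#' patients. Identical (or rank-identical) scores are a degenerate comparison
#' with p = 1.
#'
#' @param scores_a,scores_b Score vectors on the same patients.
#' @param labels Class labels (\code{"csPCa"} / \code{"non-csPCa"}).
#' @return List with \code{p}, \code{auc_a}, \code{auc_b}.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  ra <- .roc_of(as.character(labels), scores_a)
  rb <- .roc_of(as.character(labels), scores_b)
  if (isTRUE(all.equal(rank(scores_a), rank(scores_b)))) {
    return(list(p = 1, auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb))))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  p <- tst$p.value
  if (is.nan(p)) p <- 1   # zero-variance difference
  list(p = p, auc_a = as.numeric(pROC::auc(ra)),
       auc_b = as.numeric(pROC::auc(rb)))
}
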