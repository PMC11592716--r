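# fixtures: a small labelled cohort data.frame
toy_records <- function(n_cs = 11, n_non = 41, seed = 1,
                        feature_shift = 0, psad_shift = 0) {
  set.seed(seed)
  n <- n_cs + n_non
  lab <- rep(c("csPCa", "non-csPCa"), c(n_cs, n_non))
  data.frame(
    id = sprintf("P%03d", 1:n),
    zone = sample(c("PZ", "TZ"), n, replace = TRUE),
    label = lab,
    psad = exp(rnorm(n, log(0.12), 0.4)) +
      ifelse(lab == "csPCa", psad_shift, 0),
    f = rnorm(n) + ifelse(lab == "csPCa", feature_shift, 0)
  )
}

test_that("univariate model: separation, degeneracy and orientation", {
  rec <- toy_records(feature_shift = 50)
  fit <- fit_univariate(rec$f, rec$label)
  expect_equal(fit$roc$auc, 1.0)
  expect_true(fit$separable)
  expect_identical(fit$roc$rating, "outstanding")

  # constant feature carries no information
  fit0 <- fit_univariate(rep(3.3, 52), rec$label)
  expect_equal(fit0$roc$auc, 0.5)

  expect_error(fit_univariate(rnorm(5), rep("csPCa", 5)), "both classes")
})

test_that("univariate AUC equals the rank statistic U/(n1 n2) of the feature", {
  for (s in 1:10) {
    rec <- toy_records(seed = s, feature_shift = 0.8)
    fit <- fit_univariate(rec$f, rec$label)
    cmp <- mwu_test(rec$f[rec$label == "csPCa"],
                    rec$f[rec$label != "csPCa"])
    u_auc <- cmp$U / (cmp$n_cs * cmp$n_non)
    expect_equal(fit$roc$auc, max(u_auc, 1 - u_auc), tolerance = 1e-10)
  }
})

test_that("a pure-noise feature adds nothing to a PSAD-separated bivariate
          model", {
  rec <- toy_records(seed = 7, feature_shift = 0, psad_shift = 5)
  biv <- fit_bivariate(rec, "f", "continuous", seed = 2)
  psad_fit <- fit_univariate(rec$psad, rec$label)
  expect_equal(biv$roc$auc, psad_fit$roc$auc, tolerance = 0.02)
  expect_equal(biv$roc$auc, 1.0)
})

test_that("bivariate AUC is at least the better single predictor's (in-sample,
          small ridge)", {
  for (s in c(3, 4)) {
    rec <- toy_records(seed = s, feature_shift = 1, psad_shift = 0.05)
    biv <- fit_bivariate(rec, "f", "continuous", lambda = 0.001, seed = 5)
    auc_f <- fit_univariate(rec$f, rec$label)$roc$auc
    auc_p <- fit_univariate(rec$psad, rec$label)$roc$auc
    expect_gte(biv$roc$auc, max(auc_f, auc_p) - 0.03)
  }
})

test_that("duplicating every record of a balanced cohort leaves the bivariate
          fit unchanged", {
  rec <- toy_records(n_cs = 20, n_non = 20, seed = 9, feature_shift = 0.5)
  dup <- rbind(rec, rec)
  f1 <- fit_bivariate(rec, "f", "continuous", seed = 3)
  f2 <- fit_bivariate(dup, "f", "continuous", seed = 3)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("PSAD cutoff modes dichotomize at exactly 0.15 and 0.20", {
  rec <- toy_records(seed = 11, psad_shift = 0.1)
  rec$psad <- seq(0.05, 0.56, by = 0.01)
  t15 <- radiomaps:::.psad_term(rec$psad, "cutoff015")
  t20 <- radiomaps:::.psad_term(rec$psad, "cutoff020")
  expect_identical(t15, as.numeric(rec$psad >= 0.15))
  expect_identical(t20, as.numeric(rec$psad >= 0.20))
  expect_error(radiomaps:::.psad_term(rec$psad, "cutoff025"), "psad_mode")
  # the three modes produce three generally different models
  fits <- lapply(c("continuous", "cutoff015", "cutoff020"), function(m)
    fit_bivariate(rec, "f", m, seed = 1)$coefficients)
  expect_false(identical(fits[[1]], fits[[2]]))
  expect_false(identical(fits[[2]], fits[[3]]))
})

test_that("low-event strata are flagged low power", {
  rec <- toy_records(n_cs = 1, n_non = 12, seed = 13)
  biv <- fit_bivariate(rec, "f", "continuous", seed = 1)
  expect_true(biv$low_power)
})

test_that("bootstrap summaries are seeded, stratified and shaped per term", {
  rec <- toy_records(seed = 15, feature_shift = 1)
  b1 <- bootstrap_model(rec, "f", "continuous", n_boot = 50, seed = 8)
  b2 <- bootstrap_model(rec, "f", "continuous", n_boot = 50, seed = 8)
  expect_identical(b1, b2)
  b3 <- bootstrap_model(rec, "f", "continuous", n_boot = 50, seed = 9)
  expect_false(identical(b1$ci_lower, b3$ci_lower))
  expect_identical(b1$term, c("(Intercept)", "feature", "psad"))
  expect_true(all(b1$ci_lower <= b1$or & b1$or <= b1$ci_upper))
  expect_true(all(b1$p >= 1 / 51 & b1$p <= 1))
  # a strong positive feature effect: OR above 1 with a significant p
  fr <- b1[b1$term == "feature", ]
  expect_gt(fr$or, 1)
  expect_lt(fr$p, 0.05)
})

test_that("DeLong test: self-comparison, symmetry, and agreement with a paired
          permutation oracle", {
  rec <- toy_records(n_cs = 15, n_non = 25, seed = 17, feature_shift = 0.9)
  sa <- rec$f
  sb <- rec$f * 0.6 + rnorm(40, sd = 0.8)

  expect_equal(delong_test(sa, sa, rec$label)$p, 1)
  expect_equal(delong_test(rank(sa), sa, rec$label)$p, 1)  # rank-identical
  expect_equal(delong_test(sa, sb, rec$label)$p,
               delong_test(sb, sa, rec$label)$p)

  p_delong <- delong_test(sa, sb, rec$label)$p
  p_perm <- oracle_delong_permutation(sa, sb, rec$label, n_perm = 2000,
                                      seed = 3)
  expect_lt(abs(p_delong - p_perm), 0.08)
})
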