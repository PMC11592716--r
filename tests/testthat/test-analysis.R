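# feature-level cohort table: registry-named columns, a handful informative
synthetic_feature_table <- function(seed = 1, shift = 0,
                                    informative = c("firstorder.Median",
                                                    "firstorder.10Percentile"),
                                    rater2 = TRUE) {
  rec <- generate_records(cohort_config(seed = seed))
  set.seed(seed + 1000)
  n <- nrow(rec)
  for (f in feature_names()) {
    v <- rnorm(n)
    if (f %in% informative) v <- v - shift * (rec$label == "csPCa")
    rec[[f]] <- v
    if (rater2) rec[[paste0(f, "_r2")]] <- v + rnorm(n, sd = 0.05)
  }
  rec
}

test_that("the full analysis emits three strata of 93-row tables plus the ICC
          table", {
  rec <- synthetic_feature_table(seed = 2, shift = 3)
  cfg <- analysis_config(bootstrap_n = 25, seed = 5)
  an <- run_full_analysis(rec, cfg)
  expect_identical(nrow(an$comparison), 3L * 93L)
  expect_identical(nrow(an$univariate), 3L * 93L)
  expect_setequal(unique(an$comparison$stratum), c("all", "PZ", "TZ"))
  expect_identical(nrow(an$icc), 93L)
  # strong shift: the informative features screen in and classify well
  sig_all <- an$comparison[an$comparison$stratum == "all", ]
  expect_lt(sig_all$p[sig_all$feature == "firstorder.Median"], 0.05)
  uni_all <- an$univariate[an$univariate$stratum == "all", ]
  expect_gt(uni_all$auc[uni_all$feature == "firstorder.Median"], 0.9)
  # bivariate rows exist for screened features, all three PSAD modes
  expect_true(all(c("continuous", "cutoff015", "cutoff020") %in%
                    an$bivariate$psad_mode))
  expect_true("firstorder.Median" %in% an$bivariate$feature)
  # tight rater-2 noise: interrater reliability is excellent
  expect_gt(min(an$icc$icc), 0.9)
})

test_that("report CSVs are written and joinable on feature name", {
  rec <- synthetic_feature_table(seed = 3, shift = 3,
                                 informative = "glcm.Contrast")
  an <- run_full_analysis(rec, analysis_config(bootstrap_n = 10, seed = 2,
                                               strata = c("all", "PZ")))
  dir <- withr::local_tempdir()
  files <- write_analysis(an, dir)
  expect_true(all(file.exists(file.path(dir, c("comparison.csv",
                                               "univariate.csv",
                                               "bivariate.csv", "icc.csv")))))
  hm <- utils::read.csv(file.path(dir, "heatmap_univariate.csv"),
                        check.names = FALSE)
  expect_true(all(c("feature", "all", "PZ") %in% names(hm)))
  cmp <- utils::read.csv(file.path(dir, "comparison.csv"))
  uni <- utils::read.csv(file.path(dir, "univariate.csv"))
  j <- merge(cmp, uni, by = c("stratum", "feature"))
  expect_identical(nrow(j), nrow(cmp))
})

test_that("a null-effect table yields no systematic significance and the BH
          column appears on request", {
  rec <- synthetic_feature_table(seed = 4, shift = 0, rater2 = FALSE)
  cfg <- analysis_config(strata = "all", bootstrap_n = 5, adjust_bh = TRUE,
                         seed = 3)
  an <- run_full_analysis(rec, cfg)
  expect_true("p_bh" %in% names(an$comparison))
  expect_null(an$icc)
  # raw rejections hover near the nominal rate; BH prunes them
  expect_lt(mean(an$comparison$p < 0.05), 0.15)
  expect_lte(sum(an$comparison$p_bh < 0.05), sum(an$comparison$p < 0.05))
})

test_that("degenerate strata are reported as NA rather than dropped", {
  rec <- synthetic_feature_table(seed = 5, shift = 1)
  rec <- rec[!(rec$zone == "TZ" & rec$label == "csPCa"), ]  # TZ: one class
  an <- run_full_analysis(rec, analysis_config(bootstrap_n = 5, seed = 1))
  tz <- an$comparison[an$comparison$stratum == "TZ", ]
  expect_identical(nrow(tz), 93L)
  expect_true(all(is.na(tz$p)))
})
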