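test_that("PSAD reproduces the cohort-table group values", {
  expect_equal(round(psad(6, 62), 2), 0.10)
  expect_equal(round(psad(7.45, 47), 2), 0.16)
  expect_equal(round(psad(9.7, 46), 2), 0.21)
  expect_equal(psad(0, 50), 0)
  expect_equal(psad(c(6, 7.45), c(62, 47)), c(6 / 62, 7.45 / 47))
  expect_error(psad(5, 0), "positive")
  expect_error(psad(5, -10), "positive")
})

test_that("exact Mann-Whitney p agrees with full enumeration for small
          samples", {
  # the canonical hand case: complete separation of {1,2,3} and {4,5}
  cmp <- mwu_test(c(1, 2, 3), c(4, 5))
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p, 0.2)
  expect_equal(cmp$p, oracle_mwu_exact(c(1, 2, 3), c(4, 5)))

  # randomized small samples, n1 + n2 <= 8, no ties
  set.seed(31)
  for (r in 1:20) {
    n1 <- sample(2:4, 1)
    n2 <- sample(2:4, 1)
    x <- round(rnorm(n1, 0, 10), 6)
    y <- round(rnorm(n2, 1, 10), 6)
    cmp <- mwu_test(x, y)
    expect_equal(cmp$p, oracle_mwu_exact(x, y), tolerance = 1e-12)
  }
})

test_that("degenerate and symmetric Mann-Whitney cases", {
  expect_equal(mwu_test(c(2, 2, 2), c(2, 2))$p, 1)
  a <- c(0.3, 1.2, 2.5, 0.9)
  b <- c(1.0, 1.7, 0.1)
  f <- mwu_test(a, b)
  g <- mwu_test(b, a)
  expect_equal(f$p, g$p)
  expect_equal(g$U, length(a) * length(b) - f$U)   # U' = n1 n2 - U
})

test_that("large tied samples fall back to the tie-corrected normal
          approximation", {
  set.seed(32)
  x <- sample(1:5, 60, replace = TRUE)
  y <- sample(1:5, 60, replace = TRUE) + 1
  cmp <- mwu_test(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(cmp$p, ref$p.value)
  expect_lte(cmp$U, 3600)
  expect_gte(cmp$U, 0)
})

test_that("AUC rating bands", {
  expect_identical(rate_auc(0.84), "excellent")
  expect_identical(rate_auc(0.70), "acceptable")
  expect_identical(rate_auc(1.0), "outstanding")
  expect_identical(rate_auc(c(0.69, 0.799, 0.80, 0.90, 0.50)),
                   c("poor", "acceptable", "excellent", "outstanding", "poor"))
})

test_that("upsampling balances 11 vs 41 to 41 vs 41 without inventing
          records", {
  rec <- data.frame(id = sprintf("P%02d", 1:52),
                    label = rep(c("csPCa", "non-csPCa"), c(11, 41)))
  up <- upsample(rec, seed = 4)
  expect_identical(as.integer(table(up$label)), c(41L, 41L))
  # multiplicities change but the set of distinct minority records does not
  expect_setequal(unique(up$id[up$label == "csPCa"]), rec$id[1:11])
  # balanced input is returned unchanged
  bal <- data.frame(label = rep(c("csPCa", "non-csPCa"), each = 5))
  expect_identical(upsample(bal, seed = 1), bal)
  # determinism
  expect_identical(upsample(rec, seed = 9), upsample(rec, seed = 9))
})

test_that("ICC(3,1): identity, additive invariance, and a hand-worked ANOVA
          table", {
  r1 <- c(9, 8, 7, 10, 6)
  expect_equal(icc3(r1, r1)$icc, 1)
  expect_identical(icc3(r1, r1)$rating, "excellent")
  expect_equal(icc3(r1, r1 + 3)$icc, 1)   # consistency form

  # 4-subject table, mean squares computed independently via aov()
  s1 <- c(9, 2, 5, 8)
  s2 <- c(6, 1, 8, 2)
  d <- data.frame(y = c(s1, s2),
                  subj = factor(rep(1:4, 2)), rater = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  bms <- ms[1]; ems <- ms[3]
  expect_equal(icc3(s1, s2)$icc, (bms - ems) / (bms + ems))

  expect_error(icc3(c(1), c(2)), "at least 2")
  expect_error(icc3(1:3, 1:4), "length")
})

test_that("ICC ratings follow the reliability bands", {
  set.seed(33)
  subj <- rnorm(40, 0, 1)
  noisy <- function(sd) subj + rnorm(40, 0, sd)
  expect_identical(icc3(subj, noisy(0.05))$rating, "excellent")
  expect_identical(icc3(subj, noisy(3))$rating, "poor")
})
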