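test_that("the registry holds exactly 93 uniquely named features with the
          documented family sizes", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 93L)
  expect_identical(anyDuplicated(reg$name), 0L)
  sizes <- table(reg$family)
  expect_identical(as.integer(sizes[c("firstorder", "glcm", "gldm", "glrlm",
                                      "glszm", "ngtdm")]),
                   c(18L, 24L, 14L, 16L, 16L, 5L))
  expect_identical(reg$index, seq_len(93L))
})

test_that("any patch yields exactly 93 named values in registry order", {
  set.seed(8)
  for (dims in list(c(4, 4, 1), c(3, 5, 2), c(2, 2, 1))) {
    p <- array(rnorm(prod(dims), 150, 35), dims)
    fv <- compute_feature_vector(p)
    expect_identical(names(fv), feature_names())
  }
})

test_that("constant patch: entropy-type features 0, uniformity-type 1,
          texture conventions applied", {
  fv <- compute_feature_vector(array(5, c(4, 4, 1)))
  expect_equal(unname(fv["firstorder.Entropy"]), 0)
  expect_equal(unname(fv["firstorder.Uniformity"]), 1)
  expect_equal(unname(fv["glcm.JointEntropy"]), 0)
  expect_equal(unname(fv["glcm.JointEnergy"]), 1)
  # run and dependence entropies mix in patch geometry (diagonal run lengths,
  # border-truncated neighbourhoods), so they are nonzero even on a constant
  # patch; only the purely intensity-driven entropies collapse to 0
  expect_gt(unname(fv["glrlm.RunEntropy"]), 0)
  expect_gt(unname(fv["gldm.DependenceEntropy"]), 0)
  expect_equal(unname(fv["ngtdm.Coarseness"]), 1e6)
  expect_false(any(is.nan(fv)))   # >= 2 voxels: conventions, not NaN
})

test_that("single-voxel patch: first-order defined, texture families NaN", {
  fv <- compute_feature_vector(array(7, c(1, 1, 1)))
  expect_equal(unname(fv["firstorder.Mean"]), 7)
  reg <- feature_registry()
  tex <- reg$name[reg$family != "firstorder"]
  expect_true(all(is.nan(fv[tex])))
  expect_identical(sum(is.nan(fv)), 75L)
})

test_that("features are invariant to voxel enumeration order (axis
          mirroring)", {
  set.seed(21)
  p <- array(rnorm(48, 120, 30), c(4, 4, 3))
  f1 <- compute_feature_vector(p)
  f2 <- compute_feature_vector(p[4:1, , ])
  f3 <- compute_feature_vector(p[, , 3:1])
  expect_equal(f1, f2)
  expect_equal(f1, f3)
})

test_that("settings propagate: bin width changes histogram features only,
          alpha reaches the dependence family", {
  set.seed(9)
  p <- array(rnorm(16, 100, 30), c(4, 4, 1))
  f25 <- compute_feature_vector(p, feature_settings(bin_width = 25))
  f10 <- compute_feature_vector(p, feature_settings(bin_width = 10))
  expect_equal(f25["firstorder.Mean"], f10["firstorder.Mean"])
  expect_false(isTRUE(all.equal(f25["glcm.JointEntropy"],
                                f10["glcm.JointEntropy"])))
  fa <- compute_feature_vector(p, feature_settings(alpha = 5))
  expect_gte(fa[["gldm.LargeDependenceEmphasis"]],
             f25[["gldm.LargeDependenceEmphasis"]])
})
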