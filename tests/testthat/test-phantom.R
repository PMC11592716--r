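# small, fast phantom configuration used throughout these tests
phantom_cfg <- function(...) {
  cohort_config(image_shape = c(32, 32, 6), lesion_radii_mm = c(3.5, 6),
                seed = 11, ...)
}

case_of <- function(outcome, zone = "PZ", cfg = phantom_cfg(), seed = 42) {
  rec <- data.frame(id = "T01", zone = zone, outcome = outcome)
  generate_phantom(rec, cfg, seed = seed)
}

# mean intensity in a shell of background voxels around the lesion
background_shell_mean <- function(case) {
  m <- case$mask_rater1$data
  mean(case$volume$data[!m])
}

test_that("csPCa lesions are hypointense relative to the background", {
  cs <- case_of("csPCa")
  inside <- mean(cs$volume$data[cs$mask_rater1$data])
  expect_lt(inside, background_shell_mean(cs))
  # and markedly lower than a non-csPCa lesion of the same geometry
  no <- case_of("noPCa")
  expect_lt(inside, mean(no$volume$data[no$mask_rater1$data]))
})

test_that("a null lesion effect leaves the lesion indistinguishable from
          background", {
  cfg <- phantom_cfg(lesion_effect = lesion_effect_null())
  deltas <- vapply(1:10, function(s) {
    cs <- case_of("csPCa", cfg = cfg, seed = s)
    mean(cs$volume$data[cs$mask_rater1$data]) - background_shell_mean(cs)
  }, numeric(1))
  # mean intensity difference fluctuates around zero
  expect_lt(abs(mean(deltas)), 5)
})

test_that("the two raters' masks overlap strongly but are not identical", {
  for (s in 1:8) {
    cs <- case_of("csPCa", seed = s)
    expect_gt(sum(cs$mask_rater1$data), 0)
    expect_gt(sum(cs$mask_rater2$data), 0)
    expect_gt(dice_coefficient(cs$mask_rater1, cs$mask_rater2), 0.5)
  }
  expect_false(identical(case_of("csPCa", seed = 3)$mask_rater1$data,
                         case_of("csPCa", seed = 3)$mask_rater2$data))
})

test_that("phantoms regenerate exactly under the same seed", {
  a <- case_of("ciPCa", seed = 9)
  b <- case_of("ciPCa", seed = 9)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask_rater1$data, b$mask_rater1$data)
  expect_identical(a$mask_rater2$data, b$mask_rater2$data)
  expect_false(identical(a$volume$data,
                         case_of("ciPCa", seed = 10)$volume$data))
})

test_that("zone steers the lesion position", {
  pz <- case_of("noPCa", zone = "PZ", seed = 4)
  tz <- case_of("noPCa", zone = "TZ", seed = 4)
  expect_gt(pz$lesion_center[2], tz$lesion_center[2])
})

test_that("oversized lesion radii are rejected", {
  cfg <- cohort_config(image_shape = c(16, 16, 4),
                       lesion_radii_mm = c(10, 12), seed = 1)
  rec <- data.frame(id = "T01", zone = "PZ", outcome = "csPCa")
  expect_error(generate_phantom(rec, cfg, seed = 1), "exceed")
})

test_that("full cohort generation attaches one phantom per record", {
  cfg <- cohort_config(n_noPCa_PZ = 2, n_noPCa_TZ = 1, n_ciPCa_PZ = 1,
                       n_ciPCa_TZ = 0, n_csPCa_PZ = 2, n_csPCa_TZ = 1,
                       image_shape = c(24, 24, 4), lesion_radii_mm = c(3, 5),
                       seed = 21)
  co <- generate_cohort(cfg)
  expect_identical(length(co$cases), nrow(co$records))
  expect_identical(names(co$cases), co$records$id)
  # phantom stream is independent of the covariate stream: records identical
  expect_identical(co$records, generate_records(cfg))
})
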