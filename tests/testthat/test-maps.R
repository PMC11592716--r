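make_test_volume <- function(dims = c(16, 16, 2), seed = 1, sd = 40) {
  set.seed(seed)
  image_volume(array(rnorm(prod(dims), 200, sd), dims),
               spacing = c(0.5, 0.5, 3))
}

test_that("the stack always holds 93 maps sharing the grid shape", {
  v <- make_test_volume()
  st <- compute_maps(v)
  expect_identical(dim(st$maps), c(4L, 4L, 2L, 93L))
  expect_identical(dimnames(st$maps)[[4]], feature_names())
})

test_that("constant volume: entropy map identically 0, uniformity map
          identically 1", {
  v <- image_volume(array(7, c(8, 8, 2)), spacing = c(0.5, 0.5, 3))
  st <- compute_maps(v)
  expect_true(all(get_map(st, "firstorder.Entropy") == 0))
  expect_true(all(get_map(st, "firstorder.Uniformity") == 1))
  expect_true(all(get_map(st, "firstorder.Variance") == 0))
})

test_that("the mean map equals an independent block-averaging oracle", {
  v <- make_test_volume(seed = 3)
  g <- build_grid(v)
  st <- compute_maps(v, g)
  m <- get_map(st, "firstorder.Mean")
  for (k in seq_len(g$dim[3])) for (j in seq_len(g$dim[2]))
    for (i in seq_len(g$dim[1])) {
      expect_equal(m[i, j, k], mean(cell_patch(v, g, c(i, j, k))))
    }
})

test_that("round trip: a VOI aligned to one full cell reproduces that patch's
          feature vector bit-identically", {
  v <- make_test_volume(seed = 5)
  g <- build_grid(v)
  st <- compute_maps(v, g)
  mask <- array(FALSE, dim(v$data))
  mask[5:8, 9:12, 2] <- TRUE       # exactly cell (2, 3, 2)
  voi <- transfer_voi(segmentation_mask(mask, v$spacing), g)
  expect_identical(sum(voi), 1L)
  got <- extract_map_means(st, voi)
  want <- compute_feature_vector(cell_patch(v, g, c(2, 3, 2)),
                                 feature_settings(voxel_volume =
                                                    prod(v$spacing)))
  expect_identical(unname(got), unname(want))
})

test_that("shifting the volume content by one cell shifts the maps by one
          cell", {
  v <- make_test_volume(dims = c(20, 16, 2), seed = 6)
  shifted <- v
  shifted$data <- v$data[c(5:20, 1:4), , ]   # content moved by one 4-voxel cell
  s1 <- compute_maps(v)
  s2 <- compute_maps(shifted)
  # interior cells: map value at x-index i of the original appears at i-1
  expect_equal(s1$maps[2:5, , , ], s2$maps[1:4, , , ])
})

test_that("maps are finite wherever cells have >= 2 voxels and >= 2 gray
          levels", {
  v <- make_test_volume(seed = 8)
  st <- compute_maps(v)
  expect_false(any(is.nan(st$maps)))
})

test_that("map NIfTI round trip preserves values, geometry and names", {
  v <- make_test_volume(dims = c(8, 8, 2), seed = 9)
  st <- compute_maps(v)
  dir <- withr::local_tempdir()
  write_maps(st, dir, gzip = FALSE)
  expect_length(list.files(dir, pattern = "\\.nii$"), 93L)
  rt <- read_maps(dir)
  expect_equal(rt$maps, st$maps, tolerance = 1e-6)
  expect_equal(rt$grid$cell_size, st$grid$cell_size)
})
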