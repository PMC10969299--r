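cube_prep <- function(levels, n_levels = max(levels), spacing = c(1, 1, 1)) {
  list(levels = levels, mask = levels > 0, n_levels = as.integer(n_levels),
       spacing = spacing)
}

test_that("discretization policies enforce the 60-67 bin window", {
  p <- discretization_policy("range_binwidth", value_range = c(0, 1),
                             bin_width = 1 / 64)
  expect_equal(ceiling(1 / p$bin_width), 64)        # inside 60-67
  expect_error(discretization_policy("range_binwidth", value_range = c(0, 1),
                                     bin_width = 0.1), "outside")
  expect_error(discretization_policy("range_binwidth"), "value_range")
  # defaults: every biomarker policy derives 64 bins from its range
  for (p in Filter(is.list, biomarker_policies()))
    expect_equal(ceiling(diff(p$value_range) / p$bin_width - 1e-9), 64)
})

test_that("preprocessing z-scores, clips, resamples and discretizes", {
  set.seed(1)
  vol <- array(rnorm(16^3, 50, 10), c(16, 16, 16))
  mask <- ellipsoid <- array(FALSE, c(16, 16, 16)); mask[5:12, 5:12, 5:12] <- TRUE
  pz <- preprocess_map(volume_grid(vol), mask,
                       discretization_policy("zscore_binwidth"),
                       norm_mask = array(TRUE, dim(vol)))
  # z-scored image has mean 0, sd 1 over the normalization mask by definition
  z <- (vol - mean(vol)) / sd(vol)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_true(all(pz$levels[pz$mask] >= 1))
  # constant image occupies a single bin
  pc <- preprocess_map(volume_grid(array(7, c(16, 16, 16))), mask,
                       discretization_policy("zscore_binwidth"))
  expect_equal(unique(pc$levels[pc$mask]), 1L)
  # biomarker range [0,1] / 64 bins
  pb <- preprocess_map(volume_grid(array(runif(16^3), c(16, 16, 16))), mask,
                       discretization_policy("range_binwidth",
                                             value_range = c(0, 1)))
  expect_equal(pb$n_levels, 64L)
  expect_true(all(pb$levels[pb$mask] %in% 1:64))
  expect_error(preprocess_map(volume_grid(vol), array(FALSE, dim(vol)),
                              discretization_policy("zscore_binwidth")),
               "empty")
})

test_that("resampling halves voxel counts at doubled spacing and back", {
  vol <- volume_grid(array(1:(8^3), c(8, 8, 8)), spacing = c(2, 2, 2))
  fine <- resample_volume(vol, 1)
  expect_equal(dim(fine$data), c(16, 16, 16))
  # intensities are interpolated, masks stay binary under nearest neighbour
  m <- resample_volume(volume_grid(array(c(0, 1), c(8, 8, 8)),
                                   spacing = c(2, 2, 2)), 1, "nearest")
  expect_true(all(m$data %in% c(0, 1)))
})

test_that("the feature vector has exactly the 107 manifest names", {
  mf <- feature_manifest()
  expect_length(mf, 107L)
  expect_equal(sum(startsWith(mf, "shape_")), 14L)
  expect_equal(sum(startsWith(mf, "firstorder_")), 18L)
  expect_equal(sum(startsWith(mf, "glcm_")), 24L)
  expect_equal(sum(startsWith(mf, "glrlm_")), 16L)
  expect_equal(sum(startsWith(mf, "glszm_")), 16L)
  expect_equal(sum(startsWith(mf, "gldm_")), 14L)
  expect_equal(sum(startsWith(mf, "ngtdm_")), 5L)
  set.seed(2)
  lev <- array(sample(1:8, 6^3, TRUE), c(6, 6, 6))
  f <- extract_features(cube_prep(lev, 8))
  expect_length(f, 107L)
  expect_identical(names(f), mf)
  expect_true(all(is.finite(f)))
  # deterministic for fixed input
  expect_identical(f, extract_features(cube_prep(lev, 8)))
  expect_error(extract_features(cube_prep(array(c(1L, rep(0L, 26)),
                                                c(3, 3, 3)))), "8 voxels")
})

test_that("first-order features of a uniform cube are degenerate", {
  lev <- array(5L, c(4, 4, 4))
  f <- extract_features(cube_prep(lev, 8))
  expect_equal(unname(f["firstorder_Mean"]), 5)
  expect_equal(unname(f["firstorder_Variance"]), 0)
  expect_equal(unname(f["firstorder_Entropy"]), 0)
  expect_equal(unname(f["firstorder_Uniformity"]), 1)
  # shape: 4 mm cube of 1 mm voxels
  expect_equal(unname(f["shape_VoxelVolume"]), 64)
  expect_equal(unname(f["shape_SurfaceArea"]), 6 * 16)
})

test_that("a 3-D checkerboard has strictly higher GLCM contrast than uniform", {
  idx <- expand.grid(1:4, 1:4, 1:4)
  cb <- array(1L + (rowSums(idx) %% 2L), c(4, 4, 4))
  un <- array(1L, c(4, 4, 4))
  fc <- extract_features(cube_prep(cb, 2))
  fu <- extract_features(cube_prep(un, 2))
  expect_gt(fc["glcm_Contrast"], fu["glcm_Contrast"])
  # brute-force axis-offset co-occurrence oracle on the checkerboard:
  # every face-adjacent pair differs, every 2-D diagonal pair matches
  expect_equal(unname(fu["glcm_Contrast"]), 0)
})

test_that("first-order features are invariant to affine intensity rescaling", {
  set.seed(3)
  vol <- array(rnorm(12^3, 100, 15), c(12, 12, 12))
  mask <- array(FALSE, c(12, 12, 12)); mask[3:10, 3:10, 3:10] <- TRUE
  bmask <- array(TRUE, c(12, 12, 12))
  f1 <- extract_features(preprocess_map(volume_grid(vol), mask,
                                        discretization_policy("zscore_binwidth"),
                                        norm_mask = bmask))
  f2 <- extract_features(preprocess_map(volume_grid(3 * vol + 40), mask,
                                        discretization_policy("zscore_binwidth"),
                                        norm_mask = bmask))
  fo <- startsWith(names(f1), "firstorder_")
  expect_equal(f1[fo], f2[fo], tolerance = 1e-12)
})

test_that("shape features depend only on the mask, not the intensities", {
  set.seed(4)
  mask <- array(FALSE, c(10, 10, 10)); mask[3:8, 3:8, 4:7] <- TRUE
  l1 <- array(sample(1:6, 1000, TRUE), c(10, 10, 10))
  l2 <- array(sample(1:6, 1000, TRUE), c(10, 10, 10))
  l1[!mask] <- 0L; l2[!mask] <- 0L
  f1 <- extract_features(list(levels = l1, mask = mask, n_levels = 6L,
                              spacing = c(1, 1, 1)))
  f2 <- extract_features(list(levels = l2, mask = mask, n_levels = 6L,
                              spacing = c(1, 1, 1)))
  sh <- startsWith(names(f1), "shape_")
  expect_identical(f1[sh], f2[sh])
})

test_that("category vectors concatenate to 428 and 856 in canonical order", {
  v <- setNames(as.numeric(1:107), feature_manifest())
  per_map <- list(OEF = v, CMRO2 = v + 1000, capiPO2 = v + 2000,
                  mitoPO2 = v + 3000)
  out <- assemble_vector(per_map, "oxymet")
  expect_length(out, 428L)
  expect_true(startsWith(names(out)[1], "OEF_"))
  # permuting the input order does not change the output order
  out2 <- assemble_vector(per_map[c(3, 1, 4, 2)], "oxymet")
  expect_identical(out, out2)
  per_map8 <- c(per_map, list(uCBV = v, MVD = v, VSI = v, MTI = v))
  expect_length(assemble_vector(per_map8, "oxyvam"), 856L)
  expect_error(assemble_vector(per_map[-2], "oxymet"), "CMRO2")
})

test_that("patient-level extraction yields 428 features per category", {
  m <- small_mapped()
  f <- patient_features(m, "oxymet")
  expect_length(f, 428L)
  expect_true(all(is.finite(f)))
  f2 <- patient_features(m, "vam")
  expect_length(f2, 428L)
  expect_true(all(is.finite(f2)))
})
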