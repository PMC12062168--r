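toy_volume <- function(values, dim3, spacing = 1) {
  sirt_volume(array(values, dim = dim3), spacing = rep(spacing, 3),
              units = "Gy")
}

test_that("the signature holds exactly 107 features with the documented family sizes", {
  case <- cached_test_case()
  f <- extract_features(case$spect_y90, case$structures$tumor,
                        bin_width = 50)
  expect_length(f, 107)
  expect_true(all(is.finite(f)))
  fam <- table(sub("_.*$", "", names(f)))
  counts <- feature_family_counts()
  expect_equal(fam[names(counts)], table(rep(names(counts), counts))[
    names(counts)], ignore_attr = TRUE)
  expect_equal(sum(feature_family_counts()), 107L)
})

test_that("first-order features match hand-computed values on a 3x3x3 ROI", {
  x <- 1:27
  vol <- toy_volume(x, c(3, 3, 3))
  mask <- array(TRUE, c(3, 3, 3))
  f <- extract_features(vol, mask, bin_width = 5)
  expect_equal(unname(f["firstorder_Mean"]), 14)
  expect_equal(unname(f["firstorder_Energy"]), sum(x^2))
  expect_equal(unname(f["firstorder_Variance"]), mean((x - 14)^2))
  expect_equal(unname(f["firstorder_Minimum"]), 1)
  expect_equal(unname(f["firstorder_Maximum"]), 27)
  expect_equal(unname(f["firstorder_Median"]), 14)
  expect_equal(unname(f["firstorder_Range"]), 26)
  # histogram oracle: fixed bin width 5, edges aligned to multiples of 5
  lev <- floor(x / 5) - floor(min(x) / 5) + 1
  p <- as.numeric(table(lev)) / 27
  expect_equal(unname(f["firstorder_Entropy"]), -sum(p * log2(p)))
  expect_equal(unname(f["firstorder_Uniformity"]), sum(p^2))
  expect_equal(unname(f["firstorder_RootMeanSquared"]), sqrt(mean(x^2)))
})

test_that("GLCM features match a hand-built co-occurrence matrix", {
  vol <- toy_volume(c(1, 1, 2), c(3, 1, 1))
  mask <- array(TRUE, c(3, 1, 1))
  f <- extract_features(vol, mask, bin_width = 1)
  # pairs along x: (1,1) and (1,2); symmetric counts 2,1,1,0 -> P/4
  expect_equal(unname(f["glcm_Contrast"]), 0.5)
  expect_equal(unname(f["glcm_MaximumProbability"]), 0.5)
  expect_equal(unname(f["glcm_JointEntropy"]),
               -(0.5 * log2(0.5) + 2 * 0.25 * log2(0.25)))
  expect_equal(unname(f["glcm_JointEnergy"]), 0.25 + 2 * 0.0625)
})

test_that("texture matrix kernels match hand enumeration on a 3-voxel line", {
  g <- array(c(1L, 1L, 2L), c(3, 1, 1))
  dims <- c(3L, 1L, 1L)
  rlm <- sirtomics:::cpp_glrlm(as.integer(g), dims, 2L)
  expect_equal(rlm[1, 1], 24) # level 1, length 1: 2 voxels x 12 directions
  expect_equal(rlm[1, 2], 1)  # the single length-2 run along x
  expect_equal(rlm[2, 1], 13) # level 2: 12 off-axis + 1 axial
  nt <- sirtomics:::cpp_ngtdm(as.integer(g), dims, 2L)
  expect_equal(nt[, 1], c(2, 1))     # n_i
  expect_equal(nt[, 2], c(0.5, 1))   # s_i
  dl <- sirtomics:::cpp_gldm(as.integer(g), dims, 2L, 0L)
  expect_equal(dl[1, 2], 2) # two level-1 voxels with one dependent neighbor
  expect_equal(dl[2, 1], 1) # the level-2 voxel has none
  sz <- sirtomics:::cpp_glszm(as.integer(g), dims, 2L)
  expect_equal(sz[order(sz[, 1]), , drop = FALSE],
               matrix(c(1L, 2L, 2L, 1L), 2, 2))
})

test_that("degenerate flat ROIs return defined limits, not NaN", {
  vol <- toy_volume(rep(7, 64), c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  f <- extract_features(vol, mask, bin_width = 1)
  expect_true(all(is.finite(f)))
  expect_equal(unname(f["firstorder_Variance"]), 0)
  expect_equal(unname(f["firstorder_Entropy"]), 0)
  expect_equal(unname(f["firstorder_Uniformity"]), 1)
  expect_equal(unname(f["glcm_Correlation"]), 1)
  expect_equal(unname(f["ngtdm_Coarseness"]), 1e6)
})

test_that("a voxelized sphere is near-spherical with consistent volumes", {
  dim3 <- c(26L, 26L, 26L)
  cc <- 13.5; r <- 9
  g <- as.matrix(expand.grid(1:26, 1:26, 1:26))
  mask <- array(FALSE, dim3)
  mask[g[(g[, 1] - cc)^2 + (g[, 2] - cc)^2 + (g[, 3] - cc)^2 <= r^2, ]] <- TRUE
  vol <- toy_volume(rnorm(prod(dim3), 50, 5), dim3, spacing = 2)
  f <- extract_features(vol, mask, bin_width = 5)
  expect_gt(unname(f["shape_Sphericity"]), 0.92)
  expect_lt(unname(f["shape_Sphericity"]), 1.02)
  expect_equal(unname(f["shape_VoxelVolume"]), sum(mask) * 8)
  expect_lt(abs(f[["shape_MeshVolume"]] - f[["shape_VoxelVolume"]]) /
              f[["shape_VoxelVolume"]], 0.12)
  expect_lt(abs(f[["shape_Maximum3DDiameter"]] - 2 * r * 2) / (2 * r * 2),
            0.15)
  expect_lt(f[["shape_Flatness"]], 1 + 1e-9)
})

test_that("features are invariant to joint translation of image and mask", {
  set.seed(8)
  dim3 <- c(14L, 14L, 14L)
  img <- array(0, dim3)
  mask <- array(FALSE, dim3)
  img[3:7, 3:7, 3:7] <- rnorm(125, 100, 20)
  mask[3:7, 3:7, 3:7] <- TRUE
  img2 <- array(0, dim3); mask2 <- array(FALSE, dim3)
  img2[6:10, 7:11, 5:9] <- img[3:7, 3:7, 3:7]
  mask2[6:10, 7:11, 5:9] <- TRUE
  f1 <- extract_features(toy_volume(img, dim3), mask, 10)
  f2 <- extract_features(toy_volume(img2, dim3), mask2, 10)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("preprocessing applies the channel-specific rules", {
  cfg <- preprocess_config()
  ct <- sirt_volume(array(c(-900, 0, 700, 20), c(4, 1, 1)),
                    spacing = c(1.5, 1.5, 1.5), units = "HU")
  out <- preprocess_volume(ct, "CT", cfg = cfg)
  expect_equal(min(out$data), -500)
  expect_equal(max(out$data), 500)
  # MAA tumor cap
  dm <- sirt_volume(array(c(10, 700, 200), c(3, 1, 1)), units = "Gy")
  out2 <- preprocess_volume(dm, "MAA_dose", "tumor", cfg)
  expect_equal(max(out2$data), 650.34)
  out3 <- preprocess_volume(dm, "Y90_dose", "npl", cfg)
  expect_equal(max(out3$data), 133.16)
  # constant SPECT equals its own percentile: idempotent
  sp <- sirt_volume(array(5, c(4, 4, 4)), units = "counts_s")
  expect_equal(preprocess_volume(sp, "SPECT", cfg = cfg)$data, sp$data)
  expect_error(preprocess_volume(sp, "PET", cfg = cfg), "unknown channel")
})

test_that("feature tables have 321 columns and deterministic rows", {
  case <- cached_test_case()
  tb <- build_feature_table(list(case), "SPECT_Y90")
  expect_equal(nrow(tb), 1)
  expect_equal(ncol(tb) - 2, 321) # case_id, label + 3 x 107
  expect_false(any(duplicated(names(tb))))
  expect_true(all(grepl("_(tumor|npl|wnl)$",
                        setdiff(names(tb), c("case_id", "label")))))
  tb2 <- build_feature_table(list(case, case), "SPECT_Y90")
  expect_equal(as.numeric(tb2[1, -1:-2]), as.numeric(tb2[2, -1:-2]))
})

test_that("cases with corrupt masks are excluded with a message", {
  case <- cached_test_case()
  broken <- case
  broken$case_id <- "broken"
  broken$structures$tumor[] <- FALSE
  expect_message(
    tb <- build_feature_table(list(case, broken), "SPECT_Y90"),
    "excluded")
  expect_equal(nrow(tb), 1)
})

test_that("dosiomics reuse the same extractor on clipped dose maps", {
  u <- uniform_dose_case(500) # above the Y90 tumor cap of 416.25
  cfg <- preprocess_config()
  v <- preprocess_volume(u$maps$y90_dose, "Y90_dose", "tumor", cfg)
  expect_equal(unique(as.numeric(v$data)), 416.25)
  f <- extract_features(v, u$structures$tumor, cfg$bin_width$dose)
  expect_length(f, 107)
  expect_equal(unname(f["firstorder_Mean"]), 416.25)
})
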