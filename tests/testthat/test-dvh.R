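dose_from_values <- function(values, spacing = 10) {
  # 10 mm voxels -> 1 ml each
  as_dose_map(sirt_volume(array(values, dim = c(length(values), 1, 1)),
                          spacing = rep(spacing, 3), units = "Gy"),
              channel = "Y90", kind = "dose")
}

full_mask <- function(n) array(TRUE, dim = c(n, 1, 1))

test_that("uniform dose gives a step-function DVH", {
  d <- dose_from_values(rep(10, 6))
  curve <- cumulative_dvh(d, full_mask(6))
  expect_equal(volume_at_dose(curve, 10, "percent"), 100)
  expect_equal(volume_at_dose(curve, 10.01, "percent"), 0)
  expect_equal(volume_at_dose(curve, 0, "percent"), 100)
  expect_equal(dose_at_volume(curve, c(5, 50, 95)), rep(10, 3))
  expect_equal(curve$volume_pct[1], 100)
  expect_true(all(diff(curve$volume_ml) <= 0))
})

test_that("four-voxel hand examples: D_x, V_x, HI", {
  d <- dose_from_values(c(1, 2, 3, 4))
  curve <- cumulative_dvh(d, full_mask(4))
  expect_equal(volume_at_dose(curve, 2, "ml"), 3)
  expect_equal(volume_at_dose(curve, 2, "percent"), 75)
  expect_equal(volume_at_dose(curve, 3, "ml"), 2)
  expect_equal(volume_at_dose(curve, 3, "percent"), 50)
  expect_equal(dose_at_volume(curve, 50), 3)
  expect_equal(dose_at_volume(curve, 5), 4)
  expect_equal(dose_at_volume(curve, 95), 1)
  expect_equal(dose_at_volume(curve, 5) / dose_at_volume(curve, 95), 4)
  expect_equal(volume_at_dose(curve, 5, "ml"), 0) # above D_max
})

test_that("input validation", {
  d <- dose_from_values(1:4)
  expect_error(cumulative_dvh(d, array(FALSE, c(4, 1, 1))), "empty mask")
  expect_error(cumulative_dvh(d, full_mask(4), bin_width_Gy = 0),
               "bin_width")
  curve <- cumulative_dvh(d, full_mask(4))
  expect_error(dose_at_volume(curve, 0), "percent")
  expect_error(dose_at_volume(curve, 101), "percent")
  expect_error(volume_at_dose(curve, -1), "threshold")
})

test_that("DVH metrics match a brute-force sort-and-count oracle exactly", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(3:1000, 1)
    vals <- round(runif(n, 0, 300), 2)
    d <- dose_from_values(vals)
    curve <- cumulative_dvh(d, full_mask(n))
    srt <- sort(vals, decreasing = TRUE)
    for (x in c(5, 50, 70, 95, 98)) {
      # oracle: minimum dose among the hottest ceil(x% n) voxels
      expect_identical(dose_at_volume(curve, x),
                       srt[ceiling(x / 100 * n)])
    }
    thr <- runif(1, 0, 300)
    expect_identical(volume_at_dose(curve, thr, "ml"), sum(vals >= thr) * 1)
    dx <- dose_at_volume(curve, c(98, 95, 70, 50, 5))
    expect_true(all(diff(dx) >= 0)) # D98 <= D95 <= D70 <= D50 <= D5
    expect_gte(dose_at_volume(curve, 5) / dose_at_volume(curve, 95), 1)
  }
})

test_that("ml and percent volumes are consistent to 1e-12", {
  set.seed(4)
  vals <- runif(500, 0, 120)
  curve <- cumulative_dvh(dose_from_values(vals), full_mask(500))
  for (t in c(0, 10, 50, 119)) {
    expect_equal(volume_at_dose(curve, t, "ml") / curve$total_volume_ml,
                 volume_at_dose(curve, t, "percent") / 100,
                 tolerance = 1e-12)
  }
})

test_that("TNR is a ratio of mean doses, invariant to rescaling", {
  u <- uniform_dose_case(50)
  expect_equal(tnr(u$maps$y90_dose, u$structures$tumor, u$structures$npl),
               1)
  d <- u$maps$y90_dose
  d$data[u$structures$tumor] <- 40
  d$data[u$structures$npl] <- 10
  expect_equal(tnr(d, u$structures$tumor, u$structures$npl), 4)
  d2 <- d; d2$data <- d$data * 3.7
  expect_equal(tnr(d2, u$structures$tumor, u$structures$npl), 4)
  d$data[] <- 0
  expect_error(tnr(d, u$structures$tumor, u$structures$npl), "undefined")
})

test_that("uniform dose yields a degenerate DVC record with HI = 1", {
  u <- uniform_dose_case(100)
  rec <- extract_dvcs(u$maps, u$structures, lsf = 0.05, activity_GBq = 2.8)
  for (m in c("D5", "D50", "D70", "D95", "D98", "Dmean", "Dmax", "Dmin")) {
    expect_equal(rec[[paste0("tumor_Y90_dose_", m)]], 100)
  }
  expect_equal(rec$HI_Y90_dose, 1)
  expect_equal(rec$HI_MAA_dose, 1)
  expect_equal(rec$tumor_Y90_dose_V400_pct, 0)
  expect_equal(rec$npl_Y90_dose_V50_pct, 100)
  expect_equal(rec$TNR_NPL_Y90_dose, 1)
  expect_equal(rec$LSF, 0.05)
  expect_equal(rec$injected_activity_GBq, 2.8)
})

test_that("DVC records have a fixed schema across cases", {
  cohort <- cached_test_cohort()
  dvc <- cohort_dvc_table(cohort[1:2])
  expect_equal(nrow(dvc), 2)
  r1 <- extract_dvcs(case_dose_maps(cohort[[1]]), cohort[[1]]$structures,
                     0.05, 2.8, case_id = "a")
  r2 <- extract_dvcs(case_dose_maps(cohort[[2]]), cohort[[2]]$structures,
                     0.05, 2.8, case_id = "b")
  expect_identical(names(r1), names(r2))
})

test_that("missing dose maps are reported by name", {
  u <- uniform_dose_case(10)
  maps <- u$maps
  maps$maa_bed <- NULL
  expect_error(extract_dvcs(maps, u$structures, 0, 1), "maa_bed")
})

test_that("phantom DVC mean dose matches ground truth", {
  case <- generate_case(test_phantom_config(seed = 13,
                                            noise_model = "none"))
  rec <- extract_dvcs(case_dose_maps(case), case$structures,
                      case$truth$lsf, case$truth$injected_activity_GBq)
  expect_lt(abs(rec$tumor_Y90_dose_Dmean -
                  case$truth$mean_tumor_dose_true_Gy) /
              case$truth$mean_tumor_dose_true_Gy, 0.001)
})

test_that("autoplot returns a ggplot", {
  curve <- cumulative_dvh(dose_from_values(1:10), full_mask(10))
  expect_s3_class(ggplot2::autoplot(curve), "ggplot")
})
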