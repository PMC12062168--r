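# a 100 mm isotropic voxel has volume 1e6 mm^3 = 1000 cm^3 = 1 kg at unit
# density, which makes hand dose arithmetic transparent
two_voxel_spect <- function(counts) {
  sirt_volume(array(counts, dim = c(length(counts), 1, 1)),
              spacing = c(100, 100, 100), units = "counts_s")
}

test_that("LDM allocates energy proportionally to counts", {
  sp <- two_voxel_spect(c(3, 1))
  mask <- array(TRUE, dim = dim(sp$data))
  d <- ldm_dose_map(sp, mask, injected_activity_GBq = 1)
  expect_equal(as.numeric(d$data), c(37.2525, 12.4175))
})

test_that("a single hot voxel receives the whole energy budget", {
  sp <- two_voxel_spect(c(0, 5, 0))
  mask <- array(TRUE, dim = dim(sp$data))
  d <- ldm_dose_map(sp, mask, injected_activity_GBq = 2)
  expect_equal(as.numeric(d$data), c(0, 2 * 49.67, 0))
})

test_that("dose is linear in injected activity", {
  sp <- two_voxel_spect(c(2, 7, 1))
  mask <- array(TRUE, dim = dim(sp$data))
  d1 <- ldm_dose_map(sp, mask, 1.3)
  d2 <- ldm_dose_map(sp, mask, 2.6)
  expect_equal(d2$data, 2 * d1$data)
})

test_that("self-calibration cancels any global count rescaling", {
  case <- cached_test_case()
  d1 <- ldm_dose_map(case$spect_y90, case$structures$liver, 0.6)
  scaled <- case$spect_y90
  scaled$data <- scaled$data * 137.5
  d2 <- ldm_dose_map(scaled, case$structures$liver, 0.6)
  expect_equal(d1$data, d2$data)
})

test_that("energy is conserved in the calibration region to 1e-10", {
  case <- cached_test_case() # all activity lies inside the liver
  cfg <- ldm_config()
  act <- case$truth$injected_activity_GBq
  d <- ldm_dose_map(case$spect_y90, case$structures$liver, act, cfg)
  mass_kg <- prod(d$spacing) / 1e6
  total_J <- sum(d$data) * mass_kg
  expect_lt(abs(total_J - act * cfg$energy_per_activity_J_per_GBq) /
              (act * cfg$energy_per_activity_J_per_GBq), 1e-10)
})

test_that("noiseless phantom recovers the analytic mean tumor dose", {
  case <- generate_case(test_phantom_config(seed = 11,
                                            noise_model = "none"))
  d <- ldm_dose_map(case$spect_y90, case$structures$liver,
                    case$truth$injected_activity_GBq)
  rec <- mean(d$data[case$structures$tumor])
  expect_lt(abs(rec - case$truth$mean_tumor_dose_true_Gy) /
              case$truth$mean_tumor_dose_true_Gy, 0.001)
})

test_that("calibration errors are caught", {
  sp <- two_voxel_spect(c(0, 0))
  mask <- array(TRUE, dim = dim(sp$data))
  expect_error(ldm_dose_map(sp, mask, 1), "calibration")
  expect_error(ldm_dose_map(two_voxel_spect(c(1, 2)),
                            array(TRUE, dim = c(3, 1, 1)), 1),
               "different grids")
})

test_that("BED evaluates the linear-quadratic repair formula", {
  expect_equal(bed_voxel(0, bed_params_tumor()), 0)
  expect_equal(bed_voxel(100, bed_params_tumor()),
               100 * (1 + 10 * 1.5 / 65.7))
  expect_equal(round(bed_voxel(100, bed_params_tumor()), 3), 122.831)
  expect_equal(bed_voxel(100, bed_params_normal()),
               100 * (1 + 10 * 2.5 / 66.7))
  expect_equal(round(bed_voxel(100, bed_params_normal()), 3), 137.481)
  expect_error(bed_voxel(-1), "dose")
  expect_error(bed_params(alpha_beta_Gy = 0), "positive")
})

test_that("BED dominates dose, increases, is convex, and BED/D -> 1 at 0", {
  d <- seq(0, 500, by = 0.5)
  b <- bed_voxel(d, bed_params_tumor())
  expect_true(all(b >= d))
  expect_true(all(diff(b) > 0))
  expect_true(all(diff(diff(b)) > -1e-9)) # convexity
  small <- c(1e-6, 1e-4, 1e-2)
  expect_equal(bed_voxel(small, bed_params_normal()) / small,
               rep(1, 3), tolerance = 1e-4)
})

test_that("bed_map applies structure-specific parameters and zeroes the rest", {
  u <- uniform_dose_case(100)
  b <- bed_map(u$maps$y90_dose, u$structures)
  st <- u$structures
  expect_equal(unique(b$data[st$tumor]), 122.8310502, tolerance = 1e-9)
  expect_equal(unique(b$data[st$wnl]), 137.4812594, tolerance = 1e-9)
  outside <- !st$tumor & !st$wnl
  expect_true(all(b$data[outside] == 0))
  expect_identical(b$kind, "bed")
  expect_identical(b$channel, "Y90")
  # voxelwise domination within structures
  expect_true(all(b$data[st$tumor | st$wnl] >=
                    u$maps$y90_dose$data[st$tumor | st$wnl]))
})

test_that("bed_map rejects non-dose inputs", {
  u <- uniform_dose_case(10)
  expect_error(bed_map(u$maps$y90_bed, u$structures), "physical dose")
})

test_that("LSF deduction scales the administered activity when enabled", {
  sp <- two_voxel_spect(c(1, 1))
  mask <- array(TRUE, dim = dim(sp$data))
  d0 <- ldm_dose_map(sp, mask, 1, ldm_config(deduct_lsf = FALSE), lsf = 0.1)
  d1 <- ldm_dose_map(sp, mask, 1, ldm_config(deduct_lsf = TRUE), lsf = 0.1)
  expect_equal(d1$data, 0.9 * d0$data)
})
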