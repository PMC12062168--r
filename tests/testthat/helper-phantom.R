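# shared fixtures: a down-scaled phantom that keeps the clinical dose
# range (activity scaled with the smaller liver) so clipping caps bite
# realistically, plus a cached cohort reused across test files

test_phantom_config <- function(seed = 1L, ...) {
  phantom_config(grid_shape = c(36L, 32L, 24L), spacing_mm = 5,
                 liver_radius_mm = 60, tumor_radius_mm = 16,
                 injected_activity_GBq = 0.6, seed = seed, ...)
}

.test_cache <- new.env(parent = emptyenv())

cached_test_cohort <- function() {
  if (is.null(.test_cache$cohort)) {
    .test_cache$cohort <- generate_cohort(
      8, 3 / 8, base_config = test_phantom_config(), seed = 42)
  }
  .test_cache$cohort
}

cached_test_case <- function() {
  if (is.null(.test_cache$case)) {
    .test_cache$case <- generate_case(test_phantom_config(seed = 7))
  }
  .test_cache$case
}

# uniform-dose map helper on a small grid
uniform_dose_case <- function(value = 100, dim3 = c(10L, 10L, 8L),
                              spacing = 5) {
  arr <- array(value, dim = dim3)
  tumor <- array(FALSE, dim3); tumor[4:6, 4:6, 3:5] <- TRUE
  lobe <- array(FALSE, dim3); lobe[2:9, 2:9, 2:7] <- TRUE
  liver <- lobe
  st <- structure_set(tumor, lobe, liver, spacing = rep(spacing, 3))
  maps <- lapply(list(maa_dose = c("MAA", "dose"), y90_dose = c("Y90", "dose")),
                 function(ck) {
                   as_dose_map(sirt_volume(arr, rep(spacing, 3),
                                           units = "Gy"),
                               channel = ck[1], kind = ck[2])
                 })
  maps$maa_bed <- bed_map(maps$maa_dose, st)
  maps$y90_bed <- bed_map(maps$y90_dose, st)
  list(maps = maps, structures = st)
}

# synthetic modeling table: n cases, p noise features, optional informative
# feature with standardized effect size delta
make_model_table <- function(n = 17, p = 10, n_r = 5, delta = 0,
                             seed = 1L) {
  set.seed(seed)
  label <- sample(c(rep("R", n_r), rep("NR", n - n_r)))
  tb <- tibble::tibble(case_id = sprintf("c%03d", seq_len(n)),
                       label = label)
  for (j in seq_len(p)) tb[[sprintf("f%02d", j)]] <- rnorm(n)
  if (delta != 0) tb$f01 <- tb$f01 + delta * (label == "R")
  tb
}
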