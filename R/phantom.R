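#' Configuration for a synthetic SPECT/CT phantom case
#'
#' Defines the study conditions for one synthetic SIRT case: an ellipsoidal
#' liver containing a perfused lobe and a spherical tumor, a heterogeneous
#' activity field with a controllable true tumor-to-normal uptake ratio
#' (TNR), Poisson SPECT counting noise, and a label-dependent effect that
#' gives responders a recoverable signal (higher tumor uptake and finer
#' uptake texture).
#'
#' @param grid_shape Integer length-3 voxel grid.
#' @param spacing_mm Voxel spacing in mm (isotropic scalar or length 3).
#' @param liver_radius_mm Semi-axis a of the liver ellipsoid (b = 0.8 a,
#'   c = 0.6 a).
#' @param tumor_radius_mm Tumor sphere radius (must be < liver radius).
#' @param tnr_true True tumor-to-normal uptake ratio (> 0).
#' @param noise_model `"none"` or `"poisson"`.
#' @param injected_activity_GBq Planned/administered Y90 activity.
#' @param lsf Lung shunt fraction in [0, 1) (stored scalar, never computed
#'   from planar images).
#' @param base_counts Mean NPL count rate (counts/s) before noise.
#' @param texture_sigma Log-scale SD of the multiplicative uptake texture.
#' @param texture_granularity Correlation length of the texture, voxels.
#' @param mismatch SD of an extra log-scale perturbation applied to the MAA
#'   channel only (0 = MAA and Y90 share the activity field exactly).
#' @param class_effect Named list of responder shifts:
#'   `uptake_scale` multiplies tumor uptake, `sigma_scale` multiplies the
#'   tumor texture SD, `granularity_shift` is added to the tumor texture
#'   granularity. All at their neutral values give indistinguishable classes.
#' @param seed Integer RNG seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64L, 56L, 40L),
                           spacing_mm = 4,
                           liver_radius_mm = 105,
                           tumor_radius_mm = 20,
                           tnr_true = 3,
                           noise_model = c("poisson", "none"),
                           injected_activity_GBq = 2.8,
                           lsf = 0.05,
                           base_counts = 100,
                           texture_sigma = 0.3,
                           texture_granularity = 4,
                           mismatch = 0,
                           class_effect = list(uptake_scale = 1.5,
                                               sigma_scale = 1,
                                               granularity_shift = -2),
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  if (tnr_true <= 0) stop("tnr_true must be > 0", call. = FALSE)
  if (lsf < 0 || lsf >= 1) stop("lsf must be in [0, 1)", call. = FALSE)
  if (tumor_radius_mm >= liver_radius_mm) {
    stop("invalid geometry: tumor radius must be smaller than liver radius",
         call. = FALSE)
  }
  ce <- utils::modifyList(
    list(uptake_scale = 1, sigma_scale = 1, granularity_shift = 0),
    class_effect %||% list())
  structure(
    list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
         liver_radius_mm = liver_radius_mm, tumor_radius_mm = tumor_radius_mm,
         tnr_true = tnr_true, noise_model = noise_model,
         injected_activity_GBq = injected_activity_GBq, lsf = lsf,
         base_counts = base_counts, texture_sigma = texture_sigma,
         texture_granularity = texture_granularity, mismatch = mismatch,
         class_effect = ce, seed = as.integer(seed)),
    class = "phantom_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ellipsoid_mask <- function(dim, spacing, center_mm, semi_mm) {
  cx <- (seq_len(dim[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dim[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dim[3]) - 0.5) * spacing[3]
  g <- expand.grid(x = cx, y = cy, z = cz)
  v <- ((g$x - center_mm[1]) / semi_mm[1])^2 +
       ((g$y - center_mm[2]) / semi_mm[2])^2 +
       ((g$z - center_mm[3]) / semi_mm[3])^2
  array(v <= 1, dim = dim)
}

#' Generate one synthetic SPECT/CT case
#'
#' Builds the geometry (liver ellipsoid, perfused right lobe, tumor sphere),
#' a heterogeneous activity field whose tumor and NPL sample means are
#' normalized *exactly* to the configured ratio before noise, CT in a
#' liver-like HU band, and the MAA / Y90 SPECT channels from the same
#' underlying activity field with independent Poisson draws.
#'
#' The stored ground truth includes the analytic mean tumor dose implied by
#' local energy deposition with whole-liver self-calibration at the
#' configured activity.
#'
#' @param config A [phantom_config()].
#' @param label `"NR"` (default) or `"R"`; responders receive the
#'   configured `class_effect`.
#' @param case_id Optional case identifier string.
#' @return A `phantom_case`: `ct`, `spect_maa`, `spect_y90`
#'   ([sirt_volume()]s), `structures` ([structure_set()]), `truth` list,
#'   `label`, `case_id`.
#' @export
generate_case <- function(config, label = c("NR", "R"), case_id = "case") {
  label <- match.arg(label)
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  d <- config$grid_shape
  sp <- config$spacing_mm
  center <- d * sp / 2
  a <- config$liver_radius_mm
  semi <- c(a, 0.8 * a, 0.6 * a)
  liver <- ellipsoid_mask(d, sp, center, semi)
  body <- ellipsoid_mask(d, sp, center, pmin(semi * 1.45, d * sp / 2 - sp))
  body <- body | liver
  # perfused territory: the bulk of the liver on the +x side (a lobar /
  # near-whole-liver treatment volume); the remaining sliver is unperfused
  xs <- array(rep((seq_len(d[1]) - 0.5) * sp[1], times = prod(d[2:3])),
              dim = d)
  lobe <- liver & (xs > center[1] - 0.35 * a)
  tcen <- center + c(0.35 * a, 0, 0)
  tumor <- ellipsoid_mask(d, sp, tcen, rep(config$tumor_radius_mm, 3))
  if (any(tumor & !lobe)) {
    stop("invalid geometry: tumor not strictly inside the perfused lobe",
         call. = FALSE)
  }
  if (sum(tumor) < 8) {
    stop("invalid geometry: tumor too small for the grid resolution",
         call. = FALSE)
  }
  structures <- structure_set(tumor, lobe, liver, spacing = sp)

  eff <- if (label == "R") config$class_effect else
    list(uptake_scale = 1, sigma_scale = 1, granularity_shift = 0)

  # multiplicative uptake texture; tumor gets its own (label-dependent) field
  tex_n <- exp(config$texture_sigma *
                 smooth_noise_field(d, config$texture_granularity))
  gran_t <- max(1, config$texture_granularity + eff$granularity_shift)
  tex_t <- exp(config$texture_sigma * eff$sigma_scale *
                 smooth_noise_field(d, gran_t))
  activity <- array(0, dim = d)
  npl <- structures$npl
  activity[npl] <- tex_n[npl] / mean(tex_n[npl]) * config$base_counts
  activity[tumor] <- tex_t[tumor] / mean(tex_t[tumor]) *
    config$base_counts * config$tnr_true * eff$uptake_scale

  # MAA channel: same field, optional log-scale mismatch (mean-preserving)
  act_maa <- activity
  if (config$mismatch > 0) {
    pert <- exp(config$mismatch * smooth_noise_field(d, gran_t))
    act_maa[npl] <- activity[npl] * pert[npl] / mean(pert[npl])
    act_maa[tumor] <- activity[tumor] * pert[tumor] / mean(pert[tumor])
  }

  noisify <- function(lam) {
    if (config$noise_model == "none") return(lam)
    array(rpois(length(lam), lam), dim = dim(lam)) * 1.0
  }
  spect_maa <- sirt_volume(noisify(act_maa), sp, units = "counts_s")
  spect_y90 <- sirt_volume(noisify(activity), sp, units = "counts_s")

  # CT: air background, soft-tissue body, textured liver, hypodense tumor
  ct <- array(-1000, dim = d)
  ct[body] <- 30
  ct_tex <- smooth_noise_field(d, config$texture_granularity)
  ct[liver] <- 50 + 8 * ct_tex[liver]
  ct_tex_t <- smooth_noise_field(d, gran_t)
  ct[tumor] <- 42 + 8 * eff$sigma_scale * ct_tex_t[tumor]
  ct <- sirt_volume(ct, sp, units = "HU")

  # analytic mean tumor dose under LDM with whole-liver self-calibration
  e_const <- 49.67 # J/GBq, Y90 beta energy per administered activity
  mass_kg <- prod(sp) / 1e6 # 1 g/cm^3 uniform density
  total_counts <- sum(activity[liver])
  mean_tumor_counts <- mean(activity[tumor])
  truth <- list(
    tnr_true = config$tnr_true * eff$uptake_scale,
    injected_activity_GBq = config$injected_activity_GBq,
    lsf = config$lsf,
    mean_tumor_dose_true_Gy = mean_tumor_counts / total_counts *
      config$injected_activity_GBq * e_const / mass_kg)

  structure(list(ct = ct, spect_maa = spect_maa, spect_y90 = spect_y90,
                 structures = structures, truth = truth, label = label,
                 case_id = case_id, config = config),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s [%s]  tumor %d vox, TNR_true %.2f, %.1f GBq\n",
              x$case_id, x$label, sum(x$structures$tumor), x$truth$tnr_true,
              x$truth$injected_activity_GBq))
  invisible(x)
}

#' Generate a synthetic cohort with responder / non-responder labels
#'
#' Emulates a small SIRT cohort with class imbalance: `round(n_cases *
#' responder_fraction)` cases are responders and carry the configured
#' class effect; the rest are non-responders. Each case gets its own
#' derived seed, so the cohort is reproducible from `seed` alone.
#'
#' @param n_cases Number of cases (>= 4).
#' @param responder_fraction Fraction of responders in (0, 1).
#' @param base_config A [phantom_config()] shared by all cases.
#' @param seed Cohort master seed.
#' @return List of `phantom_case` objects with a `clinical` attribute
#'   holding the simulated clinical covariate tibble (see
#'   [simulate_clinical()]).
#' @export
generate_cohort <- function(n_cases, responder_fraction,
                            base_config = phantom_config(), seed = 1L) {
  if (n_cases < 4) stop("n_cases must be >= 4", call. = FALSE)
  if (responder_fraction <= 0 || responder_fraction >= 1) {
    stop("responder_fraction must be in (0, 1)", call. = FALSE)
  }
  n_r <- round(n_cases * responder_fraction)
  if (n_r < 1 || n_r > n_cases - 1) {
    stop("cohort too small to realize both classes", call. = FALSE)
  }
  set.seed(seed)
  labels <- sample(c(rep("R", n_r), rep("NR", n_cases - n_r)))
  # per-case anatomical variability (label-independent): tumor and liver
  # sizes vary across patients, so shape features carry real variance
  tum_scale <- runif(n_cases, 0.75, 1.35)
  liv_scale <- runif(n_cases, 0.9, 1.1)
  cases <- lapply(seq_len(n_cases), function(i) {
    cfg <- base_config
    cfg$tumor_radius_mm <- base_config$tumor_radius_mm * tum_scale[i]
    cfg$liver_radius_mm <- base_config$liver_radius_mm * liv_scale[i]
    cfg$seed <- as.integer((seed * 1000 + i) %% .Machine$integer.max)
    generate_case(cfg, label = labels[i],
                  case_id = sprintf("case_%03d", i))
  })
  attr(cases, "clinical") <- simulate_clinical(labels, seed = seed + 77)
  class(cases) <- c("phantom_cohort", "list")
  cases
}

#' Simulate clinical covariates for a cohort
#'
#' Sixteen columns mixing continuous and categorical covariates typical of
#' an HCC-SIRT cohort. `sex` and `extrahepatic_metastasis` are generated but
#' flagged for exclusion from modeling (extreme class imbalance in the
#' emulated cohort); the 14 remaining columns are the modeling set.
#'
#' @param labels Character vector of `"R"` / `"NR"`.
#' @param seed RNG seed.
#' @param effect Standardized mean shift added to three continuous
#'   covariates for responders (0 = no label association).
#' @return Tibble with `case_id`, `label`, 16 covariates, and an
#'   `excluded` attribute naming the two dropped columns.
#' @export
simulate_clinical <- function(labels, seed = 1L, effect = 0) {
  set.seed(seed)
  n <- length(labels)
  r <- as.numeric(labels == "R")
  tb <- tibble::tibble(
    case_id = sprintf("case_%03d", seq_len(n)),
    label = labels,
    age = round(rnorm(n, 66, 9)),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.8, 0.2)),
    bmi = rnorm(n, 26, 4),
    ecog = sample(0:1, n, replace = TRUE),
    cirrhosis = rbinom(n, 1, 0.7),
    hbv = rbinom(n, 1, 0.2),
    hcv = rbinom(n, 1, 0.25),
    alcohol = rbinom(n, 1, 0.4),
    afp_log = rnorm(n, 3, 1.2) + effect * r,
    albumin = rnorm(n, 38, 4),
    bilirubin_log = rnorm(n, 2.3, 0.5) - 0.5 * effect * r,
    alt = rnorm(n, 45, 15),
    portal_vein_thrombosis = rbinom(n, 1, 0.3),
    extrahepatic_metastasis = rbinom(n, 1, 0.06),
    baseline_tumor_volume_ml = exp(rnorm(n, 4.5, 0.6) - 0.3 * effect * r),
    prior_treatment = rbinom(n, 1, 0.35))
  attr(tb, "excluded") <- c("sex", "extrahepatic_metastasis")
  tb
}

#' Write a phantom case to disk
#'
#' Volumes and masks go to NIfTI (`.nii.gz`), ground truth and label to a
#' JSON sidecar.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if missing).
#' @return The case directory, invisibly.
#' @export
write_case <- function(case, dir) {
  cdir <- file.path(dir, case$case_id)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$ct, file.path(cdir, "ct.nii.gz"))
  write_volume(case$spect_maa, file.path(cdir, "spect_maa.nii.gz"))
  write_volume(case$spect_y90, file.path(cdir, "spect_y90.nii.gz"))
  sp <- case$structures$spacing
  for (s in c("tumor", "lobe", "liver")) {
    m <- sirt_volume(array(as.numeric(case$structures[[s]]),
                           dim = dim(case$structures[[s]])),
                     spacing = sp, units = "Gy")
    write_volume(m, file.path(cdir, paste0("mask_", s, ".nii.gz")))
  }
  jsonlite::write_json(
    list(case_id = case$case_id, label = case$label, truth = case$truth),
    file.path(cdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(cdir)
}

#' Write a cohort to disk with a CSV manifest
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort, write_case, character(1), dir = dir)
  manifest <- tibble::tibble(
    case_id = vapply(cohort, function(c) c$case_id, character(1)),
    label = vapply(cohort, function(c) c$label, character(1)),
    path = paths)
  utils::write.csv(manifest, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  cl <- attr(cohort, "clinical")
  if (!is.null(cl)) {
    utils::write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  }
  invisible(file.path(dir, "cohort.csv"))
}
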