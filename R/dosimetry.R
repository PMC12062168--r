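#' Local-deposition-method configuration
#'
#' Parameters of the counts-to-dose conversion. The energy constant is the
#' total beta energy emitted by Y90 per unit administered activity
#' (mean beta energy times the number of decays per GBq), 49.67 J/GBq.
#' The MAA channel uses the same constant with the planned Y90 activity,
#' since the pre-therapy MAA study simulates the treatment.
#'
#' @param energy_per_activity_J_per_GBq Total emitted beta energy per GBq.
#' @param voxel_mass_model `"uniform_density"` (default) or `"ct_density"`.
#' @param density_g_per_cm3 Density used in the uniform model.
#' @param calibration_region `"whole_liver"` (default) or `"body"` — which
#'   mask the self-calibration normalizes over.
#' @param deduct_lsf If `TRUE`, the administered activity is reduced by
#'   `(1 - LSF)` before calibration (off by default).
#' @return An `ldm_config` list.
#' @export
ldm_config <- function(energy_per_activity_J_per_GBq = 49.67,
                       voxel_mass_model = c("uniform_density", "ct_density"),
                       density_g_per_cm3 = 1.0,
                       calibration_region = c("whole_liver", "body"),
                       deduct_lsf = FALSE) {
  voxel_mass_model <- match.arg(voxel_mass_model)
  calibration_region <- match.arg(calibration_region)
  if (energy_per_activity_J_per_GBq <= 0 || density_g_per_cm3 <= 0) {
    stop("energy constant and density must be positive", call. = FALSE)
  }
  structure(list(energy_per_activity_J_per_GBq = energy_per_activity_J_per_GBq,
                 voxel_mass_model = voxel_mass_model,
                 density_g_per_cm3 = density_g_per_cm3,
                 calibration_region = calibration_region,
                 deduct_lsf = deduct_lsf),
            class = "ldm_config")
}

#' Voxel dose map by the local deposition method
#'
#' Each voxel's emitted beta energy is assumed absorbed locally; the SPECT
#' count map is self-calibrated so that the counts inside the calibration
#' region account for the full administered activity:
#' \deqn{D_v = \frac{c_v}{\sum_{u \in cal} c_u} \cdot
#'       \frac{A \cdot E}{m_v}}
#' with counts \eqn{c}, activity \eqn{A} (GBq), energy constant \eqn{E}
#' (J/GBq) and voxel mass \eqn{m_v} (kg). Self-calibration makes the map
#' invariant to any global rescaling of the counts, and energy is conserved:
#' when all counts lie inside the calibration mask,
#' \eqn{\sum_v D_v m_v = A E}.
#'
#' @param spect [sirt_volume()] of counts/s (non-negative).
#' @param calibration_mask Binary mask on the same grid (nonempty, positive
#'   total counts).
#' @param injected_activity_GBq Administered activity in GBq.
#' @param cfg An [ldm_config()].
#' @param channel Dose-map channel tag, `"MAA"` or `"Y90"`.
#' @param lsf Lung shunt fraction, used only when `cfg$deduct_lsf`.
#' @param ct Optional CT [sirt_volume()] for the `"ct_density"` mass model.
#' @return A [as_dose_map()]-tagged `sirt_volume` in Gy (`kind = "dose"`).
#' @export
ldm_dose_map <- function(spect, calibration_mask, injected_activity_GBq,
                         cfg = ldm_config(), channel = c("Y90", "MAA"),
                         lsf = 0, ct = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(spect, "sirt_volume"))
  mask <- as_mask_array(calibration_mask)
  check_same_grid(spect$data, mask, "SPECT and calibration mask")
  if (!any(mask)) stop("calibration mask is empty", call. = FALSE)
  if (any(spect$data < 0)) stop("SPECT counts must be >= 0", call. = FALSE)
  total <- sum(spect$data[mask])
  if (total <= 0) {
    stop("calibration error: zero total counts in calibration region",
         call. = FALSE)
  }
  activity <- injected_activity_GBq
  if (isTRUE(cfg$deduct_lsf)) activity <- activity * (1 - lsf)
  vox_cm3 <- prod(spect$spacing) / 1000
  mass_kg <- if (cfg$voxel_mass_model == "uniform_density") {
    array(vox_cm3 * cfg$density_g_per_cm3 / 1000, dim = dim(spect$data))
  } else {
    if (is.null(ct)) stop("ct_density mass model needs a CT", call. = FALSE)
    check_same_grid(spect$data, ct$data, "SPECT and CT")
    # simple HU-to-density map: rho = 1 + HU/1000 g/cm^3, floored at air
    rho <- pmax(0.001, 1 + ct$data / 1000)
    array(vox_cm3 * rho / 1000, dim = dim(spect$data))
  }
  dose <- spect$data / total * activity *
    cfg$energy_per_activity_J_per_GBq / mass_kg
  out <- sirt_volume(dose, spacing = spect$spacing, origin = spect$origin,
                     units = "Gy")
  as_dose_map(out, channel = channel, kind = "dose")
}

#' Linear-quadratic repair parameters for BED
#'
#' Structure-specific parameters of the biologically effective dose
#' transform: the alpha/beta ratio (Gy), the sublethal-damage repair
#' half-time (h) and the physical decay half-life of Y90 (64.2 h). Defaults
#' follow the glass-microsphere SIRT convention: alpha/beta = 10 for both
#' tissue classes, repair half-time 1.5 h for tumor, 2.5 h for normal liver.
#'
#' @param alpha_beta_Gy Alpha/beta ratio in Gy.
#' @param t_rep_h Repair half-time in hours.
#' @param t_phys_h Physical half-life in hours.
#' @return A `bed_params` list.
#' @export
bed_params <- function(alpha_beta_Gy = 10, t_rep_h = 1.5, t_phys_h = 64.2) {
  if (alpha_beta_Gy <= 0 || t_rep_h <= 0 || t_phys_h <= 0) {
    stop("BED parameters must be strictly positive", call. = FALSE)
  }
  structure(list(alpha_beta_Gy = alpha_beta_Gy, t_rep_h = t_rep_h,
                 t_phys_h = t_phys_h), class = "bed_params")
}

#' Tumor / normal-liver BED parameter presets
#' @rdname bed_params
#' @export
bed_params_tumor <- function() bed_params(10, 1.5, 64.2)

#' @rdname bed_params
#' @export
bed_params_normal <- function() bed_params(10, 2.5, 64.2)

#' Biologically effective dose of a physical dose
#'
#' \deqn{BED = D \left(1 + \frac{D}{\alpha/\beta} \cdot
#'       \frac{T_{Rep}}{T_{Rep} + T_{phys}}\right)}
#' for a permanently implanted decaying source. BED >= D always, strictly
#' increasing and convex in D, and BED/D tends to 1 as D tends to 0.
#'
#' @param dose_Gy Non-negative dose (vectorized).
#' @param params A [bed_params()].
#' @return BED in Gy, same shape as `dose_Gy`.
#' @export
bed_voxel <- function(dose_Gy, params = bed_params_tumor()) {
  if (any(dose_Gy < 0)) stop("dose must be >= 0", call. = FALSE)
  dose_Gy * (1 + (dose_Gy / params$alpha_beta_Gy) *
               params$t_rep_h / (params$t_rep_h + params$t_phys_h))
}

#' Voxel-wise BED map with structure-specific parameters
#'
#' Tumor voxels are transformed with the tumor parameters, normal-liver
#' voxels (NPL and WNL, i.e. everything in the liver outside the tumor)
#' with the normal parameters; voxels outside all structures are set to 0.
#'
#' @param dose A physical [as_dose_map()] (`kind == "dose"`).
#' @param structures A [structure_set()] on the same grid.
#' @param tumor_params,normal_params [bed_params()] per tissue class.
#' @return A BED dose map (`kind == "bed"`), same channel as the input.
#' @export
bed_map <- function(dose, structures,
                    tumor_params = bed_params_tumor(),
                    normal_params = bed_params_normal()) {
  stopifnot(inherits(dose, "sirt_dose"))
  if (dose$kind != "dose") {
    stop("bed_map expects a physical dose map", call. = FALSE)
  }
  check_same_grid(dose$data, structures$tumor, "dose and structures")
  if (any(structures$tumor & structures$wnl)) {
    stop("tumor and normal masks overlap", call. = FALSE)
  }
  out <- array(0, dim = dim(dose$data))
  tm <- structures$tumor
  nm <- structures$wnl # whole normal liver covers NPL
  out[tm] <- bed_voxel(dose$data[tm], tumor_params)
  out[nm] <- bed_voxel(dose$data[nm], normal_params)
  vol <- sirt_volume(out, spacing = dose$spacing, origin = dose$origin,
                     units = "Gy")
  as_dose_map(vol, channel = dose$channel, kind = "bed")
}

#' All four dose maps of a case
#'
#' Convenience wrapper: physical and BED maps for both channels of one
#' phantom case, with whole-liver self-calibration.
#'
#' @param case A `phantom_case`.
#' @param cfg An [ldm_config()].
#' @return Named list `maa_dose`, `y90_dose`, `maa_bed`, `y90_bed`.
#' @export
case_dose_maps <- function(case, cfg = ldm_config()) {
  st <- case$structures
  act <- case$truth$injected_activity_GBq
  maa <- ldm_dose_map(case$spect_maa, st$liver, act, cfg, channel = "MAA",
                      lsf = case$truth$lsf, ct = case$ct)
  y90 <- ldm_dose_map(case$spect_y90, st$liver, act, cfg, channel = "Y90",
                      lsf = case$truth$lsf, ct = case$ct)
  list(maa_dose = maa, y90_dose = y90,
       maa_bed = bed_map(maa, st), y90_bed = bed_map(y90, st))
}
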