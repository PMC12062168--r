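#' Channel-specific preprocessing configuration
#'
#' Image conditioning applied before feature extraction. CT is resampled to
#' 1.5 mm isotropic and clipped to [-500, 500] HU. SPECT is clipped between
#' 0 and its own per-image 99.9th percentile (bremsstrahlung SPECT carries
#' sparse very-hot outlier voxels). Dose/BED maps are clipped at fixed
#' structure- and channel-specific caps (Gy) so the discretization range is
#' identical across cases, and discretized with fixed bin widths:
#' 50 counts/s for SPECT, 20 HU for CT, 1 Gy for dose maps.
#'
#' @param ct_resample_mm CT target spacing (mm).
#' @param ct_clip_HU CT clipping window.
#' @param spect_clip_quantile Upper clipping quantile for SPECT.
#' @param dose_clip_caps_Gy Nested list `MAA`/`Y90`, each with named caps
#'   for `tumor`, `npl`, `wnl`.
#' @param bin_width Named list of discretization bin widths per channel
#'   class (`SPECT`, `CT`, `dose`).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(
    ct_resample_mm = c(1.5, 1.5, 1.5),
    ct_clip_HU = c(-500, 500),
    spect_clip_quantile = 0.999,
    dose_clip_caps_Gy = list(
      MAA = list(tumor = 650.34, npl = 158.02, wnl = 127.08),
      Y90 = list(tumor = 416.25, npl = 133.16, wnl = 123.08)),
    bin_width = list(SPECT = 50, CT = 20, dose = 1)) {
  stopifnot(ct_clip_HU[1] <= ct_clip_HU[2],
            all(unlist(dose_clip_caps_Gy) > 0),
            all(unlist(bin_width) > 0))
  structure(list(ct_resample_mm = ct_resample_mm, ct_clip_HU = ct_clip_HU,
                 spect_clip_quantile = spect_clip_quantile,
                 dose_clip_caps_Gy = dose_clip_caps_Gy,
                 bin_width = bin_width),
            class = "preprocess_config")
}

#' Preprocess a volume for feature extraction
#'
#' Applies the channel rule from [preprocess_config()]: CT resample + clip,
#' SPECT per-image percentile clip, dose/BED fixed structure cap. BED maps
#' use the caps of their nuclide channel.
#'
#' @param volume A [sirt_volume()].
#' @param channel One of `"CT"`, `"SPECT"`, `"MAA_dose"`, `"Y90_dose"`.
#' @param structure `"tumor"`, `"npl"` or `"wnl"` (used for dose caps).
#' @param cfg A [preprocess_config()].
#' @return The preprocessed [sirt_volume()].
#' @export
preprocess_volume <- function(volume, channel, structure = "tumor",
                              cfg = preprocess_config()) {
  stopifnot(inherits(volume, "sirt_volume"))
  if (channel == "CT") {
    out <- resample_volume(volume, cfg$ct_resample_mm, method = "linear")
    out$data[] <- pmin(pmax(out$data, cfg$ct_clip_HU[1]), cfg$ct_clip_HU[2])
    out
  } else if (channel == "SPECT") {
    cap <- as.numeric(quantile(volume$data, cfg$spect_clip_quantile))
    volume$data[] <- pmin(pmax(volume$data, 0), cap)
    volume
  } else if (channel %in% c("MAA_dose", "Y90_dose")) {
    nuc <- sub("_dose$", "", channel)
    cap <- cfg$dose_clip_caps_Gy[[nuc]][[structure]]
    volume$data[] <- pmin(pmax(volume$data, 0), cap)
    volume
  } else {
    stop("unknown channel: ", channel, call. = FALSE)
  }
}

#' Fixed-bin-width discretization
#'
#' Gray level of voxel value x is `floor(x / w) - floor(min(x) / w) + 1`,
#' so bin edges align to multiples of the bin width and levels run 1..Ng.
#'
#' @param x Numeric vector of ROI voxel values.
#' @param bin_width Bin width in the channel's units.
#' @return Integer gray levels (>= 1).
#' @keywords internal
discretize_fbw <- function(x, bin_width) {
  as.integer(floor(x / bin_width) - floor(min(x) / bin_width) + 1)
}
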