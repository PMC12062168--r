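#' Create a 3D scalar volume
#'
#' Lightweight container for a 3D scalar field on a regular grid: the voxel
#' array, the voxel spacing in mm, a physical origin, and a unit tag saying
#' what the values mean (`"counts_s"` for SPECT count rate, `"HU"` for CT,
#' `"Gy"` for dose/BED maps).
#'
#' @param data Numeric 3D array (column-major, as returned by [array()]).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param origin Numeric length-3 physical origin in mm.
#' @param units One of `"counts_s"`, `"HU"`, `"Gy"`, `"binary"`.
#' @return An object of class `sirt_volume`.
#' @export
sirt_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        units = c("counts_s", "HU", "Gy", "binary")) {
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel sizes (mm)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), units = units),
    class = "sirt_volume"
  )
}

#' @export
print.sirt_volume <- function(x, ...) {
  cat(sprintf("<sirt_volume> %s  %s voxels @ %s mm  range [%.4g, %.4g]\n",
              x$units, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.sirt_volume <- function(x) dim(x$data)

#' Voxel volume in ml
#'
#' @param vol A `sirt_volume` (or anything with a `spacing` element in mm).
#' @return Volume of one voxel in millilitres (1 ml = 1 cm^3).
#' @export
voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

#' Tag a volume as a dose map
#'
#' A dose map is a `sirt_volume` in Gy carrying its source nuclide channel
#' (`"MAA"` for the pre-therapy Tc-99m-MAA simulation, `"Y90"` for the
#' post-therapy bremsstrahlung acquisition) and dose kind (`"dose"` physical,
#' `"bed"` biologically effective).
#'
#' @param vol A `sirt_volume` with `units == "Gy"` and non-negative voxels.
#' @param channel `"MAA"` or `"Y90"`.
#' @param kind `"dose"` or `"bed"`.
#' @return The volume with class `sirt_dose` prepended and `channel`/`kind`
#'   elements set.
#' @export
as_dose_map <- function(vol, channel = c("MAA", "Y90"),
                        kind = c("dose", "bed")) {
  channel <- match.arg(channel)
  kind <- match.arg(kind)
  stopifnot(inherits(vol, "sirt_volume"))
  if (vol$units != "Gy") stop("dose maps must be in Gy", call. = FALSE)
  if (any(!is.finite(vol$data)) || any(vol$data < 0)) {
    stop("dose maps must be finite and non-negative", call. = FALSE)
  }
  vol$channel <- channel
  vol$kind <- kind
  class(vol) <- unique(c("sirt_dose", class(vol)))
  vol
}

check_same_grid <- function(a, b, what = "volumes") {
  da <- if (is.array(a)) dim(a) else dim(a$data)
  db <- if (is.array(b)) dim(b) else dim(b$data)
  if (!identical(as.integer(da), as.integer(db))) {
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "sirt_volume")) mask <- mask$data
  if (is.logical(mask)) return(mask)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1))) {
    stop("mask has non-binary values", call. = FALSE)
  }
  array(mask == 1, dim = dim(mask))
}

#' Assemble aligned structure masks
#'
#' Builds the structure set used throughout the pipeline from the three
#' delineated regions: tumor, perfused lobe, whole liver. The two normal
#' structures are derived by subtraction: NPL (normal perfused liver) =
#' perfused lobe minus tumor, WNL (whole normal liver) = whole liver minus
#' tumor.
#'
#' @param tumor,lobe,liver Binary masks (logical/0-1 arrays or
#'   `sirt_volume`s) on one grid. Tumor must lie inside the perfused lobe,
#'   the lobe inside the liver.
#' @param spacing Voxel spacing in mm.
#' @return A `sirt_structures` object: logical arrays `tumor`, `lobe`,
#'   `liver`, `npl`, `wnl` plus `spacing`.
#' @export
structure_set <- function(tumor, lobe, liver, spacing = c(1, 1, 1)) {
  tumor <- as_mask_array(tumor)
  lobe <- as_mask_array(lobe)
  liver <- as_mask_array(liver)
  check_same_grid(tumor, lobe, "tumor/lobe masks")
  check_same_grid(tumor, liver, "tumor/liver masks")
  if (any(tumor & !lobe)) stop("tumor must lie inside the perfused lobe",
                               call. = FALSE)
  if (any(lobe & !liver)) stop("perfused lobe must lie inside the liver",
                               call. = FALSE)
  structure(
    list(tumor = tumor, lobe = lobe, liver = liver,
         npl = lobe & !tumor, wnl = liver & !tumor,
         spacing = as.numeric(spacing)),
    class = "sirt_structures"
  )
}

#' @export
print.sirt_structures <- function(x, ...) {
  cat(sprintf(
    "<sirt_structures> tumor %d | NPL %d | WNL %d voxels (liver %d)\n",
    sum(x$tumor), sum(x$npl), sum(x$wnl), sum(x$liver)))
  invisible(x)
}

#' Read a volume from NIfTI
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param units Unit tag to attach (not stored in NIfTI).
#' @return A [sirt_volume()].
#' @export
read_volume <- function(path, units = "Gy") {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  sirt_volume(arr, spacing = sp[1:3], origin = c(0, 0, 0), units = units)
}

#' Write a volume to NIfTI
#'
#' Data are stored as float64 so a write/read round trip preserves voxel
#' values bit-exactly.
#'
#' @param vol A [sirt_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "sirt_volume"))
  arr <- vol$data
  attr(arr, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file holding a 0/1 volume.
#' @return Logical 3D array. Errors if the file contains values other than
#'   0 and 1.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path, units = "Gy")
  as_mask_array(vol$data)
}
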