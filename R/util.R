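# shared numeric helpers

#' @useDynLib sirtomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif sd var median quantile cor
#'   wilcox.test kruskal.test fisher.test p.adjust glm predict binomial
#'   pnorm pchisq ecdf rbinom aggregate
#' @importFrom rlang .data
NULL

#' Trilinear interpolation of a 3D array
#'
#' Samples `arr` at fractional voxel coordinates (1-based, like R array
#' indexing). Points outside the grid are clamped to the boundary.
#'
#' @param arr 3D numeric array.
#' @param x,y,z Numeric vectors of equal length, fractional indices.
#' @return Numeric vector of interpolated values.
#' @keywords internal
trilinear_interp <- function(arr, x, y, z) {
  d <- dim(arr)
  x <- pmin(pmax(x, 1), d[1])
  y <- pmin(pmax(y, 1), d[2])
  z <- pmin(pmax(z, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(y), d[2] - 1L); y1 <- y0 + 1
  z0 <- pmin(floor(z), d[3] - 1L); z1 <- z0 + 1
  if (d[1] == 1L) { x0 <- x1 <- rep(1, length(x)) }
  if (d[2] == 1L) { y0 <- y1 <- rep(1, length(y)) }
  if (d[3] == 1L) { z0 <- z1 <- rep(1, length(z)) }
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i, j, k)]
  c00 <- at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx
  c10 <- at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx
  c01 <- at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx
  c11 <- at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Resample a volume to a new voxel spacing
#'
#' Trilinear (`"linear"`) or nearest-neighbour (`"nearest"`, for masks)
#' resampling onto a grid with the requested spacing covering the same
#' physical extent.
#'
#' @param vol A [sirt_volume()] or a 3D array (then `spacing` is required).
#' @param new_spacing Target voxel spacing in mm (length 1 or 3).
#' @param spacing Current spacing when `vol` is a bare array.
#' @param method `"linear"` or `"nearest"`.
#' @return A resampled [sirt_volume()] (or array if input was an array).
#' @export
resample_volume <- function(vol, new_spacing, spacing = NULL,
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  is_vol <- inherits(vol, "sirt_volume")
  arr <- if (is_vol) vol$data else vol
  sp <- if (is_vol) vol$spacing else spacing
  if (is.null(sp)) stop("spacing required for array input", call. = FALSE)
  new_spacing <- rep(as.numeric(new_spacing), length.out = 3)
  d <- dim(arr)
  extent <- d * sp
  dn <- pmax(1L, as.integer(round(extent / new_spacing)))
  # voxel-center coordinates of the new grid in old fractional indices
  ax <- ((seq_len(dn[1]) - 0.5) * new_spacing[1]) / sp[1] + 0.5
  ay <- ((seq_len(dn[2]) - 0.5) * new_spacing[2]) / sp[2] + 0.5
  az <- ((seq_len(dn[3]) - 0.5) * new_spacing[3]) / sp[3] + 0.5
  g <- expand.grid(x = ax, y = ay, z = az)
  vals <- if (method == "linear") {
    trilinear_interp(arr, g$x, g$y, g$z)
  } else {
    d2 <- dim(arr)
    xi <- pmin(pmax(round(g$x), 1), d2[1])
    yi <- pmin(pmax(round(g$y), 1), d2[2])
    zi <- pmin(pmax(round(g$z), 1), d2[3])
    arr[cbind(xi, yi, zi)]
  }
  out <- array(vals, dim = dn)
  if (is_vol) {
    sirt_volume(out, spacing = new_spacing, origin = vol$origin,
                units = vol$units)
  } else {
    out
  }
}

#' Smooth correlated noise field
#'
#' White Gaussian noise drawn on a coarse lattice and trilinearly upsampled
#' to the full grid, giving spatially correlated texture whose granularity
#' (correlation length, in voxels) is the coarse-lattice pitch. Uses the
#' current RNG state.
#'
#' @param dim Integer length-3 output dimensions.
#' @param granularity Coarse-lattice pitch in voxels (>= 1).
#' @return 3D array of mean-zero, roughly unit-variance correlated noise.
#' @keywords internal
smooth_noise_field <- function(dim, granularity = 4) {
  granularity <- max(1, granularity)
  dc <- pmax(2L, as.integer(ceiling(dim / granularity)) + 1L)
  coarse <- array(rnorm(prod(dc)), dim = dc)
  if (granularity == 1) {
    return(coarse[seq_len(dim[1]), seq_len(dim[2]), seq_len(dim[3]),
                  drop = FALSE])
  }
  ax <- seq(1, dc[1], length.out = dim[1])
  ay <- seq(1, dc[2], length.out = dim[2])
  az <- seq(1, dc[3], length.out = dim[3])
  g <- expand.grid(x = ax, y = ay, z = az)
  array(trilinear_interp(coarse, g$x, g$y, g$z), dim = dim)
}

# entropy helper: 0 log 0 := 0, log base 2
xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)
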