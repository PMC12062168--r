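#' Cumulative dose-volume histogram of a structure
#'
#' Exact at voxel granularity: the curve stores the raw in-mask voxel doses,
#' and \eqn{V(d)} is the voxel volume times the number of mask voxels with
#' dose >= d. The binned `dose_edges_Gy` grid (default 0.1 Gy pitch) is for
#' export and plotting only; all scalar metrics are computed from the raw
#' voxels.
#'
#' @param dose A dose map ([sirt_volume()] in Gy).
#' @param mask Nonempty binary mask on the same grid.
#' @param bin_width_Gy Export binning pitch (> 0).
#' @param structure_id Label carried on the curve.
#' @return A `dvh_curve`: `dose_edges_Gy`, `volume_ml`, `volume_pct`
#'   (both non-increasing, `volume_pct[1] == 100`), `total_volume_ml`,
#'   `structure_id`, and the raw voxel `doses`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width_Gy = 0.1,
                           structure_id = "structure") {
  stopifnot(inherits(dose, "sirt_volume"))
  if (bin_width_Gy <= 0) stop("bin_width_Gy must be > 0", call. = FALSE)
  m <- as_mask_array(mask)
  check_same_grid(dose$data, m, "dose and mask")
  if (!any(m)) stop("empty mask", call. = FALSE)
  doses <- as.numeric(dose$data[m])
  vv <- voxel_volume_ml(dose)
  nb <- floor(max(doses) / bin_width_Gy + 1e-9) + 2L
  edges <- (seq_len(nb) - 1L) * bin_width_Gy
  # V(d) by reverse-cumulated histogram counts; the small tolerance keeps
  # doses landing exactly on a bin edge inside that edge's bin
  bin <- pmin(floor(doses / bin_width_Gy + 1e-9), nb - 1L) + 1L
  counts <- rev(cumsum(rev(tabulate(bin, nbins = nb))))
  structure(
    list(dose_edges_Gy = edges,
         volume_ml = counts * vv,
         volume_pct = 100 * counts / length(doses),
         total_volume_ml = length(doses) * vv,
         structure_id = structure_id,
         doses = doses, voxel_volume_ml = vv),
    class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %.1f ml, D range [%.3g, %.3g] Gy\n",
              x$structure_id, x$total_volume_ml, min(x$doses), max(x$doses)))
  invisible(x)
}

#' Dose covering a volume fraction (D_x)
#'
#' D_x is the minimum dose received by the hottest x% of the structure,
#' using the descending-sorted voxel convention without interpolation:
#' sort doses descending and take the `ceiling(x/100 * n)`-th value.
#'
#' @param curve A [cumulative_dvh()] result.
#' @param percent Volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(curve, percent) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (any(percent <= 0 | percent > 100)) {
    stop("percent must be in (0, 100]", call. = FALSE)
  }
  srt <- sort(curve$doses, decreasing = TRUE)
  n <- length(srt)
  srt[pmax(1L, ceiling(percent / 100 * n))]
}

#' Volume receiving at least a dose threshold (V_x)
#'
#' @param curve A [cumulative_dvh()] result.
#' @param threshold_Gy Dose threshold (>= 0).
#' @param unit `"ml"` or `"percent"`; the two are consistent:
#'   `pct = 100 * ml / total_volume_ml`.
#' @return Volume in the requested unit.
#' @export
volume_at_dose <- function(curve, threshold_Gy, unit = c("ml", "percent")) {
  unit <- match.arg(unit)
  stopifnot(inherits(curve, "dvh_curve"))
  if (any(threshold_Gy < 0)) stop("threshold must be >= 0", call. = FALSE)
  cnt <- vapply(threshold_Gy, function(t) sum(curve$doses >= t), numeric(1))
  if (unit == "ml") cnt * curve$voxel_volume_ml
  else 100 * cnt / length(curve$doses)
}

#' Tumor-to-normal mean dose ratio
#'
#' Mean dose over the tumor divided by mean dose over a normal structure
#' (NPL or WNL). Invariant to global dose rescaling.
#'
#' @param dose A dose map.
#' @param tumor_mask,normal_mask Nonempty binary masks.
#' @return The ratio (dimensionless).
#' @export
tnr <- function(dose, tumor_mask, normal_mask) {
  tm <- as_mask_array(tumor_mask)
  nm <- as_mask_array(normal_mask)
  check_same_grid(dose$data, tm, "dose and tumor mask")
  if (!any(tm) || !any(nm)) stop("masks must be nonempty", call. = FALSE)
  denom <- mean(dose$data[nm])
  if (denom <= 0) {
    stop("TNR undefined: zero mean dose in normal structure", call. = FALSE)
  }
  mean(dose$data[tm]) / denom
}

dvc_metrics_one <- function(curve, structure) {
  d <- curve$doses
  out <- list(
    volume_ml = curve$total_volume_ml,
    Dmean = mean(d), Dmax = max(d), Dmin = min(d),
    D5 = dose_at_volume(curve, 5), D50 = dose_at_volume(curve, 50),
    D70 = dose_at_volume(curve, 70), D95 = dose_at_volume(curve, 95),
    D98 = dose_at_volume(curve, 98))
  vx <- c(120, 205, 400)
  if (structure %in% c("npl", "wnl")) vx <- c(20, 30, 50, 70, 90, vx)
  for (t in vx) {
    out[[sprintf("V%d_ml", t)]] <- volume_at_dose(curve, t, "ml")
    out[[sprintf("V%d_pct", t)]] <- volume_at_dose(curve, t, "percent")
  }
  out
}

#' Full dose-volume-constraint record of one case
#'
#' For every structure (tumor, NPL, WNL) x channel (MAA, Y90) x dose kind
#' (physical dose, BED): structure volume, D_mean/D_max/D_min, D5/D50/D70/
#' D95/D98, and the volume constraints V120/V205/V400 (plus V20/V30/V50/
#' V70/V90 for the normal structures) in both ml and %. Adds the tumor
#' homogeneity index HI = D5/D95 per map, TNR vs NPL and WNL per map, and
#' the two scalar per-case parameters LSF and injected activity. Columns
#' follow the deterministic naming
#' `<structure>_<channel>_<kind>_<metric>`, so the record schema is fixed
#' across cases.
#'
#' @param maps Named list with elements `maa_dose`, `y90_dose`, `maa_bed`,
#'   `y90_bed` (see [case_dose_maps()]).
#' @param structures A [structure_set()].
#' @param lsf Lung shunt fraction scalar.
#' @param activity_GBq Injected Y90 activity.
#' @param case_id Case identifier.
#' @return One-row tibble.
#' @export
extract_dvcs <- function(maps, structures, lsf, activity_GBq,
                         case_id = "case") {
  need <- c("maa_dose", "y90_dose", "maa_bed", "y90_bed")
  missing <- setdiff(need, names(maps))
  if (length(missing) > 0) {
    stop("partial record: missing dose maps: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rec <- list(case_id = case_id)
  for (nm in need) {
    map <- maps[[nm]]
    channel <- map$channel
    kind <- map$kind
    for (s in c("tumor", "npl", "wnl")) {
      curve <- cumulative_dvh(map, structures[[s]], structure_id = s)
      met <- dvc_metrics_one(curve, s)
      names(met) <- sprintf("%s_%s_%s_%s", s, channel, kind, names(met))
      rec <- c(rec, met)
      if (s == "tumor") {
        rec[[sprintf("HI_%s_%s", channel, kind)]] <-
          dose_at_volume(curve, 5) / dose_at_volume(curve, 95)
      }
    }
    rec[[sprintf("TNR_NPL_%s_%s", channel, kind)]] <-
      tnr(map, structures$tumor, structures$npl)
    rec[[sprintf("TNR_WNL_%s_%s", channel, kind)]] <-
      tnr(map, structures$tumor, structures$wnl)
  }
  rec$LSF <- lsf
  rec$injected_activity_GBq <- activity_GBq
  tibble::as_tibble(rec)
}

#' DVC table for a whole cohort
#'
#' @param cohort A `phantom_cohort`.
#' @param cfg An [ldm_config()].
#' @return Tibble, one row per case, with `label` attached.
#' @export
cohort_dvc_table <- function(cohort, cfg = ldm_config()) {
  rows <- lapply(cohort, function(case) {
    maps <- case_dose_maps(case, cfg)
    rec <- extract_dvcs(maps, case$structures, case$truth$lsf,
                        case$truth$injected_activity_GBq,
                        case_id = case$case_id)
    rec$label <- case$label
    rec
  })
  dplyr::bind_rows(rows)
}

#' Plot a cumulative DVH curve
#'
#' @param object A `dvh_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dvh_curve <- function(object, ...) {
  df <- tibble::tibble(dose = object$dose_edges_Gy,
                       volume = object$volume_pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$volume)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)",
                  title = object$structure_id) +
    ggplot2::theme_minimal()
}
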