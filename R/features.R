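# 107-feature radiomic signature: 18 first-order + 14 shape (3D) +
# 24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM.
# Texture matrices are built in C++ (src/textures.cpp) over the 13 unique
# 3D directions and merged before feature computation; formulas follow the
# IBSI-conformant definitions of the standard fixed-bin-width extractors.

safe_div <- function(a, b, limit = 0) if (abs(b) < 1e-12) limit else a / b

fo_features <- function(x, g, voxvol_mm3) {
  n <- length(x)
  p <- tabulate(g) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  rob <- x[x >= q[1] & x <= q[5]]
  c(firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = voxvol_mm3 * sum(x^2),
    firstorder_Entropy = -sum(xlog2(p)),
    firstorder_Minimum = min(x),
    firstorder_10Percentile = q[1],
    firstorder_90Percentile = q[5],
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = safe_div(m3, m2^1.5),
    firstorder_Kurtosis = safe_div(m4, m2^2),
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}

shape_features <- function(mask, spacing) {
  dim3 <- dim(mask)
  mv <- cpp_mesh(as.logical(mask), as.integer(dim3), as.numeric(spacing))
  area <- mv[1]; vol <- mv[2]
  nvox <- sum(mask)
  voxvol <- nvox * prod(spacing)
  dia <- cpp_max_diameters(as.logical(mask), as.integer(dim3),
                           as.numeric(spacing))
  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx, 2, spacing, `*`)
  if (nrow(coords) > 1) {
    ev <- sort(pmax(eigen(stats::cov(coords), symmetric = TRUE,
                          only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else {
    ev <- c(0, 0, 0)
  }
  sph <- safe_div((36 * pi * vol^2)^(1 / 3), area)
  c(shape_MeshVolume = vol,
    shape_VoxelVolume = voxvol,
    shape_SurfaceArea = area,
    shape_SurfaceVolumeRatio = safe_div(area, vol),
    shape_Sphericity = sph,
    shape_Maximum3DDiameter = dia[1],
    shape_Maximum2DDiameterSlice = dia[2],
    shape_Maximum2DDiameterColumn = dia[3],
    shape_Maximum2DDiameterRow = dia[4],
    shape_MajorAxisLength = 4 * sqrt(ev[1]),
    shape_MinorAxisLength = 4 * sqrt(ev[2]),
    shape_LeastAxisLength = 4 * sqrt(ev[3]),
    shape_Elongation = sqrt(safe_div(ev[2], ev[1])),
    shape_Flatness = sqrt(safe_div(ev[3], ev[1])))
}

glcm_features <- function(P) {
  tot <- sum(P)
  if (tot < 1e-12) P <- diag(1, nrow(P)) * 0 else P <- P / tot
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  sig <- sqrt(sig2)
  k_diff <- 0:(ng - 1)
  pdiff <- as.numeric(rowsum(as.vector(P), as.vector(abs(i - j))))
  k_sum <- 2:(2 * ng)
  psum <- as.numeric(rowsum(as.vector(P), as.vector(i + j)))
  da <- sum(k_diff * pdiff)
  hx <- -sum(xlog2(px))
  hxy <- -sum(xlog2(P))
  pxpy <- outer(px, px)
  hxy1 <- -sum(ifelse(P > 0 & pxpy > 0, P * log2(pxpy), 0))
  hxy2 <- -sum(xlog2(pxpy))
  present <- which(px > 0)
  mcc <- 1
  if (length(present) >= 2) {
    # MCC = second-largest |eigenvalue| of the row-normalized GLCM; for a
    # symmetric GLCM that matrix is similar to the symmetric
    # D^(-1/2) P D^(-1/2), so a fast symmetric eigensolve suffices.
    Pp <- P[present, present, drop = FALSE]
    rs <- sqrt(px[present])
    S <- Pp / outer(rs, rs)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    mcc <- sort(abs(ev), decreasing = TRUE)[2]
  }
  corr <- if (sig2 < 1e-12) 1 else (sum(i * j * P) - mu^2) / sig2
  c(glcm_Autocorrelation = sum(i * j * P),
    glcm_JointAverage = mu,
    glcm_ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    glcm_ClusterShade = sum((i + j - 2 * mu)^3 * P),
    glcm_ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    glcm_Contrast = sum((i - j)^2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(xlog2(pdiff)),
    glcm_DifferenceVariance = sum((k_diff - da)^2 * pdiff),
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = hxy,
    glcm_Imc1 = safe_div(hxy - hxy1, hx), # HX = HY on a symmetric GLCM
    glcm_Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    glcm_Idm = sum(P / (1 + (i - j)^2)),
    glcm_Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    glcm_Id = sum(P / (1 + abs(i - j))),
    glcm_Idn = sum(P / (1 + abs(i - j) / ng)),
    glcm_InverseVariance = sum(ifelse(i != j, P / (i - j)^2, 0)),
    glcm_MaximumProbability = max(P),
    glcm_MCC = mcc,
    glcm_SumAverage = sum(k_sum * psum),
    glcm_SumEntropy = -sum(xlog2(psum)),
    glcm_SumSquares = sig2)
}

glrlm_features <- function(P, np) {
  nr <- sum(P)
  if (nr < 1) nr <- 1
  Pn <- P / nr
  ng <- nrow(P); nl <- ncol(P)
  i <- matrix(seq_len(ng), ng, nl)
  l <- t(matrix(seq_len(nl), nl, ng))
  pg <- rowSums(Pn)
  pl <- colSums(Pn)
  mu_g <- sum(i * Pn)
  mu_l <- sum(l * Pn)
  c(glrlm_ShortRunEmphasis = sum(Pn / l^2),
    glrlm_LongRunEmphasis = sum(Pn * l^2),
    glrlm_GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(pg^2),
    glrlm_RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    glrlm_RunLengthNonUniformityNormalized = sum(pl^2),
    # merged over 13 directions: each voxel can start up to 13 runs
    glrlm_RunPercentage = nr / (np * 13),
    glrlm_GrayLevelVariance = sum((i - mu_g)^2 * Pn),
    glrlm_RunVariance = sum((l - mu_l)^2 * Pn),
    glrlm_RunEntropy = -sum(xlog2(Pn)),
    glrlm_LowGrayLevelRunEmphasis = sum(Pn / i^2),
    glrlm_HighGrayLevelRunEmphasis = sum(Pn * i^2),
    glrlm_ShortRunLowGrayLevelEmphasis = sum(Pn / (i^2 * l^2)),
    glrlm_ShortRunHighGrayLevelEmphasis = sum(Pn * i^2 / l^2),
    glrlm_LongRunLowGrayLevelEmphasis = sum(Pn * l^2 / i^2),
    glrlm_LongRunHighGrayLevelEmphasis = sum(Pn * i^2 * l^2))
}

glszm_features <- function(zones, np) {
  # zones: two-column matrix (gray level, zone size), one row per zone
  i <- as.numeric(zones[, 1])
  s <- as.numeric(zones[, 2])
  nz <- length(i)
  if (nz < 1) { i <- 1; s <- 1; nz <- 1 }
  # per-cell joint counts for entropy and marginal non-uniformities
  joint <- table(paste(i, s))
  pg <- tabulate(zones[, 1])
  ps <- tabulate(zones[, 2])
  mu_g <- mean(i)
  mu_s <- mean(s)
  c(glszm_SmallAreaEmphasis = mean(1 / s^2),
    glszm_LargeAreaEmphasis = mean(s^2),
    glszm_GrayLevelNonUniformity = sum(pg^2) / nz,
    glszm_GrayLevelNonUniformityNormalized = sum(pg^2) / nz^2,
    glszm_SizeZoneNonUniformity = sum(ps^2) / nz,
    glszm_SizeZoneNonUniformityNormalized = sum(ps^2) / nz^2,
    glszm_ZonePercentage = nz / np,
    glszm_GrayLevelVariance = mean((i - mu_g)^2),
    glszm_ZoneVariance = mean((s - mu_s)^2),
    glszm_ZoneEntropy = -sum(xlog2(as.numeric(joint) / nz)),
    glszm_LowGrayLevelZoneEmphasis = mean(1 / i^2),
    glszm_HighGrayLevelZoneEmphasis = mean(i^2),
    glszm_SmallAreaLowGrayLevelEmphasis = mean(1 / (i^2 * s^2)),
    glszm_SmallAreaHighGrayLevelEmphasis = mean(i^2 / s^2),
    glszm_LargeAreaLowGrayLevelEmphasis = mean(s^2 / i^2),
    glszm_LargeAreaHighGrayLevelEmphasis = mean(i^2 * s^2))
}

ngtdm_features <- function(NS, np) {
  n_i <- NS[, 1]
  s_i <- NS[, 2]
  nvp <- sum(n_i)
  if (nvp < 1) nvp <- 1
  p_i <- n_i / nvp
  lev <- seq_len(nrow(NS))
  pres <- which(p_i > 0)
  ngp <- length(pres)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den < 1e-12) 1e6 else min(1 / coarse_den, 1e6)
  contrast <- 0
  busyness <- 0
  complexity <- 0
  strength <- 0
  if (ngp >= 1) {
    ii <- matrix(lev[pres], ngp, ngp)
    jj <- t(ii)
    pi_m <- matrix(p_i[pres], ngp, ngp)
    pj_m <- t(pi_m)
    si_m <- matrix(s_i[pres], ngp, ngp)
    sj_m <- t(si_m)
    if (ngp > 1) {
      contrast <- sum(pi_m * pj_m * (ii - jj)^2) / (ngp * (ngp - 1)) *
        sum(s_i) / nvp
      bus_den <- sum(abs(ii * pi_m - jj * pj_m))
      busyness <- safe_div(sum(p_i * s_i), bus_den)
    }
    complexity <- sum(abs(ii - jj) * (pi_m * si_m + pj_m * sj_m) /
                        (pi_m + pj_m)) / nvp
    str_num <- sum((pi_m + pj_m) * (ii - jj)^2)
    strength <- if (sum(s_i) < 1e-12) 0 else str_num / sum(s_i)
  }
  c(ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

gldm_features <- function(P) {
  nz <- sum(P)
  if (nz < 1) nz <- 1
  Pn <- P / nz
  ng <- nrow(P); nd <- ncol(P)
  i <- matrix(seq_len(ng), ng, nd)
  d <- t(matrix(seq_len(nd), nd, ng)) # dependence size = neighbors + 1
  pg <- rowSums(Pn)
  pd <- colSums(Pn)
  mu_g <- sum(i * Pn)
  mu_d <- sum(d * Pn)
  c(gldm_SmallDependenceEmphasis = sum(Pn / d^2),
    gldm_LargeDependenceEmphasis = sum(Pn * d^2),
    gldm_GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    gldm_DependenceNonUniformity = sum(colSums(P)^2) / nz,
    gldm_DependenceNonUniformityNormalized = sum(pd^2),
    gldm_GrayLevelVariance = sum((i - mu_g)^2 * Pn),
    gldm_DependenceVariance = sum((d - mu_d)^2 * Pn),
    gldm_DependenceEntropy = -sum(xlog2(Pn)),
    gldm_LowGrayLevelEmphasis = sum(Pn / i^2),
    gldm_HighGrayLevelEmphasis = sum(Pn * i^2),
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(Pn / (i^2 * d^2)),
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(Pn * i^2 / d^2),
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(Pn * d^2 / i^2),
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(Pn * i^2 * d^2))
}

#' Extract the 107-feature radiomic signature of one ROI
#'
#' Computes 18 first-order, 14 shape (3D), 24 GLCM, 16 GLRLM, 16 GLSZM,
#' 5 NGTDM and 14 GLDM features (107 total) from one image and one binary
#' mask, using fixed-bin-width discretization for the texture families.
#' Texture matrices aggregate the 13 unique 3D directions by merging.
#' Degenerate (single-gray-level) ROIs return the defined limits of each
#' formula (e.g. zero entropies, NGTDM coarseness capped at 1e6) rather
#' than NaN.
#'
#' @param image A [sirt_volume()] (already preprocessed/clipped).
#' @param mask Nonempty binary mask on the same grid.
#' @param bin_width Discretization bin width in the image's units.
#' @param gldm_alpha Gray-level similarity tolerance for GLDM (default 0).
#' @return Named numeric vector of 107 features.
#' @export
extract_features <- function(image, mask, bin_width, gldm_alpha = 0L) {
  stopifnot(inherits(image, "sirt_volume"))
  m <- as_mask_array(mask)
  check_same_grid(image$data, m, "image and mask")
  if (!any(m)) stop("empty mask", call. = FALSE)
  x <- as.numeric(image$data[m])
  glev <- discretize_fbw(x, bin_width)
  ng <- max(glev)
  garr <- array(0L, dim = dim(m))
  garr[m] <- glev
  dims <- as.integer(dim(m))
  np <- length(x)
  vox_mm3 <- prod(image$spacing)
  out <- c(
    fo_features(x, glev, vox_mm3),
    shape_features(m, image$spacing),
    glcm_features(cpp_glcm(garr, dims, ng)),
    glrlm_features(cpp_glrlm(garr, dims, ng), np),
    glszm_features(cpp_glszm(garr, dims, ng), np),
    ngtdm_features(cpp_ngtdm(garr, dims, ng), np),
    gldm_features(cpp_gldm(garr, dims, ng, as.integer(gldm_alpha))))
  stopifnot(length(out) == 107L)
  out
}

#' Feature family cardinalities of the implemented catalogue
#'
#' @return Named integer vector of features per family (sums to 107).
#' @export
feature_family_counts <- function() {
  c(firstorder = 18L, shape = 14L, glcm = 24L, glrlm = 16L,
    glszm = 16L, ngtdm = 5L, gldm = 14L)
}

channel_bin_width <- function(channel, cfg) {
  switch(sub("_(MAA|Y90)$", "", channel),
         SPECT = cfg$bin_width$SPECT,
         CT = cfg$bin_width$CT,
         DOSE = cfg$bin_width$dose,
         BED = cfg$bin_width$dose,
         stop("unknown channel: ", channel, call. = FALSE))
}

case_channel_volume <- function(case, channel, maps = NULL) {
  switch(channel,
         CT = case$ct,
         SPECT_MAA = case$spect_maa,
         SPECT_Y90 = case$spect_y90,
         DOSE_MAA = maps$maa_dose,
         DOSE_Y90 = maps$y90_dose,
         BED_MAA = maps$maa_bed,
         BED_Y90 = maps$y90_bed,
         stop("unknown channel: ", channel, call. = FALSE))
}

preprocess_channel_tag <- function(channel) {
  if (channel == "CT") "CT"
  else if (channel %in% c("SPECT_MAA", "SPECT_Y90")) "SPECT"
  else if (channel %in% c("DOSE_MAA", "BED_MAA")) "MAA_dose"
  else "Y90_dose"
}

#' Build a cases-by-features table for one image channel
#'
#' Extracts the 107 features for the three structures (tumor, NPL, WNL) of
#' every case: 321 columns named `<family>_<feature>_<structure>`, plus
#' `case_id` and `label`. For the CT channel the image and all masks are
#' resampled to the configured grid first; dose channels are clipped at
#' their fixed structure caps. Cases whose extraction fails (e.g. corrupt
#' masks) are excluded with a message.
#'
#' @param cohort A `phantom_cohort` (list of `phantom_case`).
#' @param channel One of `"CT"`, `"SPECT_MAA"`, `"SPECT_Y90"`,
#'   `"DOSE_MAA"`, `"DOSE_Y90"`, `"BED_MAA"`, `"BED_Y90"`.
#' @param cfg A [preprocess_config()].
#' @param ldm An [ldm_config()] (used by the dose channels).
#' @param maps_by_case Optional precomputed list of [case_dose_maps()]
#'   outputs, named by case id, to avoid recomputing dosimetry.
#' @return Tibble with `case_id`, `label` and 321 feature columns.
#' @export
build_feature_table <- function(cohort, channel, cfg = preprocess_config(),
                                ldm = ldm_config(), maps_by_case = NULL) {
  bw <- channel_bin_width(channel, cfg)
  ptag <- preprocess_channel_tag(channel)
  rows <- list()
  for (case in cohort) {
    row <- tryCatch({
      maps <- NULL
      if (grepl("^(DOSE|BED)_", channel)) {
        maps <- maps_by_case[[case$case_id]] %||% case_dose_maps(case, ldm)
      }
      vol <- case_channel_volume(case, channel, maps)
      st <- case$structures
      feats <- list()
      # CT / SPECT conditioning is structure-independent: do it once
      shared_v <- if (ptag %in% c("CT", "SPECT")) {
        preprocess_volume(vol, ptag, cfg = cfg)
      } else NULL
      for (s in c("tumor", "npl", "wnl")) {
        v <- shared_v %||% preprocess_volume(vol, ptag, structure = s,
                                             cfg = cfg)
        msk <- st[[s]]
        if (ptag == "CT") {
          msk <- resample_volume(msk * 1, cfg$ct_resample_mm,
                                 spacing = st$spacing, method = "nearest")
          msk <- msk > 0.5
        }
        f <- extract_features(v, msk, bw)
        names(f) <- paste0(names(f), "_", s)
        feats[[s]] <- f
      }
      fv <- unlist(feats, use.names = FALSE)
      names(fv) <- unlist(lapply(feats, names))
      tibble::as_tibble(c(list(case_id = case$case_id, label = case$label),
                          as.list(fv)))
    }, error = function(e) {
      message(sprintf("case %s excluded from %s features: %s",
                      case$case_id, channel, conditionMessage(e)))
      NULL
    })
    rows[[length(rows) + 1]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "channel") <- channel
  attr(out, "bin_width") <- bw
  out
}

#' Feature tables for every channel of a cohort
#'
#' Computes dosimetry once per case and builds the seven channel tables
#' (CT, two SPECT, two physical dose, two BED).
#'
#' @param cohort A `phantom_cohort`.
#' @param cfg A [preprocess_config()].
#' @param ldm An [ldm_config()].
#' @param channels Channels to build (default all seven).
#' @return Named list of feature tibbles.
#' @export
cohort_feature_tables <- function(cohort, cfg = preprocess_config(),
                                  ldm = ldm_config(),
                                  channels = c("CT", "SPECT_MAA", "SPECT_Y90",
                                               "DOSE_MAA", "DOSE_Y90",
                                               "BED_MAA", "BED_Y90")) {
  maps_by_case <- NULL
  if (any(grepl("^(DOSE|BED)_", channels))) {
    maps_by_case <- lapply(cohort, case_dose_maps, cfg = ldm)
    names(maps_by_case) <- vapply(cohort, function(c) c$case_id,
                                  character(1))
  }
  out <- lapply(channels, function(ch) {
    build_feature_table(cohort, ch, cfg = cfg, ldm = ldm,
                        maps_by_case = maps_by_case)
  })
  names(out) <- channels
  out
}
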