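---
title: "Methods: voxel dosimetry, dose-volume metrics, radiomics and response modeling for Y90 SIRT"
author: "sirtomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel dosimetry, dose-volume metrics, radiomics and response modeling for Y90 SIRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtomics)
```

# Scope

`sirtomics` implements a complete tumor-response analysis pipeline for
selective internal radiation therapy (SIRT) of liver tumors with Y-90
microspheres: voxel-level absorbed-dose maps from SPECT count images,
biologically effective dose (BED) maps, cumulative dose-volume histograms
(DVH/BVH) with the standard dose-volume-constraint (DVC) catalogue, a
107-feature radiomic/dosiomic signature per anatomical structure, and a
36-strategy machine-learning harness evaluated by seeded nested
cross-validation. Because clinical SPECT/CT cohorts of this kind are not
publicly distributable, the package ships a synthetic phantom generator
with analytic ground truth; every downstream stage is validated against
that truth or against independent brute-force oracles.

# Dosimetry

## Local deposition with self-calibration

SPECT voxel values (counts/s) are proportional to local activity but not
calibrated; acquisition duration, delay and camera sensitivity all scale
them. Because both Tc-99m-MAA and Y-90 glass microspheres are effectively
trapped after intra-arterial injection, the whole liver can serve as its
own calibration phantom: the counts inside the liver are assumed to
account for the entire administered activity. Under local energy
deposition (each voxel absorbs the beta energy emitted within it), the
dose to voxel $v$ is

$$D_v \;=\; \frac{c_v}{\sum_{u \in \mathrm{cal}} c_u}\;
\frac{A \cdot E}{m_v},$$

with counts $c$, administered activity $A$ (GBq), voxel mass $m_v$, and
$E$ the total emitted beta energy per unit activity. We use
$E = 49.67$ J/GBq for Y-90 (mean beta energy times the number of decays
per GBq of permanently implanted activity); the constant is a config
field (`ldm_config()`), as is the voxel-mass model (uniform
1.0 g/cm^3 by default, optionally CT-derived density) and the calibration
region (whole liver by default; the whole body is the alternative). The
MAA channel is converted with the *planned* Y-90 activity, since the MAA
study simulates the treatment. Lung-shunt deduction of the activity,
$A(1-\mathrm{LSF})$, is available but off by default; the LSF itself is
always an input scalar, never computed from planar images.

Two structural consequences are tested: self-calibration makes the map
invariant to any global count rescaling, and energy is conserved —
$\sum_v D_v m_v = A E$ to 1e-10 relative when all counts lie in the
calibration region.

## Biologically effective dose

Dose maps are transformed voxel-wise with the linear-quadratic repair
model for a permanently implanted, exponentially decaying source:

$$\mathrm{BED} = D\left(1 + \frac{D}{\alpha/\beta}\cdot
\frac{T_{Rep}}{T_{Rep}+T_{phys}}\right),$$

with $\alpha/\beta = 10$ Gy for both tissue classes, repair half-time
$T_{Rep} = 1.5$ h for tumor and $2.5$ h for normal liver, and the Y-90
physical half-life $T_{phys} = 64.2$ h. Tumor voxels use the tumor
parameters, all normal-liver voxels the normal parameters, and voxels
outside every structure are set to zero. BED $\ge$ D always, the
transform is strictly increasing and convex, and BED/D tends to 1 at
small dose; all three properties are asserted by tests, together with the
hand-evaluated anchor points BED(100 Gy) = 122.831 Gy (tumor) and
137.481 Gy (normal).

# DVH and the DVC catalogue

DVH curves are exact at voxel granularity: $V(d)$ is the voxel volume
times the number of in-mask voxels with dose $\ge d$. The exported curve
is binned (0.1 Gy pitch by default) but every scalar metric is computed
from the raw voxel doses, never from the binned curve. $D_x$ uses the
descending-sorted voxel convention without interpolation — the
$\lceil x\% \cdot n \rceil$-th hottest voxel — because it is exact,
trivially oracle-checkable, and matches treatment-planning-system
exports. $D_{max}/D_{min}$ are raw voxel extrema.

The per-case DVC record covers, for every structure (tumor, NPL, WNL)
$\times$ channel (MAA, Y90) $\times$ kind (dose, BED): structure volume,
$D_{mean}$, $D_{max}$, $D_{min}$, $D_5$, $D_{50}$, $D_{70}$, $D_{95}$,
$D_{98}$, and $V_{120}/V_{205}/V_{400}$ in both ml and % (the normal
structures add $V_{20}/V_{30}/V_{50}/V_{70}/V_{90}$), plus the tumor
homogeneity index $HI = D_5/D_{95}$ per map, the tumor-to-normal mean
dose ratios $TNR_{NPL}$ and $TNR_{WNL}$ per map, and the two scalar
personalized parameters LSF and injected activity. The same volume
thresholds are applied to dose and BED maps. Column names follow
`<structure>_<channel>_<kind>_<metric>`, so the schema is identical for
every case.

# The feature signature

## Catalogue

Each (structure, channel) pair yields exactly 107 features — 18
first-order, 14 shape (3D), 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and 14
GLDM — i.e. 321 columns per image channel over the three structures.
This is the default catalogue of the widely used fixed-bin-width
extractors, and it is the only family decomposition consistent with the
321 = 3 x 107 column contract; 2D shape features are not part of the
catalogue. Feature definitions follow the IBSI-conformant formulas;
small hand-computed oracles (first-order statistics on a 3x3x3 block,
co-occurrence/run/zone/dependence matrices enumerated by hand on a
three-voxel line) guard against drift in the implementation.

## Preprocessing and discretization

CT is resampled to 1.5 mm isotropic (trilinear; masks nearest-neighbour)
and clipped to [-500, 500] HU. SPECT is clipped between 0 and its own
99.9th percentile — bremsstrahlung SPECT carries sparse very hot outlier
voxels. Dose and BED maps are clipped at fixed caps so the intensity
range is comparable across cases: 650.34 / 158.02 / 127.08 Gy
(tumor/NPL/WNL) for the MAA channel and 416.25 / 133.16 / 123.08 Gy for
the Y-90 channel; BED maps use their channel's caps. Discretization is
fixed-bin-width with edges aligned to multiples of the width — 50
counts/s for SPECT, 20 HU for CT, 1 Gy for dose maps. SPECT and dose
maps are not resampled; dose maps inherit the SPECT grid.

## Numerical choices

* **Direction aggregation.** The four directional texture families
  (GLCM, GLRLM) merge their 13 unique 3D direction matrices before
  feature computation (the IBSI "merged" aggregation) rather than
  averaging features over directions. This is deterministic, faster, and
  makes the matrix-level hand oracles exact. Run percentage is
  normalized by $13 N_p$ accordingly.
* **GLCM MCC.** For a symmetric GLCM the row-normalized transition
  matrix is similar to $D^{-1/2} P D^{-1/2}$, so MCC (the second-largest
  eigenvalue magnitude) is computed with a symmetric eigensolver on the
  occupied gray levels — exact and an order of magnitude faster than a
  general eigendecomposition at the 1 Gy dose binning.
* **Shape.** Mesh surface area and volume come from marching tetrahedra
  at isolevel 0.5 on a 3x3x3 box-smoothed occupancy field with linearly
  interpolated crossings; the smoothing suppresses the staircase bias of
  meshing a raw binary mask (a 9-voxel-radius test sphere yields
  sphericity 0.99). Very small structures (a few voxels across) are
  rounded by the smoothing and their mesh volume under-reads; voxel
  volume is reported alongside. Axis lengths use the eigenvalues of the
  physical-coordinate covariance; maximum diameters use exact pairwise
  distances between surface voxels.
* **Degenerate ROIs.** Flat (single-gray-level) regions return each
  formula's defined limit instead of NaN: zero entropies and variances,
  uniformity 1, GLCM correlation 1, NGTDM coarseness capped at 1e6. Any
  non-finite feature that still arises is median-imputed *within
  training folds only* during modeling.

# The modeling harness

## Strategies

Six categories — {MAA, Y90} x {radiomics, dosiomics, DVH} — each with six
input mixes (radiomics: CT / SPECT / CT+Clinical / SPECT+Clinical /
CT+SPECT / CT+SPECT+Clinical; dosiomics and DVH: Dose / BED / Dose+BED /
Dose+Clinical / BED+Clinical / BED+Dose+Clinical) give 36 strategies;
with 5 feature selectors and 8 classifiers the full grid holds 1440
models. Sixteen clinical covariates are simulated; sex and extrahepatic
metastasis are excluded from modeling (extreme imbalance in the emulated
cohort), leaving 14. Note that three of the six mixes in *every*
category involve clinical features, so a missing clinical table
invalidates 18 of the 36 strategies.

## Pipeline order and leakage control

Per outer fold (3 stratified folds): z-score normalization (sample SD;
training statistics applied to the test fold), Spearman redundancy
pruning at $|\rho| \ge 0.90$ (keep the column with the better univariate
Kruskal score, ties broken lexicographically), feature ranking by the
selector, SMOTE oversampling of the minority class (5 neighbors), fit.
The inner threefold loop grid-searches the classifier hyperparameters
and the number of selected features $k \in \{5, 10, 15\}$ by pooled
inner AUC; every one of these steps is re-fitted inside each inner
training fold, so no test information leaks into any of them. The
pipeline order is prune → select → SMOTE → fit: oversampling last keeps
synthetic points out of the selection statistics. Rankings are
classifier-independent and therefore computed once per fold; the greedy
selectors produce nested rankings, so the $k$ search reuses prefixes. A
leakage canary (a feature equal to the label on training folds but
corrupted on test folds) is part of the test suite and must stay at
chance AUC.

Metrics (AUC, accuracy, sensitivity = responder recall, specificity) are
reported both pooled over the outer-test predictions and averaged per
fold, with a 1000-replicate bootstrap percentile CI on the pooled AUC.

## Methods realized on established fits

DT = `rpart`, LR = `stats::glm`, MLP = `nnet`, NB and SVM = `e1071`,
RF = `randomForest`, XGB = `xgboost`. GLMB — named but nowhere specified
in the SIRT modeling literature we follow — is realized here as
component-wise boosting of a logistic base learner (at each of `mstop`
steps the current log-loss gradient is fitted by the single best simple
linear learner with shrinkage 0.1). ANOVA and Kruskal selectors use the
closed-form two-group tests; MRMR is the greedy
relevance-minus-redundancy scheme (normalized F-score relevance, mean
|Pearson r| redundancy, with near-duplicates above |r| = 0.95 deferred,
mirroring the self-information penalty of mutual-information mRMR);
Relief is ReliefF with 3 nearest hits/misses over all instances; RFE
eliminates 20% batches on linear-SVM weights. Hyperparameter grids are
deliberately small published-convention grids (2-4 combinations per
classifier), recorded in `classifier_spec()`.

The DeLong test is implemented from the placement-value covariance; its
AUC equals the rank AUC to 1e-12, the p-value is cross-checked against
both an exhaustive 2^10 permutation oracle and the reference
implementation in `pROC`, and degenerate cases are reported explicitly
(identical rankings give p = 1; perfect separation by both classifiers
leaves the statistic undefined). Univariate screening uses Mann-Whitney
U for continuous and Fisher's exact test for categorical columns with
Benjamini-Hochberg adjustment at q = 0.05, reporting significance before
and after adjustment.

# The phantom generator

## What it emulates

Each case is an ellipsoidal liver (semi-axes 105/84/63 mm, about 2.3 L)
inside a soft-tissue body on air, with a perfused territory covering the
bulk of the liver and a spherical tumor strictly inside it. NPL and WNL
are derived by mask subtraction, exactly as in the clinical workflow.
The activity field is piecewise log-normal with spatially correlated
texture (coarse Gaussian noise, trilinearly upsampled; correlation
length 4 voxels); within each structure the sample mean is renormalized
*exactly*, so the noiseless tumor-to-NPL count ratio equals the
configured TNR to machine precision — this is what makes dosimetry
recovery testable at the 0.1% level. MAA and Y90 SPECT derive from the
same underlying field with independent Poisson draws; an optional
mean-preserving mismatch field (default 0, since the MAA-vs-Y90
discrepancy is not quantified in the literature we follow) can decouple
them. CT shows liver at 50 ± 8 HU with the same correlation structure
and a slightly hypodense tumor.

Default study conditions, chosen once for clinical realism: 4 mm
isotropic SPECT grid (64 x 56 x 40), 2.8 GBq planned activity (a typical
median for glass microspheres), TNR 3, LSF 0.05, NPL uptake 100
counts/s (about 3 x 10^6 counts/s over the perfused volume, enough for
sub-percent Poisson concentration). These conditions put the mean tumor
dose near 230 Gy and mean NPL dose near 75 Gy — inside the range the
fixed dose-clipping caps were designed for. Per-case anatomy is jittered
(tumor radius x0.75-1.35, liver x0.9-1.1, label-independent) so shape
and volume features carry real between-patient variance; note this also
injects dose variability through the calibration mass, which is why the
default-conditions cohort is *not* perfectly separable.

The emulated cohort is 17 cases with 5 responders / 12 non-responders.
Responders carry the class effect: tumor uptake scaled by 1.5 and finer
tumor texture (granularity shift -2). With the effect zeroed the classes
are indistinguishable by construction; with a large effect
(uptake x 3) a nested-CV model on Y90 dosiomics reaches
AUC = ACC = SEN = SPE = 1, the synthetic analogue of the
perfect-separation headline reported for such cohorts.

## What it does not emulate

No projection/reconstruction physics (no OSEM, collimator, scatter or
partial-volume effects), no registration error, no anatomical atlas
realism, no MAA-vs-Y90 biological mismatch by default, and no
dose-response biology beyond the configured uptake/texture shift.
Passing tests therefore demonstrate the *correctness of the pipeline
machinery* — conservation, exactness, leakage-freedom, determinism —
not clinical predictive validity on real patients.

# Problem sizes and determinism

The test suite uses a down-scaled phantom (5 mm grid, 36 x 32 x 24,
0.6 GBq so the dose range matches the clinical caps) for per-module
checks, the full-size conditions for the schema and counting checks,
and synthetic Gaussian tables for the statistical properties of the
harness; the acceptance script runs the full-size 17-case cohort.
Every stochastic step — phantom draws, fold assignment, SMOTE, Relief,
classifier fits, bootstrap — derives its seed from one master seed, and
the full pipeline (`run_all()`) writes a manifest of MD5 checksums that
is reproduced byte-identically on reruns.

# Known limitations

* The mesh-based shape features under-read structures only a few voxels
  across (occupancy smoothing); voxel-count volume is exact.
* With 17 cases, threefold outer folds hold 5-6 cases; pooled metrics
  are reported alongside per-fold means precisely because per-fold AUCs
  on such folds are coarse.
* The GLMB and Relief variants are reasonable namesake realizations, not
  reimplementations of any specific published code.
* BH-corrected univariate screening at n = 17 with hundreds of features
  has essentially no power (the rank-test p floor times the correction
  exceeds q) — the same behaviour reported in small SIRT cohorts; the
  package reports both raw and adjusted flags.
```
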