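---
title: "Methods: multimodal imaging features for IDH1 genotype prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal imaging features for IDH1 genotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpath)
```

## The problem

IDH1 mutation status stratifies the diagnosis and prognosis of diffuse
glioma, but molecular testing requires tissue and a genetics laboratory.
`radpath` implements an automated machine-learning pipeline that predicts
IDH1 genotype from two imaging modalities that are routinely available:
digitized H&E histopathology slides and co-registered multi-sequence MR
volumes (post-contrast T1 and T2-FLAIR) with tumor-compartment masks
(enhancing tumor, necrosis, peritumoral edema), fused with age and sex.

The pipeline is: automated histology ROI selection, two-level feature
extraction (histology morphometry + texture; 3D MRI radiomics), fusion,
random-forest recursive feature elimination (RF-RFE) nested inside
stratified 10-fold cross-validation, and a LIME-style local surrogate to
explain individual predictions.

Because no patient images ship with the package, a first-class synthetic
fixture module generates H&E-like tiles with known nucleus ground truth and
ellipsoidal MR phantoms with a controllable class effect. Every downstream
stage is tested against these fixtures.

## Histology ROI selection

A slide is represented as a set of RGB tiles with slide origins. Three ROI
groups are selected per slide:

1. **The highest cell-density tile.** Nuclei are detected by stain
   deconvolution (Ruifrok–Johnston H&E optical-density vectors), Otsu
   thresholding of the hematoxylin channel, hole filling, removal of objects
   below `min_area` (default 40 px at 40X), and a distance-transform
   watershed to split touching nuclei (`EBImage`). Density is the nucleus
   count divided by tissue-pixel count — count *per tissue area* rather than
   the raw count, so tiles that are half glass are not penalized for their
   background. Ties are broken by lowest (y, x) origin, which makes the
   choice invariant to candidate order.
2. **Five HSV-representative tiles at the native (40X) level.** Tissue
   pixels are those with saturation ≥ 0.05 and value ≤ 0.98 (glass is
   near-white: high value, near-zero saturation). The whole-slide profile is
   a joint 16×8×8 Hue–Saturation–Value histogram over tissue pixels; each
   tile is scored by the chi-squared distance of its own profile to the
   slide profile and the five lowest-distance tiles are taken, greedily
   skipping tiles that share an edge with an already-selected tile. When the
   adjacency constraint cannot be satisfied the remaining slots are filled
   by score (the greedy pass does not attempt a combinatorially optimal
   independent set).
3. **Five HSV-representative tiles at the low (4X) level**, computed the
   same way; when only one magnification exists on disk the low level is
   emulated by 4× average pooling.

The density tile is kept distinct from the representative set, so a slide
contributes 11 ROIs.

## Histology feature banks

- **Visual (22).** Ten per-nucleus measures (area, perimeter, major/minor
  axis, eccentricity, solidity, extent, circularity, equivalent diameter,
  mean hematoxylin OD), each summarized as mean and standard deviation
  across nuclei, plus nucleus count and nucleus density. An empty tile
  reports count/density 0 and missing (imputable) values elsewhere.
- **Sub-visual (171).** On the luminance image restricted to tissue: the
  19 first-order features (the standard 18 plus StandardDeviation) and 19
  co-occurrence features × 4 directions (0°, 45°, 90°, 135°) × 2 distances
  (1, 2 px) on a 32-level equal-width discretization. Each
  direction/distance is kept as a separate feature (no direction averaging)
  — that composition is what yields 19 + 152 = 171. The 19 co-occurrence
  names are the 3D GLCM set minus JointAverage (redundant with the
  first-order mean) and the two Ng-normalized inverse-difference variants
  (Idmn, Idn), whose normalization is uninformative at fixed Ng.

Tile vectors are pooled to one slide vector by a missing-aware feature-wise
mean; both magnification levels contribute to the same pooled bank (keeping
separate per-level banks would double the width without adding information
on the fixtures, and the pooled form keeps the printed bank sizes).

## MRI radiomics bank (1,132 features)

Thirteen image types — the original volume, Laplacian-of-Gaussian filters at
σ = 1, 2, 3, 4 mm, and the eight sub-bands of a one-level 3D discrete
wavelet transform — each contribute 18 first-order + 22 GLCM + 16 GLRLM +
16 GLSZM + 14 GLDM = 86 features; 14 shape features are computed once on
the mask. 13 × 86 + 14 = 1,132, with class sub-counts 234 first-order,
286 GLCM, 208 GLRLM, 208 GLSZM and 182 GLDM. This is the unique standard
configuration consistent with all of those totals at once. NGTDM features
are implemented but excluded from the default bank (`include_ngtdm = TRUE`
adds 5 per image type); no printed total accounts for them.

Key numerical conventions, all fixed in code and registry:

- **Discretization**: 32 equal-width bins over the in-mask range,
  right-closed (`level = ceiling((x − min)/w)`, minimum → level 1). A
  constant region occupies a single level.
- **Texture matrices**: accumulated in C++ over the 13 unique 3D offsets at
  distance 1; GLCMs are symmetric and normalized per direction; features
  are averaged over directions that contain at least one pair/run (a
  single-voxel mask yields missing GLCM features). GLSZM zones are
  26-connected components of equal level; GLDM uses the 26-neighbourhood
  with similarity tolerance α = 0, dependence size = dependent count + 1.
  Formulas follow the standard definitions, e.g. Uniformity
  \(F_u=\sum_i p(i)^2\), MaximumProbability \(F_{MP}=\max p(i,j)\),
  LongRunLowGrayLevelEmphasis
  \(F_L=\tfrac{1}{N_r(\theta)}\sum_{i,j}P(i,j|\theta)\,j^2/i^2\), and
  SmallAreaLowGrayLevelEmphasis
  \(F_{SALGLE}=\tfrac{1}{N_z}\sum_{i,j}P(i,j)/(i^2 j^2)\).
- **Shape**: principal-component axis lengths \(4\sqrt{\lambda}\) of the
  voxel-centre cloud in mm; Flatness = \(\sqrt{\lambda_{least}/\lambda_{major}}\)
  (≈ c/a for a solid ellipsoid, 0.25 for semi-axes 8, 4, 2). Surface area is
  face-counted; maximum diameters use surface voxels with a deterministic
  stride subsample above 1,500 points to bound the quadratic cost. A
  degenerate coplanar mask reports Flatness 0.
- **Wavelet bank**: one-level separable DWT with the orthonormal coiflet-1
  filter pair and periodic boundary; each sub-band is projected back to the
  original grid by inverting with the other bands zeroed. The eight outputs
  are orthogonal projections: they sum to the input and their energies sum
  to the input energy (exact for even axis lengths; odd axes are padded by
  one reflected sample and cropped). Band letters LLL…HHH index axes 1–3.
- **LoG bank**: separable scale-normalized \(\sigma^2\nabla^2 G_\sigma\)
  filtering in physical units (per-axis voxel sigma σ/spacing), reflective
  boundaries, second-derivative kernels corrected to sum to zero so a
  constant volume responds exactly 0. Scale normalization makes the
  response of a ball of radius r peak near σ = r/√3, which the tests use.

Every feature name encodes its provenance
(`<filter>__<class>__<feature>`, plus `<sequence>__<mask>__` at the subject
level), and the registry (`mri_bank_registry()`, `histo_bank_registry()`)
is hashed (FNV-1a) into fitted models so schema drift is detectable.

## Fixtures: what the generators emulate

`make_tile()` renders nuclei as filled ellipses in optical-density space
(transmitted light \(I = 10^{-OD}\), eosin-like background plus per-nucleus
hematoxylin contributions), so stain deconvolution behaves as on scanned
H&E. Centres are sampled on the integer pixel grid; with zero radius spread
all nuclei rasterize to the identical disk, giving exact pixel-count
oracles. Elongation jitter is proportional to the radius coefficient of
variation; placement is rejection-sampled under a centre-distance overlap
rule, and an impossible packing is an explicit error.

`make_phantom()` builds nested ellipsoid compartments (necrosis ⊂ enhancing
⊂ edema) shared exactly between the two modality volumes, with
Gaussian-smoothed noise of stated correlation length (2 mm default). The
class effect shifts tumor-compartment means by `effect × noise_sd` and
multiplies the noise correlation length by `1 + effect/2`, so both
intensity and co-occurrence texture respond monotonically to the effect.

`make_cohort()` writes tiles, phantoms and a manifest per subject. The
injected effect also acts on tile nucleus density (+12 %/unit), stain
intensity (+0.05/unit) and age (−4.27 years/unit for mutants around a
56-year wildtype mean with SD 10 — at the default large effect of 3 the age
channel alone separates classes at roughly the 0.74 accuracy expected of
age in this disease). Cohort tiles allow 30 % nucleus overlap, as touching
nuclei are the norm in tissue. `make_feature_table()` is the tabular
counterpart (informative features with a stated effect in SD units plus
pure noise) used for model-level simulations where image rendering would
only add runtime.

What the fixtures deliberately do **not** model: MR physics (bias fields,
motion, partial volume beyond voxelization), pyramidal WSI files, nucleus
type heterogeneity, and registration error (both modalities share masks
exactly). Passing tests therefore demonstrate the correctness and signal
path of the machinery, not clinical performance; cohort-level accuracies on
real patients are out of scope by design.

## Modeling

`fuse()` concatenates modality tables on subject id and appends age and
sex. All preprocessing is fitted strictly on training folds: median
imputation, then z-scoring. `rf_rfe()` fits a 500-tree probability forest
(`ranger`, impurity importance, `min.node.size = 1` — the probability-forest
default of 10 cannot split small training folds), removes the
lowest-importance 10 % of remaining features per iteration, and picks the
candidate set maximizing internal 5-fold accuracy; ties go to the smaller
set, and importance ties are broken by column order (documented contract,
exercised by the all-constant-feature test). `cv_evaluate()` wraps this in
stratified 10-fold cross-validation with RF-RFE refit inside every
training fold — selection never sees its test fold, which the
permuted-label check verifies by staying at chance. Accuracy is reported
as mean ± sd over folds; the ROC/AUC pools test-fold probabilities.
`idh_rf()` refits preprocessing + selection + forest on the full table and
returns a classed fit with `predict()`, carrying its scaler, medians,
selected features and registry hash.

All forests run single-threaded with derived seeds, so a run is exactly
reproducible from one integer seed; derived seeds stay below 2^31.

## Local surrogate explanations

`explain_instance()` draws Gaussian perturbations (unit variance) around
the standardized instance, weights them by \(\exp(-d^2/w^2)\) with
\(w = 0.75\sqrt{p}\) (the common kernel-width convention), and fits a
weighted ridge regression (λ = 0.01, intercept unpenalized) to the
classifier's mutant probability. The binary sex indicator is perturbed by
resampling the training frequency rather than adding noise. Reported are
signed weights (positive = increasing the feature increases predicted
mutation probability near this case), the top-k by |weight|, and a
weighted R² fidelity clipped to [0, 1]. The surrogate recovers the signs,
ranking and linear scaling of a known linear black box within tolerance,
and a constant black box yields zero weights.

## Problem sizes and defaults

The demonstration configuration uses a 12-subject cohort, 80–96 px tiles,
28×28×20-voxel phantoms, 3–4 CV folds and 200–300 trees; with those sizes a
full pipeline run takes about a minute on one CPU. The signal-recovery
simulations use 60-subject tabular cohorts with a 3-SD injected effect,
nested RF-RFE 10-fold CV at the default 500 trees, 10 permutation
repetitions and 20 selection-stability seeds. Default phantom geometry
(36×36×26 voxels at 1 mm, edema semi-axes 14×11×9 mm) keeps compartments in
realistic proportion while each VOI extracts in ~1 s. `"5,120 × 5,120"`-px
density tiles are a configuration value, not a code path: scaled fixtures
exercise the identical code.

## Known limitations

- Greedy representative-tile selection may fall back to score-filling when
  non-adjacency is infeasible, as documented above.
- Surface area is face-counted (voxelized), not mesh-based; it converges to
  the smooth surface area only up to a voxelization factor, which is why
  sphericity/compactness are compared against fixtures rather than analytic
  solids.
- Correlation of a constant-level GLCM is defined as 1 by convention;
  single-voxel masks flag texture features missing rather than inventing
  values.
- The watershed splits nuclei overlapping by less than about a third of a
  radius; heavier clumping merges, which is the usual failure mode of
  distance-transform watersheds.
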