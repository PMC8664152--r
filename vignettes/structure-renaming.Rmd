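---
title: "Shape-based classification and renaming of radiotherapy structure sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based classification and renaming of radiotherapy structure sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiotherapy structure sets accumulate years of free-text naming habits:
the right femoral head may appear as `FemoralHead_R`, `caput dx`, `caput dx1`
or `avoid dx`, and target volumes carry ad-hoc dose suffixes and scenario
abbreviations. Text rules can repair some of this, but they trust the label,
not the delineated geometry, and they break across clinics and languages.
`rtnamer` instead classifies each structure *by its shape and its spatial
context*, using only the binary delineation masks — never the underlying CT
or MR intensities — so the same model applies to any image modality. The
pipeline ends by writing a renamed copy of the DICOM structure set with
standardized class names, carrying over the prescription-dose token found in
the original name of target structures.

## Input representation

Each structure is rasterized from its planar contours onto the image grid (a
voxel is foreground iff its center lies inside the polygon, even-odd rule)
and condensed into a four-channel 2D input:

1. **Transversal, coronal, sagittal projections** (channels 1–3): for each
   view, rays are traced through the mask, per-ray voxel sums are truncated
   at 1, which is exactly the max-projection "shadow" of the 3D shape.
2. **AddMap** (channel 4): at the structure's center-of-mass axial slice, a
   weighted sum of *all other* structures' masks — weight 0.1 for the body
   outline, 0.2 for every other structure — truncated at a ceiling of 1.

The AddMap is what lets the model tell a CTV from its PTV: the CTV's AddMap
contains the surrounding PTV ring and vice versa, encoding inter-structure
geometry that a single-structure shadow cannot. Optimization helper
structures (names beginning, in any letter case, with `Tuning`, `Help`, `X`,
`Y`, `Z`, `Dose` or `Match`) and empty structures are excluded both as
samples and from every AddMap.

All views are resampled to the network resolution (default 256×256, here
64×64 for desk-scale runs) with nearest-neighbour interpolation (target
pixel `i` reads source pixel `ceiling((i - 0.5) * S/T)`), so binary channels
stay binary. The structure volume is computed *before* resampling and kept
alongside the sample; it is used only for quality control, never as model
input.

One representational subtlety: the AddMap needs to know which structure is
the body before classes are known. At training time the ground-truth body
label is used; at inference time the largest-volume structure in the set is
taken as the body, which is robust for pelvic structure sets where the
external outline dominates every organ.

## Classifier and ensemble

The taxonomy has 22 trainable classes (9 organs at risk, 2 couch support
structures, 1 GTV, and CTV+PTV for five target scenarios) plus an
analysis-only `Other` class that can occur as ground truth but is never
predicted. Training uses subject-level K-fold cross-validation (default 10
folds; desk-scale runs use 3) so no subject contributes to both training
and validation, a class-balanced weighted categorical cross-entropy
(`w_c = N/(K n_c)`, computed on each fold's own training subjects to avoid
validation leakage), Adam with learning rate 0.001, and a plateau schedule
that multiplies the rate by 0.2 after 10 epochs without strict improvement
of the validation weighted accuracy. No early stopping is used: the
final-epoch model of every fold is kept. "Weighted accuracy" here is
inverse-class-frequency weighted, i.e. the mean per-class recall, which
reduces to plain accuracy when classes are balanced.

The backbone is a *contract* (init / forward / train-step), not a fixed
architecture. The built-in reference backbone is a compact fully-connected
softmax network over the flattened 4-channel input (ReLU, He
initialization), implemented in base R matrix algebra: the scientific
machinery exercised by this package — the representation, the ensemble
voting and the QC — is backbone-agnostic, and the phantom classes are
separable enough that a deeper convolutional backbone adds nothing at desk
scale. Heavier backbones can be registered under new ids for full-scale
data.

At inference every structure is scored by all K fold models. The final
label is the majority vote; ties break first on the larger summed
probability over the tied classes, then on the lower class id (the tie rule
is a package choice — votes from an odd number of folds rarely tie). The
mean winner probability is averaged over exactly the folds that voted for
the final class.

## Quality control

Three advisory checks run in sequence, stopping at the first failure, so
each structure carries at most one flag:

1. **Volume**: the structure volume must lie within the 1st–99th percentile
   (linear interpolation between order statistics) of the training volumes
   of the predicted class.
2. **Agreement**: at least 6 of 10 models must agree; for smaller ensembles
   the threshold generalizes as `ceiling(0.6 K)`.
3. **Probability**: the mean winner probability must not be below 0.7 — a
   low value suggests an input the model was never trained on.

Flags are advisory: flagged structures are still renamed, and the flag is
recorded in the QC table. Structures failing checks are deliberately *not*
remapped to `Other` — the model has no `Other` output class.

## The synthetic phantom cohort

The generator emulates the geometry a pelvic structure-set classifier must
learn, not anatomy per se: an elliptical-cylinder body, two couch slabs
(thin surface, thick interior), ellipsoidal/tubular organs at risk at
plausible offsets, and per-subject target scenarios (gland only, gland with
separate or fused seminal vesicles, pelvic lymph-node irradiation with its
U-shaped elective node band, and post-operative prostate bed). Every PTV is
its CTV expanded isotropically by a 7 mm margin; the GTV sits strictly
inside the gland CTV. Structure sizes and positions are jittered per
subject (global size factor ±8%, per-structure radii ±8%, centers a few
mm), and clinical-style display names are drawn from per-class synonym
pools, with dose tokens in assorted spellings (`78Gy`, `42,7 gy`, …)
embedded in target names. Optimization structures with the standard
prefixes are injected at a configurable rate (default 0.2 per anatomical
structure) and occasional empty structures exercise the skip path. Stress
options inject out-of-taxonomy fused targets (gland+vesicles+nodes as one
structure) and gross volume outliers for QC testing.

Shapes are generated as per-slice polygons and written as a real DICOM
subject (uniform-intensity CT-like series carrying only geometry, plus an
RTSTRUCT), so every downstream module runs on exactly the files it would
see in production, and re-rasterizing the written contours reproduces the
generator's masks voxel-for-voxel. The PTV margin is applied analytically
in contour space (semi-axis/radius expansion) rather than by dilating voxel
masks: this keeps the contour-mask round trip exact while preserving the
margin semantics (the CTV→PTV boundary distance along the axes is the
configured margin to within one voxel, which the tests verify with a
distance oracle).

What the phantom does *not* emulate: real delineation noise, inter-observer
variability, non-ellipsoidal organ shapes, overlapping targets in arbitrary
boolean combinations, or class-volume distributions of any particular
clinic. Passing the synthetic suite therefore demonstrates that the
pipeline's machinery is correct and that the representation separates
geometrically distinct classes — not that the shipped configuration reaches
clinical accuracy on real data, which requires training on a clinical
cohort.

## Numerical choices and degenerate inputs

- Rasterization: even-odd combination of multiple polygons on a slice (inner
  rings create holes; a union fill is available); contours fill only their
  own slice, with no inter-slice interpolation; degenerate polygons (<3
  points) are skipped with a warning, out-of-volume contours are clipped.
- Center-of-mass slice: mean foreground slice index, ties rounding half up.
- Loss: `-w log(p + 1e-12)`; the epsilon only guards `log(0)`.
- Learning-rate plateau: "no change" means no strict improvement over the
  best value so far.
- Percentiles: linear interpolation between order statistics
  (`quantile(type = 7)`); a single-sample class has `p1 == p99`.
- Empty structures have no center of mass and are excluded before
  featurization; a structure failing featurization is recorded as skipped,
  not fatal.
- Renamed DICOM copies change only the ROI name fields and the SOP instance
  UID; names longer than the 64-character DICOM LO limit are refused rather
  than truncated.
- DICOM I/O is restricted to axis-aligned axial series in Explicit VR
  Little Endian; anything else is rejected with a clear error rather than
  silently reinterpreted.

## Desk-scale study conditions

The reference synthetic experiment — used by the test suite and the
acceptance script — generates 120 training subjects and a held-out cohort
of 30, at the default 128×128×64 grid with 3 mm voxels, features at 64×64,
and a 3-fold ensemble trained 15 epochs with the default optimizer
settings. This fits comfortably in a few minutes on one CPU while
exercising every module at full fidelity; the resolution, fold count and
epochs are configurable up to the full-scale recipe (256×256, 10 folds, 100
epochs) when real cohorts and hardware are available.

## Known limitations

- The feature store is held in memory (a tibble with an array list-column);
  cohorts of tens of thousands of structures at 256×256 would need a
  chunked on-disk store.
- The reference backbone is not a convolutional network; with messy
  clinical masks a CNN backbone plugged into the backbone contract is the
  expected upgrade path.
- Body identification at inference (largest volume) can mis-weight the
  AddMap for cropped scans where the body is not the largest structure.
- QC volume bounds inherit the training cohort's scan extent: couch and
  body structures from scanners with different fields of view will flag on
  volume, which mirrors the advisory intent of the check.
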