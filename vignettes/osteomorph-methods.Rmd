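---
title: "Methods: microCT morphometry and surface-based erosion scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microCT morphometry and surface-based erosion scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic phantoms do and do not emulate, the numerical conventions, and
the known limitations. Nothing here states an empirical number that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

The input is a reconstructed microCT volume calibrated to
hydroxyapatite-equivalent mineral density (mg HA/cm³) on an isotropic
grid, 6 μm voxels by default. We assume calibration (and any
beam-hardening correction) was applied by the producer of the volume;
the package performs none. The tomogram stack runs along the first array
axis, and all regions of interest are expressed as contiguous tomogram
runs, matching how such protocols are reported (counts of tomograms, or
millimetres at a stated voxel size).

Bone is separated from soft tissue and marrow by a *fixed* global
threshold after light Gaussian denoising. A fixed threshold on a
calibrated scale is what makes longitudinal and between-group
comparisons meaningful; adaptive thresholds would confound group effects
with segmentation effects. The comparison is inclusive (density ≥
threshold counts as bone): the choice is arbitrary but fixed and tested.

## Filtering

`gaussianFilter` implements the scanner-software convention of a
*sampled, truncated, renormalised* separable Gaussian specified by two
numbers, both in voxel units:

* `sigma` — the standard deviation of the sampled kernel;
* `support` — the truncation half-width; `support = 1` gives a 3-tap
  kernel per axis.

Renormalisation makes constants exactly invariant, so the filter cannot
shift the calibrated density scale. Boundaries are mirror-reflected,
which avoids the edge darkening that zero-padding would cause — and that
would otherwise bias surface estimates near ROI boundaries. `sigma = 0`
or `support = 0` is the exact identity. The defaults are the standard
noise filter (σ = 0.8, support 1); the erosion module additionally uses
a strong smoothing filter (σ = 2.5, support 5). Whether the vendor
software samples the continuous Gaussian or integrates it over voxels is
not documented anywhere we know of; the sampled-and-renormalised form is
used here and is the form the oracle tests pin down.

## Morphometry conventions

Volumes (BV, TV, marrow, total diaphysis volume) are voxel counts times
the voxel volume. This makes conservation identities exact by
construction: `total = marrow + cortical BV` holds to machine precision,
and the acceptance script verifies it at ~1e-16 relative.

The bone surface BS is deliberately *not* voxel-face counting, which
overestimates the area of smooth surfaces by up to ~50%. Instead BS is
the area of a triangulated iso-surface of the *filtered grayscale*
density field at the segmentation threshold, computed by marching
tetrahedra on the Kuhn 6-tetrahedron decomposition of each grid cell
with linear interpolation of edge crossings. The mixed convention
(mesh area for BS, voxel counting for BV) trades a little internal
consistency for much better absolute accuracy of each quantity, and is
documented here because ratios such as BS/BV inherit both conventions.

Two details of the surface estimator matter in practice:

* **ROI clipping.** A grid cell contributes surface only if all eight of
  its corners lie inside the ROI. Surface sheets cut open at a slab end
  are left open — the cut ends are ROI artefacts, not anatomy, and are
  not counted.
* **Residual voxelisation bias.** On binary phantoms voxelised at voxel
  centres, the light standard filter does not fully erase the staircase,
  and the leftover roughness inflates the mesh area by a small
  radius-independent relative amount (the test suite bounds it at 3%,
  and measures ~1.5% for spheres). Because the bias is constant in
  relative terms, the area error does *not* vanish as the radius grows;
  what does shrink with radius is the scatter induced by the sub-voxel
  placement of the surface, and that is what the convergence test
  asserts. On real (band-limited) scans, which are not binary, this
  voxelisation term is largely absent.

Tb.Th and Ct.Th use the model-independent direct method: the local
thickness at a bone voxel is the diameter of the largest sphere fully
inscribed in the structure that contains that voxel. The implementation
computes the exact Euclidean distance transform (distance to the nearest
background voxel centre), prunes sphere centres whose spheres are
contained in a neighbour's, and paints the surviving spheres. Averaging
is per-voxel (volume-weighted) over the ROI, the standard definition.
The distance-to-centre convention makes a 10-slice plate exactly 10
voxels thick and a tube wall accurate to ~+0.4 voxel, but gives digital
cylinders at half-integer lateral centres a ~−1 voxel bias; for
features near 10 voxels this is the dominant thickness error and it
halves (in mm) when the voxel size halves. Features ≥ 15 voxels are
comfortably inside the package's stability tests.

## The erosion scores

Focal erosion is scored per joint ROI with two deliberately independent
numbers:

* **BS/BV** (1/mm) — surface density. Pitting adds surface while
  removing volume, so BS/BV rises; bone accrual (e.g. endosteal
  apposition) adds volume and lowers it. It is therefore sensitive to
  *both* erosion and bone-mass changes.
* **BSsmooth/BS** — smoothness. BS is recomputed (same mesh, same ROI,
  same threshold) after applying the strong filter (σ = 2.5, support 5)
  to the *raw* grayscale volume, and the ratio taken. A smooth surface
  is nearly invariant under extra smoothing (ratio ≈ 1); a pitted
  surface loses its excess area (ratio → 0). Because both numerator and
  denominator are areas of the same anatomy, the ratio is insensitive to
  bone volume as such — which is exactly what lets it dissociate
  "erosion repaired" from "erosion buried under new bone".

Design choices here, and why:

* The strong filter acts on the raw volume, not on the already-filtered
  one (the difference is tiny — the combined σ would be
  √(0.8² + 2.5²) ≈ 2.6 — but raw is the literal reading of "applied to
  the images"). Smoothing the *binary segmentation* instead is available
  (`onMask = TRUE`) but is not the default: re-binarising a smoothed
  mask measures a different, contrast-free notion of roughness.
* If the strong filter erases every iso-crossing, BSsmooth = 0 and the
  smoothness is defined as 0 — the extremely-rough limit.
* Joint ROIs pool all bone surfaces inside them (all tarsal bones in an
  ankle ROI are scored together).

One genuine singularity of the estimator is worth knowing about. The
rough limit "smoothness → 0" relies on the strongly smoothed field
pulling away from the threshold. For a random bone/background mixture
whose *mean density equals the threshold* (e.g. 50% bone at 900 against
background 100 with the threshold at exactly 500), the smoothed field
still crosses the iso-level everywhere and the ratio converges not to 0
but to roughly the bandwidth ratio of the two filters (~0.3; the
acceptance script computes it on 128³ speckle). Any asymmetry breaks the
degeneracy: at 40% bone the estimator collapses to ~10⁻⁴ (a property
test computes this). Real pitted surfaces are nowhere near this singular
point, but a validation phantom can be.

## Regions of interest

Slabs are contiguous tomogram runs (1-based, inclusive in the R API);
millimetre extents convert to slice counts by rounding half away from
zero, so 0.6 mm and 1.2 mm at 6 μm are
*exactly* 100 and 200 tomograms — the acceptance script asserts the
equality. The anatomic landmark (growth plate) is an explicit slice
index supplied by the user or the generator; automatic landmark
detection is out of scope. Centred joint slabs break ties toward the
lower slice index.

Operator-drawn contours are replaced by programmatic geometry: the
cortical shell is, per slice, the set of bone components in contact with
the exterior background (flooded from the slice border), and the
trabecular compartment is the shell's filled interior minus the shell.
A slice where the shell encloses nothing is re-checked after a one-voxel
morphological closing: if the closed shell does enclose an interior, the
shell is reported as "not closed" with the slice index (a ≤ 2-voxel gap
is a data defect worth flagging); if not, the cross-section is treated
as genuinely solid and simply has no marrow. Gaps wider than two voxels
are indistinguishable from open anatomy at this resolution and are
treated as the latter.

## The phantom generator

Phantoms are analytic solids voxelised at voxel centres (no partial
volume), mapped to bone 900 / background 100 mg HA/cm³, with i.i.d.
Gaussian noise (sd 60 mg HA/cm³) added everywhere. These defaults are
plausible murine cortical values that bracket the 500 threshold with
~6–7 noise SDs on either side, so segmentation is discriminative but the
noise is not decorative. Pits are hemispherical indentations centred on
the analytic surface with Poisson-distributed count at a configured
density per mm² — the simplest model of superficial pitting. Generation
is fully deterministic given (spec, seed), and changing the seed changes
only noise and pit placement, never the analytic geometry; each
phantom's ground-truth record carries the closed-form BV, BS, thickness,
marrow volume and the realised pit count.

The composite "tibia" used by `makeStudy` stacks three segments along
the scan axis — a pitted cortical tube (joint), the same tube with an
interior rod lattice (metaphysis; 2-voxel endosteal clearance keeps
shell and trabeculae disconnected), and a plain tube (diaphysis) — with
the growth-plate landmark at the first metaphyseal slice. Group effects
mirror an arthritis treatment study: the diseased group thins the rod
lattice (factor 0.8) and pits the periosteal joint surface
(5 pits/mm²); the treated group keeps the pitting but adds endosteal
apposition, shrinking the shaft marrow volume by a configured 1.6-fold;
controls are unperturbed.

What the phantoms deliberately do **not** emulate: anatomic shape
variation, partial-volume blur at the true scanner PSF, beam hardening,
ring artefacts, spatially correlated noise, and marrow heterogeneity.
Passing the suite therefore demonstrates that the *estimators* are
correct and well-calibrated on known geometry under realistic contrast
and noise — not that any biological effect size in real scans would be
recovered with these error bars.

Default problem sizes are chosen so the whole validation runs at desk
scale: pitted-sphere surface studies use radius 0.45 mm (75 voxels,
~2.5 mm² of surface — large enough that Poisson pit counts separate
adjacent densities of {0, 1, 2, 5, 10}/mm²), the composite tibia is
300 × 128 × 128 voxels, and speckle volumes 128³.

## Statistics

Group comparisons follow the conventions of the field: one-way
fixed-effects ANOVA with Tukey's HSD over all group pairs (studentized
range distribution) for morphometric parameters, two-sided throughout;
Mann-Whitney U for ordinal clinical-score-like data; summaries as
mean ± SD, with SEM reported for score-like measurements. Constant
input (no variance anywhere) returns F = 0, p = 1 by definition.

The Mann-Whitney p-value is exact where feasible: via the null Wilcoxon
distribution for tie-free samples with nA·nB ≤ 400, and by complete
enumeration of group assignments for tied samples when
choose(nA+nB, nA) ≤ 2·10⁵ (full enumeration of tied samples much beyond
that is combinatorially impossible). Otherwise a tie-corrected normal
approximation with continuity correction is used, sharpened by an
Edgeworth kurtosis term (the U null is symmetric but platykurtic,
γ₂ = −(6/5)(m² + n² + mn + m + n)/(mn(N+1))); the tests bound the
exact-vs-asymptotic disagreement at 8 vs 8.

Type-I calibration of the ANOVA layer is checked against the null study
generator at the *measurement level*: with null effect parameters the
generator's groups are exchangeable, so the sampling distribution of any
per-sample readout is a single common distribution, and the calibration
draws measurements directly from it (2000 replicates of 3 × 10) rather
than re-imaging thousands of volumes — p-value calibration depends only
on that exchangeability, not on the imaging chain.

## Pipeline and reproducibility

`runPipeline` runs read → filter → segment → ROI → morphometry →
erosion per sample, continues past per-sample failures (reporting the
sample and stage), and finishes with group statistics. Numeric CSV
output is formatted at a fixed 10 significant digits so identical
configurations reproduce identical bytes; provenance JSON records the
parameter set, package and R versions, and an MD5 hash of every input
volume. All randomness in the generator and the acceptance script
derives from explicit integer seeds.

## Known limitations

* Thickness of thin digital cylinders carries the ~−1 voxel bias
  discussed above; ratios between groups are much more stable than
  absolute values (the thinning-factor recovery in the acceptance script
  is accurate to ~1% while absolute Tb.Th of 10-voxel rods is ~10% low).
* BS on centre-voxelised binary phantoms carries the ~+1.5% roughness
  bias; BS on real grayscale data does not have this term.
* The smoothness estimator's rough limit is degenerate exactly at
  mean-density = threshold (see above).
* MetaImage/NRRD support covers the common raw-encoded little-endian
  subset; compressed encodings and anisotropic grids are rejected, not
  resampled. Proprietary scanner formats and DICOM are out of scope.
* The segmentation is a single global threshold by design; volumes whose
  calibration drifts spatially need correction upstream.
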