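---
title: "Quantifying acute TBI features on head CT: models and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acute TBI features on head CT: models and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tbiq quantifies three clinically decisive features of acute traumatic brain
injury on non-contrast head CT: the volume of acute intracranial lesions
(hyperdense fresh blood: epidural and subdural haematomas, contusions,
intracerebral haemorrhage), the volume of the basal cisterns (whose
compression signals raised intracranial pressure), and the midline shift
(MLS; lateral displacement of the septum pellucidum, with 5 mm a common
surgical decision threshold). This vignette explains each stage's model and
assumptions, the synthetic phantoms the package validates itself against,
the tunable parameters, and the numerical choices that are easy to miss in
the code.

## The pipeline

`run_pipeline()` executes, in order:

1. **Brain extraction.** The reference method is deterministic
   morphology: keep voxels in the soft-tissue/fluid window [-20, 100] HU,
   open with 2 iterations of 6-connected erosion/dilation, keep the largest
   connected component, fill interior holes, and finally re-exclude
   bone-density (> 100 HU) and air (< -200 HU) voxels so that intracranial
   calcifications do not enter the mask. A trainable per-slice 2D U-Net
   extractor (`train_brain_extractor()`, Adadelta, two 3x3 convolutions per
   level, 64 first-level filters by default, doubling per level) is provided
   as the learning-based alternative; tests do not depend on its training
   success.
2. **Resampling and normalization.** The working grid is 1 mm isotropic
   (trilinear for intensities, nearest-neighbour for masks). Intensities
   are rescaled to zero mean, unit standard deviation *strictly inside the
   brain mask* — the only reading consistent with feeding extracted-brain
   images to the downstream models; voxels outside the mask are set to 0.
3. **Affine atlas registration** (below).
4. **EM tissue segmentation** of GM/WM/CSF with warped, relaxed atlas
   priors (below).
5. **Structure localisation**: CSF hard labels intersected with the warped
   binary ventricle/cistern priors, dilated 2 voxels to absorb residual
   registration error.
6. **Cistern segmentation** by constrained morphology, **lesion
   segmentation** by the patch-based 3D U-Net (when a trained model is
   supplied), and **MLS estimation**.

## Synthetic phantoms and the atlas

No suitable public dataset with voxel-level acute-TBI ground truth is
redistributable, so validation runs on synthetic head phantoms
(`generate_phantom()`) with *exact* ground truth. A phantom is built from
ellipsoids on a configurable grid (default 144 x 168 x 128 voxels at 1 mm):
a skull shell at 1000 HU around a cranial cavity; white matter (30 HU) with
a cortical grey-matter shell (40 HU) and a thin subarachnoid CSF rim
(8 HU); paired lateral ventricles with frontal horns plus a midline
septum/third-ventricle slab; basal cisterns as a CSF annulus around a
brainstem cylinder at the skull base, with the annulus radius solved so the
cistern volume hits its target exactly; optional hyperdense lesions
(70 HU) grown voxel-by-voxel around a seed point inside the parenchyma
until the requested volume is met (error if it cannot fit); and i.i.d.
Gaussian noise (default sigma 3 HU, a typical soft-tissue noise level).
Midline shift is induced by translating the ventricles and septum laterally
by a known amount, so the true MLS is exact by construction. A 1-voxel
parasagittal sheet at 60 HU emulates the falx/venous-sinus "false lesion"
for the two-stage network experiments.

The skull also carries the orientation landmarks real heads have — a
frontal sinus (air pocket in the anterior shell), an occipital
protuberance, petrous ridges, and pineal/choroid-plexus calcifications (at
skull attenuation, so a noise-free phantom still takes exactly the five
configured HU values plus background air). These matter: a purely
ellipsoidal head is invariant under the conjugate-orthogonal group of its
own quadratic form, which makes 12-dof registration rotationally
ill-posed — rotation trades off against shear and scale almost exactly.
The landmark structures carry exactly the rotational information the
registration stage needs, as they do in clinical CT.

The atlas bundle (`generate_atlas()`) is built from `n` unshifted,
lesion-free phantoms with ±3% random per-axis anatomical jitter: the
template is the voxelwise mean CT, tissue priors are voxelwise class
frequencies renormalized to sum to one inside the template brain, the
ventricle/cistern priors are majority votes, and the two axial landmark
planes (foramen-of-Monro level, roof of the lateral ventricles) are the
inferior/superior extent of the ventricle prior.

What the phantoms deliberately do **not** emulate: partial-volume averaging
and reconstruction-kernel correlation of CT noise, beam hardening and
streaks, gyral/sulcal cortical folding, anatomical asymmetry beyond the
induced shift, and lesion heterogeneity (mixed-density haematomas). Passing
the phantom suite therefore demonstrates correctness of the algorithms
under their stated assumptions — not clinical-grade performance; the
separation of 8/30/40/70 HU classes under 3 HU noise is easier than real
tissue contrast.

## Affine registration

`register_affine()` estimates a 12-dof world-coordinate affine
(translation, rotation, per-axis scale, shear; centred on the atlas grid
centre) from subject to atlas space. The global stage maximizes normalized
mutual information, NMI = (H(A)+H(B))/H(A,B), from a 32-bin joint
histogram evaluated at template *head* voxels only (air carries no
alignment information and dilutes the score; out-of-field samples are
filled with the air value so the sample domain stays fixed — excluding
them would reward transforms that shrink the overlap). The schedule is:
centre-of-mass initialization; rigid-only Nelder-Mead at 4x downsampling;
deterministic grid probes over rotations (±6°, ±3°) and log-scales (±3%)
that catch gross basin misses a simplex cannot recover from; then
restarted 12-dof Nelder-Mead.

Because both images share the HU scale, the local stage switches to a
least-squares criterion for precision: BFGS with numerical gradients on
sigma-2 mm Gaussian-smoothed intensities at a fixed 50 000-point head
sample, full resolution. Shear is the degenerate direction of the
near-quadric head, so the polish alternates shear-free (9-parameter)
refinement, a short shear-only fit, and a final 9-parameter pass, with a
rotation-nudged multi-start ranked by fine-level residual; a last pass on
the *unsmoothed* images pins the scale to a fraction of a voxel against
the sharp skull/air boundary. If the optimum fails to improve the
fine-level NMI over the identity, the identity is returned with a warning
and `converged = FALSE`.

The stage is affine-only by design; the reference clinical pipeline uses a
nonrigid tool, but affine suffices for phantom-scale geometry and keeps the
stage self-contained.

## EM tissue segmentation and prior relaxation

`segment_tissues_em()` fits a three-class Gaussian mixture with spatially
varying priors: the E-step posterior is proportional to prior times
Gaussian likelihood (computed in the log domain, so exact-zero priors act
as absolute vetoes and numerical underflow cannot occur), and the M-step
re-estimates class means and variances from the posteriors; spatial priors
are fixed, so the EM log-likelihood is non-decreasing — asserted in the
tests. Means and variances are initialized from prior-weighted statistics;
iteration stops below a relative log-likelihood change of 1e-5 or at 50
iterations; variances are floored at 1e-8 (normalized units squared, i.e.
noise-free phantoms) and flagged. Hard labels are the posterior argmax with
ties to the lowest class index (GM < WM < CSF).

An exact-zero atlas prior vetoes intensity evidence. That is the correct
semantics for the function, but wrong for pathology: a midline shift moves
ventricular CSF outside the atlas CSF support, where a zero prior would
force tissue labels regardless of intensity. The pipeline therefore relaxes
warped priors before EM (`relax_priors()`): Gaussian smoothing at sigma
3 mm plus a uniform mixture floor epsilon = 0.1, renormalized inside the
mask. With phantom class separations the intensity likelihood then
dominates wherever the displaced anatomy lands.

## Cistern segmentation

From the located candidates, `segment_cisterns()` applies (1) constrained
dilation — k = 3 iterations of 1-voxel dilation accepted only where the
CSF posterior is at least p_csf = 0.5; (2) smoothing — morphological
closing, Gaussian smoothing of the indicator at sigma 1 voxel,
re-threshold at 0.5; (3) nonoverlap — voxels claimed by the ventricle mask
are removed. The clinical description names these operations without
parameter values; the defaults here were fixed from the phantom geometry
(the dilation must recover cisterns a few millimetres larger than the
atlas prior; the smoothing scale matches the 1-2 voxel surface roughness
EM leaves) and are all configurable. "Nonoverlap at the cistern border" is
read as exclusion against the ventricle mask — the only adjacent CSF
structure this pipeline segments. Empty candidates return volume 0 without
error (clinically: obliterated cisterns).

## Lesion segmentation: patch-based 3D U-Net

The network (`unet_config()`, `build` via `unet_init()`) is the
valid-convolution volumetric U-Net: per resolution level two unpadded
3x3x3 convolutions with ReLU, 2x2x2 max pooling on the contracting path
and 2x2x2 nearest-neighbour upsampling on the expanding path, shortcut
crop-and-concatenate connections at equal resolution, a final 1x1x1
convolution and softmax. First-level filter counts are (32, 64), doubling
per level; four levels; a 132-voxel input patch maps to a 44-voxel output
patch (`shape_trace()` computes this arithmetic per axis and rejects sizes
that go non-positive or odd before pooling, naming the failing level).
Training uses Adam (learning rate 1e-5, decay 0 by default), categorical
cross entropy, batch size one, and augmentation by random flips,
translations (<= 10 voxels, mirror-filled), in-plane rotations (<= 10°)
and Gaussian noise (sigma 0.1 normalized units) — image and label patches
share the geometric transform, labels resampled nearest-neighbour.

Training is two-stage. Stage 1 separates lesion from background. The
false-lesion mask — stage-1 prediction minus ground truth, disjoint from
the truth by construction and asserted — then becomes a third class, and
stage 2 retrains with stage-1 weights warm-started; the final layer is
re-shaped for three classes, carrying over the trained background and
lesion columns so the calibrated lesion logit survives the retraining
(a fully fresh final layer must re-learn its scale, which a short
retraining cannot reliably do). This forces the network to discriminate true
lesions from lesion-like structures (falx, venous sinus). At inference
only the lesion-class probability is used, thresholded at 0.7 (the
operating point of the clinical method), over a non-overlapping
valid-convolution tiling: output tiles at stride equal to the output patch
size, inputs mirror-padded, so every brain voxel is predicted exactly
once (asserted by a coverage counter).

Patch sampling draws, per case per epoch, `patches_per_case` patches
centred on a random lesion voxel with probability `lesion_patch_prob`
(default 0.5) and uniformly inside the brain otherwise (stage 2 adds
false-lesion-centred patches). The final classification layer's bias is
initialized at the log class frequencies inside the brain, so early
optimization does not spend its budget re-learning the class prior —
with a one-voxel-in-fifty lesion fraction and batch size one, a
zero-initialized bias leaves the network in a background-prior plateau for
over a hundred steps.

The implementation is R with a float-native compiled core: the whole
forward/backward state lives in single precision on the C++ side (handed
to R as an external pointer), and the convolution is expressed as one
accumulating `sgemm` per kernel offset on row-shifted views of the flat
feature matrix, blocked along z so the accumulator stays cache-resident —
on memory-bandwidth-limited hardware several times faster than an im2col
formulation. Backward passes are verified against finite differences in
the tests; single precision bounds the attainable agreement at about 1e-3
relative. The reference 132³/depth-4 configuration is constructed and
shape-checked; training in the test suite runs a reduced desk-scale
configuration: input patch 60³, depth 2, filters (8, 16) with the
`"light"` synthesis option, learning rate 1e-3, 30 epochs of 2 patches
per case, all patches lesion-centred, one training and two held-out
phantoms at 2.5 mm (25 mL lesion, noise sigma 5 HU — at that noise the
60 HU falx decoy genuinely overlaps the lesion intensity distribution, so
stage 1 produces the false positives stage 2 is designed to remove; at
the default sigma 3 the decoy is separable by intensity alone and the
two-stage comparison degenerates).

## Midline shift

`estimate_mls()` works on the landmark-bounded axial range: the atlas
planes at the foramen of Monro and the roof of the lateral ventricles are
mapped through the inverse subject-to-atlas transform (error if the order
collapses). On each slice, `measure_slice_shift()` computes B, the maximal
left-right inner-skull width, and C, the distance from the inner table to
the middle of the frontal part of the ventricles along the same left-right
line — B and C share their starting x-coordinate, taken on the side
opposite the shift, as in the manual reading protocol; the slice shift is
|B/2 - C|, and the patient-level MLS is the maximum over measurable slices
(ties to the most inferior slice; slices without ventricle voxels return a
"not measurable" sentinel; if no slice is measurable the function errors
rather than guessing — fully effaced ventricles defeat any
ventricle-landmark method). "Middle of the frontal part" is
operationalized as the midpoint of the centroids of the left and right
anterior-third ventricle components on the slice (centroid of the anterior
third of a single merged component) — the septum pellucidum itself is not
separately segmented, and the frontal-horn centroid midpoint is its
geometric proxy. Measurements are taken at 1 mm isotropic resolution,
in millimetres; centroids are sub-voxel.

One parameter deserves emphasis: the ventricle mask used for the MLS
measurement is re-located with the binary ventricle prior dilated by 15 mm
(`mls_prior_dilation_mm`), not the 2-voxel relaxation used for reporting
ventricle candidates. A 2-voxel dilation cannot contain a ventricle
displaced 12 mm from the atlas position; 15 mm covers the clinically
reported shift range with margin while staying far from other CSF spaces
in this geometry.

## Agreement metrics

`overlap_metrics()` implements Dice = 2TP/(2TP+FP+FN), sensitivity =
TP/(TP+FN), precision = TP/(TP+FP). Empty-mask conventions (the source
description is silent): both masks empty is perfect agreement (all three
equal 1); an empty reference with a non-empty prediction gives sensitivity
NaN, precision 0, Dice 0, and symmetrically. `volume_agreement()` reports
reference-minus-prediction in mL, so positive means undersegmentation.
`icc_absolute()` is the two-way, single-rater, absolute-agreement
intraclass correlation ICC(2,1) from the mean-squares decomposition,
tested to 1e-10 against an independent ANOVA-table oracle.
`classification_accuracy()` binarizes both series at a cutoff (25 mL for
lesions, 5 mm for MLS); values exactly at the cutoff go to the low class
(the clinical definitions use strict inequalities only); Cohen's kappa is
NaN with a warning when the 2x2 table degenerates. Cohort summaries use
median and 25th-75th percentiles (linear-interpolation quantiles), with
cistern overlap statistics additionally stratified to reference volumes
above 5 mL, where Dice is not dominated by small-structure sensitivity.

## Problem sizes and determinism

All randomness flows through per-call seeds with save/restore of the
caller's RNG state; identical spec and seed give bit-identical phantoms,
training runs and pipeline reports. The validation suite uses: full-scale
(1 mm) phantoms for the registration-recovery and symmetry checks; 2 mm
phantoms of identical geometry for pipeline-level cohorts (20 cases for
MLS recovery, 10 for cistern recovery), processed at their native
resolution — the midline measurement takes sub-voxel ventricle centroids,
so 2 mm sampling still recovers induced shifts to a few tenths of a
millimetre, and upsampling masks by nearest neighbour would only add
interpolation artefacts; 2.5 mm phantoms for network training; 4 mm
phantoms for the 2D extractor. These sizes keep the suite to a single-CPU
run of modest length while leaving every accuracy criterion meaningful at
its native tolerance.

## Known limitations

- The phantom's tissue contrast and noise are kinder than clinical CT;
  accuracy numbers on phantoms bound the algorithmic, not clinical, error.
- Registration assumes the full head (skull included) is present and
  approximately atlas-like; it is affine-only.
- The EM stage models three tissue classes; lesions are not a mixture
  component and rely on the brain mask and the lesion network.
- Lesion subtype classification, edema, and traumatic subarachnoid
  haemorrhage are out of scope.
- The MLS method requires visible ventricles in the landmark range and
  errors on fully effaced ventricles.
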