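# tbiq — quantification of acute traumatic brain injury on head CT

After traumatic brain injury, three numbers on the non-contrast head CT
drive management: the volume of acute intracranial lesions (fresh
hyperdense blood — epidural/subdural haematoma, contusion, intracerebral
haemorrhage), the volume of the basal cisterns (compression signals raised
intracranial pressure), and the midline shift (MLS; displacement of the
septum pellucidum, with >5 mm a surgical decision threshold). Reading them
by hand is slow and observer-dependent. `tbiq` is an R implementation of a
fully automated pipeline that computes all three, plus the synthetic
phantoms and agreement statistics needed to validate every stage against
exact ground truth. It is aimed at researchers in medical image analysis
who want a self-contained, dependency-light reference implementation they
can take apart.

The pipeline: brain extraction (deterministic morphology, or a trainable
per-slice 2D U-Net) → resampling to 1 mm and zero-mean/unit-variance
normalization inside the brain → 12-dof affine registration to a synthetic
CT atlas (normalized mutual information global search, least-squares
polish) → expectation–maximization tissue segmentation with warped,
relaxed atlas priors (posterior ∝ prior × Gaussian likelihood) → basal
cistern segmentation by constrained dilation, smoothing and
ventricle-nonoverlap → acute lesion segmentation with a patch-based
valid-convolution 3D U-Net (two 3×3×3 convolutions per level, 2×2×2
pooling; a 132³ input patch yields a 44³ output patch) trained in two
stages, the second adding the stage-1 false positives as an explicit
"false lesion" class; lesion probability thresholded at 0.7 → geometric
MLS over the slice range between the foramen of Monro and the ventricle
roof, per slice **|B̄/2 − C̄|** where B̄ is the maximal inner-skull width
and C̄ the distance from the inner table to the middle of the frontal
ventricles on the same line; the patient MLS is the per-slice maximum.

Agreement statistics follow the clinical validation conventions: volume
difference (reference − prediction, positive = undersegmentation), Dice =
2TP/(2TP+FP+FN), precision, sensitivity, absolute-agreement intraclass
correlation ICC(2,1), and cutoff classification accuracy (25 mL largest
lesion, 5 mm shift) with Cohen's kappa.

The 3D/2D U-Nets, their optimizers (Adam, Adadelta) and backpropagation
are implemented in the package itself with compiled single-precision
kernels (one accumulating BLAS `sgemm` per kernel offset on row-shifted
views of the flat feature matrix), so the whole method trains and runs on
a plain CPU.

## A worked example

```r
library(tbiq)

atlas <- generate_atlas(phantom_spec(), n_subjects = 8, seed = 42)
case  <- generate_phantom(phantom_spec(induced_shift = 6, seed = 7))
print(case)
#> <phantom_case> 144x168x128 voxels, true MLS 6.00 mm, lesions 0.00 mL, cisterns 10.06 mL

report <- run_pipeline(case$ct, atlas)
print(report)
#> <case_report>
#>   cistern volume:      9.87 mL
#>   midline shift:       6.00 mm
```

The phantom was built with a 6 mm lateral displacement of the ventricles
and a ~10 mL cistern system; the pipeline — which never sees the ground
truth — recovers the shift to within a fraction of a millimetre and the
cistern volume to within a few percent (`report$mls_per_slice` holds the
per-slice B̄, C̄ and shift values; `report$intermediates` the masks).
Phantoms, atlases, masks and reports can be written to NIfTI-1 + JSON via
`write_phantom_case()`, `write_atlas()` and the `out_dir` argument of
`run_pipeline()`; `inst/cli/tbiq` wraps the same functions for shell use.

See the vignette (`vignettes/tbiq-methods.Rmd`) for the models,
assumptions, parameter choices and limitations, and `evaluate_cohort()`
for cohort-level agreement reports.

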