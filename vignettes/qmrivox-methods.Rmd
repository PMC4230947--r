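---
title: "Voxel-based quantitative MRI group analysis with qmrivox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based quantitative MRI group analysis with qmrivox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative MRI (qMRI) maps the physical tissue parameters behind MR
contrast on an absolute scale: the longitudinal relaxation rate R1 = 1/T1
(s^-1^), the transversal relaxation rate R2 = 1/T2 (s^-1^), and the proton
density PD (% of pure water at 37&nbsp;°C). Because the scale is absolute,
maps can be compared voxel by voxel across subjects after spatial
normalization. In demyelinating disease the expected pattern is lower R1
and R2 and higher PD in affected white matter, both in focal lesions and as
diffuse change in normal-appearing white matter (NAWM).

`qmrivox` implements a complete desk-scale replica of this analysis:
cohort simulation with known ground truth, map estimation from the raw
multi-delay multi-echo acquisition, tissue segmentation and volumetry,
affine normalization, voxel-wise statistics with permutation-based
family-wise-error (FWE) control, multi-parametric difference histograms,
and region-of-interest (ROI) erosion analysis.

## Signal model and map fitting

The acquisition is a saturation-recovery multi-echo spin-echo scheme: 4
saturation delays (100, 400, 1380, 2860 ms; TR 2950 ms) crossed with 5
echo times (14–70 ms), i.e. 20 images per slice. The forward model is the
product of mono-exponential recovery and decay,

$$S(\tau, T_E) = g \cdot PD \cdot (1 - e^{-\tau R_1})\, e^{-T_E R_2},$$

with perfect saturation efficiency and no multi-compartment terms (only
the dominant R1 and R2 components are modelled). `fit_parameter_maps()`
inverts it per voxel with a two-stage initialiser — log-linear regression
over echoes per delay gives R2 and the echo-extrapolated amplitudes; a
monotone bisection on the first-to-last amplitude ratio gives R1 — then a
vectorised Levenberg–Marquardt refinement of (amplitude, R1, R2) jointly.

Numerical choices worth knowing:

* Voxels whose peak intensity is below 5 % of the stack maximum are
  treated as background and excluded.
* R1 is bounded below at 0.05 s^-1^. At these delays the longest recovery
  window (2860 ms) captures only about half of the CSF recovery, so for
  very small R1 the amplitude and R1 trade off almost freely and the
  fitted amplitude can diverge. The bound, together with a robust CSF
  reference, keeps the PD calibration stable.
* PD calibration: the fitted amplitude equals gain × PD. When a pure-CSF
  reference mask is supplied, PD is re-expressed as % of the median CSF
  amplitude (100 % = pure water), after excluding reference voxels whose
  fitted recovery at the longest delay is under 35 % — below that the
  amplitude is weakly identified and biased high. The pipeline uses each
  subject's ventricle mask eroded by 2 mm — the full mask would deflate
  the reference through partial-volume voxels, and by different amounts in
  atrophic and non-atrophic subjects.
* Simulation adds Gaussian noise on magnitude signals (Rician effects are
  negligible at the simulated SNR), with σ expressed as a fraction of the
  maximum noiseless signal (default 2 %).

## The digital phantom

`build_template()` constructs a simplified head: an intracranial ellipsoid
(semi-axes 48 × 59 × 42 mm) with a 2 mm subarachnoid CSF rim, an 8 mm
cortical grey-matter band, two deep grey nuclei, two lateral ventricles
(~1 % of the intracranial volume, matching a healthy ventricular
fraction), and white matter filling the interior, on a 64 × 64 × 48 grid
of 2 mm voxels. Partial volume at interfaces comes from 2× supersampling;
the ventricles use an analytic radial field so their volume can be
re-scaled per subject without rebuilding the template. Named ROI masks
(ventricles, periventricular WM, a corpus-callosum-like slab, deep GM,
cortical band, whole WM, frontal WM) and all per-subject ground truth
(class fractions, lesion masks, applied affines) are emitted so every
downstream stage has an oracle.

Subject sampling (`sample_subject_maps()`) draws per-class subject means
from between-subject Gaussians and adds per-voxel Gaussian texture; voxel
values are fraction-weighted mixtures of the class fields. The class means
are the reference-group white matter (1.20 s^-1^, 11.1 s^-1^, 74 %),
cortical GM (1.02, 10.0, 75) and pure-CSF-like values (0.25, 1.5, 100 %).
Patients additionally receive

* a diffuse NAWM shift of (−0.13 s^-1^, −0.9 s^-1^, +3 %) — the
  whole-WM patient-minus-reference difference — scaled inside
  frontal-labelled WM by EDSS/3.7 so that disability has a spatially
  specific imaging correlate;
* a grey-matter shift of (−0.10, −0.9, +2), the cortical-GM group
  difference, so grey-matter ROIs also carry a group effect;
* spherical lesions (Poisson count, mean 6; radii 2.5–5 mm; 80 %
  placed in the periventricular shell) whose parameters are pulled halfway
  towards CSF values;
* ventricles dilated 2.5× in volume, taking the ventricular fraction from
  ~1 % to ~2.5 %.

Two deliberate deviations from the printed summary tables:

* The per-voxel texture SDs (e.g. 0.15 s^-1^ for WM R1) are set *below*
  the printed within-ROI SDs (0.41). The printed values are observations
  pooled over subjects and contaminated by partial volume and lesions —
  the erosion analysis in this very package demonstrates that
  contamination. Used directly as pure-tissue texture they would make the
  three classes essentially inseparable in (R1, R2, PD) space, which
  contradicts the working range-based segmentation the analysis assumes.
* Atrophy is modelled as ventricular dilation only. The published
  brain-parenchymal-fraction gap (89.9 vs 82.1 %) also reflects global
  parenchymal loss that the phantom does not model; the phantom's BPF
  contrast is therefore smaller but in the same direction.

What passing tests on this phantom do **not** show: realistic cortical
folding, B0/B1 artifacts, multi-exponential relaxation, nonlinear
anatomical variability. Conclusions about real data rest on the pipeline's
correctness, not on the phantom's realism.

## Segmentation and volumetry

`classify_tissue()` implements range-based partial-volume classification.
Each class has a centre and per-parameter acceptance radii (defaults are
the cropped-ROI values for WM (1.35, 11.7, 71), cortical GM
(1.01, 10.0, 77) and ventricular CSF (0.29, 3.4, 96), the least
partial-volume-contaminated printed values). A voxel inside exactly one
acceptance box is pure; all other voxels are mixed between their two
nearest classes with weights ∝ 1/d, where d is the radius-normalised
distance — two-class mixing matches physical partial volume at tissue
interfaces. Voxels further than 6 normalised units from every class are
non-brain (background sits beyond 10 on every class; tissue voxels rarely
pass 5 even at full texture). The GM radii are deliberately tight so that the WM tissue point
lies in the WM box only and the WM–CSF midpoint mixes WM with CSF rather
than GM.

`compute_volumes()` sums fractions × voxel volume inside the largest
6-connected component (conservative bridge suppression) of the
brain-dominant and intracranial-dominant voxels; the ventricular volume is
the CSF fraction inside a ventricle mask — ground truth for the phantom, a
user-supplied mask for real data. BPF and ventricular fraction are the
percentage ratios to intracranial volume.

## Normalization

Registration sources are synthetic T2-weighted images
(`synthesize_contrast_image()`, TE 100 ms / TR 4500 ms) smoothed with an
8 mm FWHM Gaussian; both sides are divided by their mean object intensity
because the mean-squared-difference cost is not invariant to the
per-subject PD calibration scale. `estimate_affine()` optimises the 12
affine parameters (translation, rotation, zoom, shear) over a 3-level
image pyramid with BFGS, a rigid-only first pass at the coarsest level,
and a small quadratic penalty on zooms and shears (2 % of the initial
cost). The penalty matters: a smoothed, quasi-ellipsoidal head makes
rotation and shear nearly interchangeable, and unregularised fits can land
in wrong-rotation local minima. The finest level evaluates the cost on an
informative-voxel subsample (object voxels plus a sparse background
lattice, stride 3), which keeps a 38-subject run in minutes without
measurable accuracy loss. Maps are re-gridded to the 2 mm isotropic target
with trilinear interpolation; masks nearest-neighbour, so they stay crisp.
Nonlinear warping is deliberately out of scope — the phantom's
misalignment model is affine, so the pipeline is internally consistent.

On the default cohort the ventricle-mask Dice after normalization averages
≈ 0.93 for reference subjects. Patient ventricles are 2.5× dilated and
cannot fully overlap the reference template under any affine map, so the
registration QC averages reference subjects only — the same limitation the
original normalization reported for atrophic brains.

## Voxel statistics

`glm_group_contrast()` fits y = β0 + β1·group + β2·age per voxel
(group coded reference = 1, so positive T means reference > patient;
df = n − 3; age mean-centred). `edss_slope_map()` fits
y = β0 + β1·EDSS + β2·age over patients and returns the slope per EDSS
point and its T. Family-wise error over ROIs uses max-T permutation of the
group labels (age stays with its subject) with a Bonferroni factor for the
number of ROIs — a deliberate, assumption-free substitution for
random-field theory; with 4+4 subjects or fewer distinct relabellings than
requested permutations the enumeration is exhaustive. Directional
one-sided tests follow the expected disease directions (R1, R2 lower, PD
higher in patients); a two-sided mode exists. `map_regression()` regresses
raw slope-map values on raw T-map values over all in-mask voxels — the
published slope ≈ 0.5 at R² ≈ 0.5 is only consistent with unstandardised
values.

## Multi-parametric histograms

`difference_histogram()` pools voxels of each group into a 2-D histogram
over a parameter pair, divides by the group's subject count (a no-op for
19 vs 19, but it keeps unequal cohorts comparable) and subtracts: positive
mass = reference excess (blue), negative = patient excess (red). Default
display windows are R1 0–3 s^-1^, R2 0–15 s^-1^, PD 50–100 % with 200
bins whole-brain and 50 bins for ROI views (ranges from the pooled 1st–99th
percentiles). The 10 % inclusion rule is applied to the reference-group
mean PD map — the acquisition-derived intensity proxy available after
normalization; the source text does not name the image, so this is an
interpretation, recorded here. ROI markers are pooled group means on
2 mm-eroded ROIs, with arrows from reference to patient.

## ROI erosion and mixed models

`distance_from_surface()` is an exact separable Euclidean distance
transform (anisotropic spacings supported); distances are measured between
voxel centres, so on the 2 mm grid a surface voxel is at 2 mm and
`erode_roi(mask, 2)` strips exactly the one-voxel shell — the strict
`> level` rule makes the 0/2/4/6/8 mm ladder nested. Whether the original
procedure used Euclidean or city-block distance is not stated; Euclidean
is chosen and tested against an exhaustive oracle, not claimed identical.

`mixed_model_group_test()` fits y_sv = β0 + β1·group + b_s + ε with a
random subject intercept over all ROI voxels. On balanced data (equal
voxel counts — always true on the common grid) the REML solution is the
two-sample analysis of subject means, computed in closed form; unbalanced
data go through iterative REML (lme4), and the two agree to 10^-6 on
balanced inputs by test. Zero between-subject variance is flagged and
falls back to the subject-means t test. Voxel-level observations enter
without spatial correlation modelling, mirroring the stated model.

## Pipeline, determinism and problem sizes

`run_pipeline()` sequences simulate → fit → segment → normalize → stats →
hist → roi with explicit dependency checks; every random stage derives its
seed from the single master seed, so a fixed-seed run is bit-identical.
Stage re-runs are cheap at desk scale, so no output caching layer is
maintained — determinism plus re-execution replaces content addressing.
The default problem sizes were chosen for interactive use: the full
19 + 19 cohort at 64 × 64 × 48 × 2 mm completes in roughly ten minutes on
one core; unit tests use the same anatomy at 4 mm (34 × 36 × 28) and the
law-of-large-numbers check uses 6 mm voxels with 200 subjects per group.
`scripts/acceptance.R` re-runs the full-size default cohort.

## Known limitations

* Affine-only normalization: residual shape differences (especially
  dilated ventricles) remain; CSF-adjacent ROIs inherit partial-volume
  bias, which is exactly what the erosion analysis quantifies.
* The range-based segmentation under-estimates parenchyma near interfaces
  (two-class 1/d mixing leaks a few percent of brain fraction into
  neighbouring classes), so absolute BPF runs below the published values;
  group contrasts are unaffected in direction.
* The vendor fit's loss function and saturation-efficiency handling are
  not public; equivalence with vendor output is not claimed — only the
  model-based recovery properties tested here.
* EDSS enters the phantom as a linear modifier of frontal NAWM change;
  real disability–imaging coupling is far less tidy, so slope-map
  magnitudes are not comparable to patient data.
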