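# qmrivox

Voxel-based group analysis of quantitative MRI (qMRI) brain maps in R.

Quantitative MRI measures, in every voxel and on an absolute scale, the
tissue parameters behind MR contrast: the longitudinal relaxation rate
R1 = 1/T1 (s⁻¹), the transversal relaxation rate R2 = 1/T2 (s⁻¹) and the
proton density PD (% of pure water at 37 °C). Because the scale is
absolute, maps from different subjects can be compared voxel by voxel
after spatial normalization — the basis for detecting both focal lesions
and diffuse tissue change (for example in multiple sclerosis, where
affected white matter shows lower R1 and R2 and higher PD).

`qmrivox` is for methodologists and imaging scientists who want a fully
inspectable, desk-scale implementation of that analysis chain with a
simulation framework around it:

* **Digital brain phantom** — two-group cohorts (healthy reference vs.
  MS-like patients) with ground-truth tissue fractions, periventricular
  lesions, diffuse normal-appearing-white-matter change, ventricular
  enlargement, acquisition noise and per-subject misalignment
  (`phantom_spec()`, `build_template()`, `generate_cohort()`).
* **Relaxometry** — forward signal model for a 4-delay × 5-echo
  saturation-recovery acquisition, `S = g·PD·(1−e^{−τR1})·e^{−TE·R2}`,
  per-voxel nonlinear least-squares map fitting, and synthetic
  contrast-weighted image reconstruction (`predict_signal()`,
  `fit_parameter_maps()`, `synthesize_contrast_image()`).
* **Segmentation & volumetry** — range-based partial-volume WM/GM/CSF
  classification in (R1, R2, PD) space, brain parenchymal fraction
  (BPF) and ventricular fraction (`classify_tissue()`,
  `compute_volumes()`).
* **Normalization** — 8 mm Gaussian smoothing, 12-parameter affine
  registration on synthetic T2-weighted images, re-gridding to a common
  2 mm isotropic grid (`smooth_gaussian()`, `estimate_affine()`,
  `apply_and_regrid()`).
* **Voxel statistics** — two-sample T maps controlling for age, EDSS
  (disability) slope maps with age as nuisance, permutation max-T
  family-wise-error small-volume correction, T-vs-slope map regression
  (`glm_group_contrast()`, `edss_slope_map()`, `permutation_fwe_svc()`,
  `map_regression()`).
* **Multi-parametric histograms** — signed 2-D voxel-count differences
  between groups over (R1,R2), (R1,PD), (R2,PD) with ROI mean markers
  (`difference_histogram()`, `roi_markers()`, `plot_diff_histogram()`).
* **ROI erosion analysis** — exact Euclidean distance transforms, erosion
  in 2 mm steps, per-level summaries and mixed-model group tests with
  subjects as random samples (`erode_roi()`, `roi_summary()`,
  `mixed_model_group_test()`).

Everything is orchestrated by `run_pipeline()`; a thin command-line
wrapper lives at `inst/cli/qmrivox`.

## Worked example

A reduced cohort (4 + 4 subjects on a 4 mm grid) runs in under a minute:

```r
library(qmrivox)

spec <- phantom_spec(grid_shape = c(34, 36, 28), voxel_size = 4)
cfg  <- run_config(spec = spec, n_ref = 4, n_pat = 4, seed = 2,
                   n_perm = 100)
rep  <- run_pipeline(cfg)
print(rep)
#> pipeline_report; stages: simulate, fit, segment, normalize, stats, hist, roi
#>   mean registration Dice: 0.723
#>       group  bpf_pct   vf_pct
#> 1   patient 58.89253 1.449619
#> 2 reference 61.19252 0.637407
```

The patient group loses brain parenchymal fraction and gains roughly a
ventricular-fraction point, as it should with lesions and 2.5×-dilated
ventricles (absolute BPF and the ventricle-overlap Dice are depressed by
the deliberately coarse 4 mm demo grid; at the default 2 mm resolution
the reference-group Dice is ≈ 0.93 and the BPF gap widens to ≈ 9
points). The small-volume-corrected permutation test flags every
white-matter family ROI — `p_fwe_bonf` is 4/70, the smallest value
attainable with 70 exhaustive relabellings and 4 regions:

```r
rep$svc[rep$svc$param == "R1", c("roi", "max_t", "p_fwe_bonf")]
#>                  roi    max_t p_fwe_bonf
#> 1       white_matter 67.04831 0.05714286
#> 2         frontal_wm 43.23925 0.05714286
#> 3 periventricular_wm 43.23925 0.05714286
#> 4    corpus_callosum 24.07538 0.05714286
```

Difference histograms visualize where in parameter space the patient
voxels went (blue = reference excess, red = patient excess):

```r
ref_ids <- rep$cohort$subjects$id[rep$cohort$subjects$group == "reference"]
pat_ids <- rep$cohort$subjects$id[rep$cohort$subjects$group == "patient"]
dh <- difference_histogram(rep$normalized[ref_ids],
                           rep$normalized[pat_ids],
                           pair = c("R1", "R2"), bins = 200,
                           threshold_frac = 0.10)
plot_diff_histogram(dh, rep$roi_markers)
```

At full scale (19 + 19 subjects, 64 × 64 × 48 voxels at 2 mm — the
default `run_config()`) the pipeline takes roughly ten minutes on one
core and reproduces the expected pattern: positive group T values for R1
and R2 in white matter (patients lower), negative for PD (patients
higher), ventricular-fraction difference of about 1 percentage point,
erosion-driven purification of CSF-adjacent ROIs, and significant
mixed-model group effects in every ROI.

## Testing

```r
devtools::test()        # or: testthat::test_dir("tests/testthat")
```

The suite covers every module with oracle-backed tests (exhaustive
distance-transform and histogram enumeration, closed-form GLM and
mixed-model references, grid-search fit recovery) plus an end-to-end
acceptance file that re-runs the default cohort.

## Limitations

Normalization is affine-only (no nonlinear warps); segmentation is
range-based with two-class partial-volume mixing, so absolute BPF runs
below atlas-based values; the phantom's anatomy is simplified (ellipsoidal
head, no cortical folding). See the methods vignette
(`vignettes/qmrivox-methods.Rmd`) for the full model description and the
reasoning behind every default.
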