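# cinelv

Quantification and evaluation tools for left-ventricular (LV) analysis of
short-axis cine cardiac MR, built around the comparison of two endocardial
contouring conventions:

- **rounded** segmentation — a smooth contour approximating the compacted
  myocardial border, with papillary muscles and trabeculae counted as blood
  pool;
- **trabecular** segmentation — papillary muscles and trabeculae assigned to
  myocardium, coupled through the rounded stage so that, pixel by pixel,
  trabecular blood ⊆ rounded blood and trabecular myocardium ⊇ rounded
  myocardium.

Because the choice of convention systematically shifts every clinical metric
(EDV, ESV, SV, EF, LV mass and their BSA-indexed forms), the package provides
the full chain needed to measure those shifts and decide whether they matter:

1. **Synthetic phantom generator** — a thick-walled truncated-ellipsoid LV
   with sinusoidal endocardial ridges (trabeculae), papillary cylinders, a
   tilted mitral annular plane, cine contraction, scan–rescan repositioning
   jitter, and ground-truth volumes for *both* conventions computed by fine
   voxelization. Writes/reads NIfTI with patient-space affines plus JSON
   landmark sidecars.
2. **Plane geometry** — plane intersections, the spatial-normalization
   transform (intersection point of the short-axis/2-chamber/4-chamber views
   at the image centre, 1 mm pixels, 2-chamber line along the y-axis), and
   least-squares mitral-plane fitting from long-axis landmarks.
3. **Deterministic segmenters** — an Otsu-based rounded segmenter
   (grayscale smoothing, largest central component, convex-deficiency fill
   toward the cavity centroid) and the coupled trabecular relabelling on the
   80×80 myocardial crop.
4. **Volumetry** — Simpson summation with *column-wise partial inclusion* of
   basal voxels at the mitral annular plane:
   `V = Σ area × slab × clip_fraction`, EF = 100·(EDV−ESV)/EDV,
   LVM = 1.05 g/mL × myocardial volume at ED, Mosteller BSA indexing.
5. **Precision statistics** — RMS coefficient of variation with a 10,000-
   sample bootstrap, SEM from paired differences, MDC = 1.96·√2·SEM,
   ICC(2,1), CoV contrasts with Bonferroni correction, weighted Cohen's κ,
   Bland–Altman, mean ± 2 SD reference intervals, and paired-test /
   relative sample-size calculators.
6. **Prognosis** — univariable Cox proportional-hazards fits (Breslow ties,
   via the survival package) with LR χ², AIC (Δ > 4 rule), Harrell's
   C-index (Δ ≥ 0.05 rule, bootstrap p), the global Schoenfeld test, and
   EF < 35% / < 50% reclassification counts.

## Worked example

```r
library(cinelv)

spec <- phantom_spec(truth_res_mm = 0.5)   # healthy-sized trabeculated LV
phantom <- make_phantom(spec, seed = 7)
analysis <- analyze_study(phantom)
analysis
#> LV quantification
#>      method EDV_ml ESV_ml SV_ml EF_pct LVM_g
#>     rounded 104.16  36.49 67.66  64.96 100.9
#>  trabecular  91.16  28.92 62.24  68.28 114.5

as.data.frame(phantom$truth)[, 3:4]
#>   cavity_volume_rounded_ml cavity_volume_trabecular_ml
#> 1                 104.5445                    91.48925
#> 2                  37.5830                    28.56363
```

The rounded end-diastolic volume (104.2 mL) recovers the voxelized ground
truth (104.5 mL) to well within 3%, and the trabecular EDV (91.2 mL)
matches its own truth (91.5 mL); the trabecular convention yields a smaller
blood pool, heavier myocardium, and an EF about 3 points higher — the
systematic offsets the evaluation statistics are designed to quantify.

```r
# precision of one metric across simulated rescan pairs
pairs <- replicate(20, {
  pr <- make_rescan_pair(spec, seed = sample.int(1e6, 1), compute_truth = FALSE)
  c(analyze_study(pr$scan1)$metrics$EDV_ml[1],
    analyze_study(pr$scan2)$metrics$EDV_ml[1])
})
cov_rms(pairs[1, ], pairs[2, ], n_boot = 10000, seed = 1)
```

`run_pipeline(pipeline_config(...))` orchestrates the full evaluation
(cohort metrics, Bland–Altman and EF reclassification, rescan precision,
simulated two-observer error audit with κ, and the simulated survival-cohort
Cox comparison) and writes CSV outputs stamped with the config hash and
seed.

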