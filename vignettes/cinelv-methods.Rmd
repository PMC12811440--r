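---
title: "Methods: phantom model, segmentation conventions, and evaluation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom model, segmentation conventions, and evaluation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

cinelv quantifies left-ventricular structure and function from short-axis
cine cardiac MR and compares two endocardial contouring conventions —
*rounded* (papillary muscles and trabeculae counted as blood) and
*trabecular* (those structures counted as myocardium). Because no public
imaging cohort accompanies this problem, the package is built around a
synthetic phantom whose ground truth is known for both conventions; every
downstream stage (geometry, segmentation, volumetry, precision statistics,
prognosis models) is exercised and validated against that truth or against
closed-form/brute-force oracles.

# The phantom

## Anatomy model

The LV is modelled in its own frame (millimetres; +z from apex to base) as a
thick-walled shell:

- **Epicardium**: a half-ellipsoid with semi-axes $(a, a, c)$ for $z < 0$
  continued as a cylinder of radius $a$ for $z \ge 0$. Defaults
  $a = 33$ mm, $c = 55$ mm. The cylinder–ellipsoid join is $C^1$.
- **Rounded endocardium**: the same construction with radius $a - w$ and
  apical half-length $c - w$, where $w = 8$ mm is the wall thickness,
  scaled radially by the phase-dependent cavity scale $s_p$.
- **Trabeculae**: sinusoidal radial ridges of the endocardial surface,
  $r_\text{trab}(\theta) = \max\!\big(s_p (a-w) - A\,\tfrac{1+\sin k\theta}{2},\,0\big)$,
  with ridge depth $A = 2.2$ mm and count $k = 16$ by default.
- **Papillary muscles**: two cylinders (radius 4 mm, azimuths 100° and
  260°) whose centres ride at $0.5\,s_p(a-w)$ so they stay inside the
  contracting cavity.
- **Mitral annular plane**: centred at $z = 0.4c$, tilted about the x-axis
  by 12° by default; the anatomy continues 8 mm past it so that volumetry
  must clip at the plane rather than at the end of the anatomy (basal
  partial-volume handling is therefore genuinely exercised).
- **Contraction**: phase 0 is end-diastole, phase $n/2$ end-systole; the
  cavity scale interpolates cosinusoidally between 1 and
  `es_cavity_scale` (default 0.6). Contraction is purely radial; long-axis
  shortening is not modelled.

With these defaults the rounded truth is EDV ≈ 105 mL, EF ≈ 64%, mass
≈ 101 g — a healthy-sized ventricle — and the trabecular truth differs in
the clinically expected direction (smaller cavity, heavier myocardium,
higher EF). The cohort generator used by `run_pipeline()` draws each
subject's geometry from ranges around these defaults ($a \in [30, 36]$,
$c \in [50, 60]$, $w \in [7, 10]$ mm, $A \in [1.5, 3]$ mm, $k \in [12, 20]$,
papillary radius $[3, 5]$ mm, ES scale $[0.55, 0.7]$, tilt $[5, 15]$°),
values we consider representative spread for a mixed adult cohort; they are
free choices, not calibrated against any measured trabecular morphology.

## Ground truth

Ridged truncated shells clipped by a tilted plane have no tractable closed
form, so truth volumes are computed by voxelization: the analytic membership
functions are evaluated on an isotropic grid (0.25 mm by default) and voxel
centres are counted, clipped to the apex side of the mitral plane. Two
safeguards validate the oracle itself: a pure half-ellipsoid cavity agrees
with $\tfrac{2}{3}\pi a b c$ to better than 1%, and 0.5 mm vs 0.25 mm grids
agree to better than 0.5% on the default phantom. The pipeline-scale tests
and the acceptance script therefore use 0.5 mm truth, which keeps a full
truth evaluation near one second.

## Acquisition simulation

Each view is rendered by classifying pixel centres (no partial-volume
integration within a pixel; the 1.25 mm grid and the later bilinear
resampling provide the only edge blur) with additive Gaussian noise
(SD 0.02 against a blood/myocardium/background contrast of
0.85/0.35/0.05). Scan–rescan pairs share one anatomy and truth and differ
only in acquisition-frame rotation, slice-stack offset and noise stream —
repositioning between same-day scans. Not modelled, deliberately: coil
shading, flow artifacts, wrap, mis-gating, breath-hold mis-registration,
through-plane motion. Consequently the synthetic scan–rescan variability is
much smaller than clinical test–retest variability; the precision
statistics are validated for *recovery of a known variability*, not for
reproducing clinical magnitudes.

The two-observer error audit is simulated with a miss-only observer model:
each case carries a latent error with the configured prevalence, and each
blinded observer overlooks a true error independently with probability
$(1-\text{agreement})/2$, never inventing one. Zero prevalence then yields
an all-zero (degenerate) table, and perfect agreement reproduces the latent
labels, both of which the statistics layer must flag rather than crash on.

# Geometry and preprocessing

Patient space is LPS millimetres; affines map 0-based voxel indices (pixel
centres) to patient coordinates; the NIfTI sform (code 2) carries the
affine on disk. Spatial normalization follows the standard cine recipe: the
intersection point of the short-axis, 2-chamber and 4-chamber planes is
placed at the centre pixel of a 160 × 160, 1 mm frame, rotated so the
2-chamber/short-axis intersection line runs along +y. The sign ambiguity of
that line is resolved by requiring the 4-chamber/short-axis direction to
have a positive x-component after rotation. Intensities are resampled
bilinearly in a single step (rotate-then-crop, one interpolation); labels
always travel by nearest neighbour.

Two numerical decisions deserve comment:

- **Percentile definition.** Intensity normalization clips at the 99th
  centile and rescales to $[0,1]$. We use the inverse-ECDF (order-statistic)
  centile rather than a linear-interpolation quantile: with an interpolated
  quantile, the 99th centile of an already-clipped image falls strictly
  below 1 and a second application rescales the whole image again. The
  order-statistic form makes normalization an exact fixed point
  (idempotent to machine precision), which downstream stages rely on.
- **Histogram unit.** The normalization is applied per short-axis stack
  (one histogram per stack per phase), not per 2-D frame. Threshold
  segmentation needs slice-comparable intensities; per-frame scaling would
  stretch empty basal/apical slices into amplified pure noise and
  invite spurious components.

The myocardial crop takes the tight bounding box of the rounded myocardium,
pads it by 8 normalized pixels, squares it by expanding the short side
symmetrically, and resamples to 80 × 80 (bilinear image, nearest-neighbour
labels), recording the window so decisions made on the crop map back to the
full frame exactly.

# Segmentation

The trained networks of a production system are replaced by deterministic
threshold operators so that every downstream contract (volumes, precision,
prognosis) is measurable without private model weights.

**Thresholds.** The pipeline estimates a two-threshold (3-class) Otsu split
of the stack histogram (256 bins), then refines each cut using the density
modes of the three classes, which are robust to the partial-volume boundary
pixels that bias class means. The background/tissue cut and the trabecular
relabelling cut sit at the 50% point between adjacent modes (unbiased edge
placement under symmetric noise). The *rounded* endocardial cut sits at the
30% point between the myocardial and blood modes: a smoothed rounded
contour deliberately assigns predominantly-blood partial-volume pixels at
trabecular crest interfaces to the blood pool, and crest tips — grazing,
one-sided structures — are systematically eroded by a midpoint cut.

**Rounded stage.** Grayscale morphological closing (3 mm disc) fills dark
ridges and papillary slivers narrower than the smoothing element while
leaving smooth edges invariant; the bright central connected component
above the rounded cut is then binary-closed and filled to its convex
deficiency *toward the cavity centroid*: the boundary radius is linearly
interpolated, in polar coordinates about the centroid, between the
convex-hull vertices. The polar form matters — a Cartesian hull polygon
chords across crest tips and loses 1–4% of cavity area; interpolating the
radius between tips at the same radius reconstructs the smooth envelope.
Myocardium is the shell between this contour and the outer tissue boundary.

**Trabecular stage.** Within the rounded blood pool only, pixels whose
crop-resolution intensity falls at or below the trabecular cut are
relabelled myocardium; everything outside the rounded blood pool is kept.
This enforces, pixel by pixel, trabecular blood ⊆ rounded blood and
trabecular myocardium ⊇ rounded myocardium — which in turn forces
EDV(trab) ≤ EDV(rounded) and LVM(trab) ≥ LVM(rounded) for every subject,
and a rounded-stage failure necessarily propagates to the trabecular stage.

**Known limitation.** The inclusive rounded cut is tuned to trabeculated
anatomy, the population of interest. On a completely smooth cavity
(ridge-free, no papillaries) it over-segments the blood pool by roughly
3–4%; on trabeculated phantoms across the generator's ranges the rounded
truth is recovered within about 3% (worst case at end-systole). Multiple
bright regions are disambiguated by keeping the component containing the
image centre, which the spatial normalization guarantees is the LV.

# Volumetry

Simpson summation over slices with slab height equal to the slice spacing
(thickness and gap treated as one contiguous slab — the conventional
choice). Basal clipping is *column-wise*: for each labelled pixel the
fraction of its slab interval on the apex side of the mitral plane is
computed exactly (linear in the plane offset, clamped to $[0,1]$), which is
strictly more accurate than including or excluding whole slices and is
validated against a 1000-point line-sampling Monte-Carlo oracle to 1e-3.
The mitral plane is fitted once per study by least squares through the four
landmark points (two per long-axis view; two points total would
under-determine a plane), with the normal oriented so a mid-ventricular
blood centroid lies on its apex side. Landmarks are provided per study
because the phantom's annulus is static; the fit is applied per phase when
per-phase landmarks exist.

ED and ES are the phases of maximal and minimal blood volume (frame
selection is not otherwise defined for a two-phase acquisition); mass uses
the conventional myocardial density 1.05 g/mL, evaluated at ED; indexing
uses Mosteller BSA, $\sqrt{hw/3600}$.

# Precision and agreement statistics

- **RMS CoV**: per subject $CV_i = |x_1 - x_2| / (\sqrt{2}\,\bar{x}_i)$;
  the reported CoV is $100\sqrt{\text{mean}(CV_i^2)}$, with percentile
  bootstrap (10,000 resamples, seeded) for the SD and CI. The CoV contrast
  between two methods on the same subjects uses a *paired* subject-level
  bootstrap of the CoV difference with a two-sided percentile p-value —
  the natural test given the bootstrap machinery, since the contrast has
  no standard closed form.
- **SEM and MDC**: $\text{SEM} = \sqrt{\sum d_i^2 / 2n}$ (within-subject SD
  from paired differences); $\text{MDC} = 1.96 \times \text{SEM} \times
  \sqrt{2}$, the 95% no-change band.
- **ICC**: ICC(2,1) — two-way random effects, absolute agreement, single
  measurement — computed from the ANOVA decomposition of the
  subjects × occasions table; the standard scan–rescan form.
- **Cohen's κ**: weighted form for ordinal tables (all weightings coincide
  for the binary error audit), with the large-sample weighted-kappa SE for
  the CI (the CI method is a package choice; several are defensible).
- **Sample sizes**: the paired-test calculator uses the normal
  approximation $n = \lceil (z_{1-\alpha/2} + z_{\beta})^2 \sigma_d^2 /
  \delta^2 \rceil$ (an exact noncentral-t iteration is available via
  `exact = TRUE` and yields slightly larger n); the relative calculator
  uses the $n \propto \text{SEM}^2$ scaling,
  $100\,(1 - (\text{SEM}_\text{new}/\text{SEM}_\text{ref})^2)$ percent.
- Degenerate inputs (zero variance, all-identical pairs, empty marginals)
  return flagged NA values rather than errors wherever a flag is the more
  useful behaviour for a table-producing pipeline.

# Prognosis models

Univariable Cox proportional-hazards fits use the survival package with
Breslow tie handling (the simplest well-defined choice). Each fit reports
β, the Wald HR CI, the likelihood-ratio χ² against the null, AIC
(−2LL + 2p, checked as an exact identity in the tests), and Harrell's
C-index of the linear predictor (in-package exhaustive-pair definition;
tied risks count ½; `survival::concordance` serves as an independent
cross-check in the tests, not as the implementation). Comparing two
*non-nested* single-covariate models by a likelihood-ratio test is not
well-posed; the comparison battery therefore reports each model's own χ²
against the null, the AIC difference (superior fit declared only beyond an
AIC reduction of 4), the C-index difference (greater discrimination only at
|ΔC| ≥ 0.05) with a seeded subject-resampling bootstrap p-value, and the
global Schoenfeld test (Kaplan–Meier time transform, the referenced
implementation's default). EF-threshold reclassification counts subjects
crossing 35% and 50% between methods.

The survival simulator draws exponential event times with rate
$\lambda_0 e^{\beta x}$ and administrative censoring, so β is the exact
estimand; recovery within the Wald CI and null calibration of the
Schoenfeld test are both verified in the tests.

# Problem sizes and determinism

The test suite and acceptance script are sized for a single CPU: phantom
truth at 0.5 mm; a 100-phantom cohort for the coupling-direction check;
10–20 scan–rescan pairs; 50-replicate coverage simulations with the full
10,000-sample bootstrap; survival cohorts of 300–500 subjects. Every
stochastic stage takes an explicit seed, RNG state is restored after each
seeded operation, and pipeline outputs are stamped with an MD5 hash of the
scientific configuration plus the seed; re-running a configuration
reproduces its outputs byte-identically.

# Limitations

The phantom's geometry is idealized (circular cross-sections, sinusoidal
ridges, cylindrical papillaries, radial-only contraction); passing tests
demonstrate correctness of the measurement chain and its statistics under
known truth, not segmentation performance on clinical images. The rounded
segmenter's inclusive cut over-segments perfectly smooth cavities (above).
Clinical magnitudes of scan–rescan variability, error rates and prognostic
strength depend on cohorts this package does not ship; the statistics layer
reproduces the published self-contained worked values exactly, while
pipeline-level quantities are validated for direction and for recovery of
simulated truth.
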