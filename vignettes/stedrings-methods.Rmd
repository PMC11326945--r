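---
title: "Quantifying organelle membrane rings in two-channel nanoscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organelle membrane rings in two-channel nanoscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

STED nanoscopy resolves the membrane of a yeast peroxisome as a ring:
the membrane marker (here called channel 1, e.g. Pex3 with a HaloTag dye)
forms a closed contour with a dark lumen, while a companion protein
imaged confocally (channel 2, e.g. the pexophagy receptor Atg30 with GFP)
appears as a diffraction-limited halo on and around that contour.
`stedrings` turns such image pairs into per-organelle numbers:

1. a circle fitted to the membrane signal, seeded from a manually clicked
   approximate center (`fit_ring()`);
2. the intensity of both channels as a function of membrane arc position
   (`extract_dual_profiles()`);
3. the Pearson correlation of the two smoothed profiles, one value per
   organelle (`ring_correlation()`);
4. a Between/Outside classification of each membrane sample — is the
   membrane point apposed to another organelle or exposed to the cytosol
   (`label_arc_samples()`) — with per-cell predominant localisation
   (`classify_cell()`) and cohort percentages (`outside_percentage()`);
5. condition-level summaries with a one-way ANOVA across conditions and a
   one-tailed paired t-test on replicate-level percentages
   (`summarize_conditions()`).

A seeded synthetic scene generator (`generate_scene()`, `render_scene()`)
provides ground-truthed input so every stage can be validated without any
microscope data.

## Circle fitting

From the seed, `detect_peak_points()` shoots 360 rays and samples the
radial intensity profile between `r_min_px` and `r_max_px` (default 1 to
20 px) by bilinear interpolation at 0.25 px steps. Each ray's membrane
peak is the global maximum of that profile; because the bilinear
interpolant is only piecewise smooth, the sub-step position is refined by
a dense local rescan at 1/25 of the radial step followed by a parabolic
step on the fine grid, rather than a single parabola on the coarse grid
(which can err by ~0.2 px at the interpolant's kinks). A ray is retained
only if its peak exceeds the local background — median plus
`background_sigma` (default 5) MADs of an annulus at 1.2–1.5 × `r_max_px`.
Five MADs, not two, because the peak is a maximum over ~80 radial
samples: a milder cutoff "detects" pure shot noise and a click on empty
background would not fail as it should.

The circle itself is the algebraic (Kåsa) least-squares fit, which is
closed-form, deterministic, and exact on noiseless circular data. Peaks
deviating more than `outlier_fraction` (default 10%) from the mean peak
radius are excluded in a single pass before fitting, and the
detect/exclude/fit round is repeated `refit_iterations` (default 2) times
from the refined center.

Three robustness measures surround that core, all motivated by clustered
organelles and imperfect clicks:

* **Initialisation.** A click can sit 1–2 px from the true center of a
  4–5 px ring. Radial *deviations from the seed* then reflect the click
  offset, not outliers — but the peak *points* still lie on the membrane
  circle. The first circle estimate therefore comes from a deterministic
  consensus fit over well-separated point triplets (inliers within
  0.5 px, radius constrained to the search range), applied before any
  deviation-based exclusion.
* **Retention reference.** Rays that cross a touching neighbour ring can
  lock onto its farther, often brighter membrane crest. The contaminated
  mean can then sit between the two radius populations so that the ±10%
  band keeps a small, wrong minority (masking). The same deviation band
  is therefore evaluated around both the mean and the median of the peak
  radii and the variant retaining more rays wins; on clean data the two
  retain essentially the same set, and the exclusion operation itself
  (`exclude_outlier_peaks()`) keeps its documented single-pass
  mean-referenced semantics.
* **Iterate guards.** A degenerate or out-of-range circle iterate keeps
  the previous estimate instead of diverging.

**Small filled organelles.** When an organelle is at or below the
resolution limit there is no luminal intensity dip and a radial peak fit
is meaningless. `fit_ring()` tests the interpolated intensity at the
*initialised* center against `dip_ratio` (default 0.7) times the mean
peak intensity; filled structures go to `segment_fallback()`, which
thresholds a local window (Otsu by default), takes the connected
component at the seed, and reports the intensity-weighted centroid and
half the moment-based major axis as the circle.

**Peak-position bias.** The radial peak of a circle of radius $a$ blurred
with an isotropic Gaussian of width $\sigma$ sits inward of $a$, at the
root of $r = a\, I_1(ra/\sigma^2)/I_0(ra/\sigma^2)$ — roughly
$\sigma^2/2a$, i.e. ~0.2 px for an 80 nm ring imaged at 60 nm FWHM with
20 nm pixels. Because the PSF width is known in any calibrated
experiment, `fit_config(psf_fwhm_nm = …)` optionally inverts this
relation on the fitted radius. The default is no correction, which
reproduces the plain peak-fit behaviour.

Circumference is reported as $2\pi r$ in nanometres alongside the number
of retained peaks; both scale with organelle size and either can serve as
the size statistic.

## Membrane profiles

`extract_profile()` samples each channel at `n_samples` (default 360)
equally spaced angles on the fitted circle, averaging over a radial band
of half-width `band_half_width_px` (default 2 px) so that the inner and
outer side of the membrane both contribute. The band average uses
trapezoidal weights (half weight on the two edge radii); with the default
0.5 px substep this tracks a dense radial integration of the image to
within 1%, where plain equal weighting is biased by several percent on a
curved profile. The companion channel uses a band
`companion_band_factor` (default 2) times wider, reflecting its coarser
PSF. Angles are uniform, so arc spacing is uniform per ring;
cross-ring comparisons are made on intensities, not on a common arc grid.
`aggregation = "max"` is available for peak-tracking use cases; the mean
is the default because it is robust to single-pixel outliers.

## Per-organelle correlation

Both profiles are smoothed with the same circular moving average
(`moving_average_circular()`, default window 5 samples ≈ 5°) and the
Pearson correlation of the smoothed sequences is the organelle's R value.
The window is a free parameter (the appropriate smoothing depends on the
confocal PSF in arc units); results tables record the window used.
Smoothing is symmetric in the two channels. Zero-variance profiles yield
an explicit undefined flag (`NA`), which downstream summaries exclude
with a count — an undefined correlation is never silently zero. The
circular window preserves the profile mean exactly.

## Between/Outside classification

A profile sample on ring $i$ at angle $\theta$ lies at
$p = c_i + r_i(\cos\theta, \sin\theta)$. It is **Between** when its
boundary-to-boundary distance to any other fitted ring,
$\bigl|\,\lVert p - c_j\rVert - r_j\,\bigr|$, is at most `gap_nm`
(default 30 nm, the scale of observed peroxisome–peroxisome appositions);
otherwise it is **Outside**. Per ring, the companion channel's class
means are reported; per cell, the class means are pooled across the
cell's rings weighted by sample counts, and the cell is *outside*
predominant when pooled-outside / pooled-between exceeds 1. Ties
classify as *between* (the conservative direction), and cells with an
empty class — e.g. a cell whose single peroxisome touches nothing — are
*indeterminate* and excluded from percentages, with counts logged.

**A structural caveat this package makes explicit.** At a contact the two
membranes coincide within the gap, so a Between sample integrates the
companion signal of *two* membranes; and a confocal-scale PSF smears
bright arcs into the narrow contact arc (the angular smearing is
$\sigma/r$ — about 30° for a 200 nm ring at 250 nm FWHM). Both effects
bias the measured outside/between ratio downward by a factor that can
reach ~2–3 for small, tightly clustered organelles. On synthetic scenes
with a planted three-fold Outside enrichment this bias keeps the measured
ratio below 1, so the unity threshold under-reports Outside-predominant
cells even though enriched and non-enriched cohorts remain cleanly
separable by their ratios. Validation therefore asserts monotonicity of
the measured ratio in the planted enrichment, and cohort percentages from
this classifier should be compared between conditions (where the
geometric bias is shared) rather than read as absolute fractions.

## Population statistics

`one_way_anova()` is the classical fixed-effects F test
(`stats::oneway.test` with equal variances), run by default on per-ring
values pooled across replicates; a replicate-means mode is available
(`anova_level = "replicate"`). `paired_t_one_tailed()` tests replicate
pairs of outside percentages in a stated direction — the direction is an
explicit argument, never a hidden default. No multiple-testing
correction is applied, and the output tables record the grouping level
used. Identical paired vectors return t = 0, p = 0.5 by convention;
zero-variance differences with nonzero mean are a degenerate-input error.

## The synthetic scene generator

`generate_scene()` plants what the estimators assume and `render_scene()`
images it:

* **Geometry.** Rings of radius 80–300 nm (4–15 px at 20 nm pixels) in
  1–3 rings per cell; within a cell, each subsequent ring is tangent to a
  previous one with probability `cluster_probability` (exact tangency —
  boundary gap 0 — so the default 30 nm gap labels contacts), otherwise
  placed with a clear margin. Placement retries are bounded; impossible
  configurations raise an explicit error.
* **Angular truth.** Channel 1 is a baseline plus von Mises patches
  (default 2–5 patches, κ = 4 ≈ 28° patch width, amplitude 2× baseline),
  emulating the patchy membrane distribution of the marker. Channel 2 is
  `coupling_alpha` × (normalized channel 1) + (1 − α) × an independent
  patch mixture, then multiplied by `outside_enrichment_beta` over
  Outside arcs. α = 0 gives uncorrelated truths, α = 1 proportional ones;
  the mapping from α to the *measured* R after two different PSFs is not
  closed-form, so validation asserts monotonicity and the endpoint
  behaviour rather than an analytic curve.
* **Imaging.** Each ring's truth is deposited along its circle at a fine
  arc step and convolved with an isotropic Gaussian per channel (defaults
  60 nm STED, 250 nm confocal FWHM — plausible placeholders for this
  imaging regime, configurable). Intensities are calibrated so a
  unit-truth membrane crest carries `photon_budget` expected photons
  (default 100, peak SNR ≈ 10 with the default background of 2); Poisson
  noise is applied on top (seeded, and switchable off for noiseless
  oracles). Centers are exported jittered by ≤ 2 px to emulate manual
  clicking.
* **Not modelled.** 3D structure, camera read noise, drift, bleaching,
  vacuole or other organelle context, depletion-beam physics. Passing
  tests on these scenes therefore demonstrate correctness of the
  estimators under the stated assumptions, not performance on every
  property of real data (e.g. non-circular organelles or structured
  background).

Determinism is part of the contract: identical configuration (including
the seed) yields bit-identical truths, rasters and, through the pipeline,
byte-identical result tables.

## Problem sizes used in validation

The packaged checks run at sizes chosen to give stable statistics on a
single CPU in a few minutes: 100 single-ring scenes for radius recovery
(noiseless and at peak SNR ≈ 10), ~208 rings per coupling level on the
α ∈ {0, 0.25, 0.5, 0.75, 1} grid, 30+ tangent-cluster scenes for label
agreement, a 150-cell cohort for the classification experiment, 500
replicates for the ANOVA null calibration, and a 2-condition ×
2-replicate seeded study for the end-to-end byte-identity check.

## Known limitations

* The Between/Outside ratio is biased toward *between* for tightly
  clustered, small organelles (see above); compare conditions, not
  absolute values.
* The Kåsa fit, while exact on clean circles, is not a maximum-likelihood
  estimator under noise; its residual bias is far below the pixel scale
  here, and a geometric refinement was deliberately omitted to keep fits
  closed-form and deterministic.
* The segmentation fallback reports half the moment-based major axis,
  which for an intensity-weighted, thresholded Gaussian spot
  underestimates the half-maximum radius slightly; it is a size proxy for
  sub-resolution structures, not a calibrated diameter.
* Both channels must share one raster grid; resampling a companion
  channel acquired on a coarser grid is a preprocessing step outside this
  package.
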