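# stedrings

Quantitative analysis of ring-shaped organelle membranes in paired
STED / confocal fluorescence images.

In methylotrophic yeast, STED nanoscopy resolves a peroxisome's membrane
marker (e.g. Pex3-Halo) as a closed ring with a dark lumen, while a
companion protein (e.g. the pexophagy receptor Atg30-GFP) is imaged
confocally in a second channel. `stedrings` measures, per organelle:

* a **circle fit** to the membrane signal, seeded from a manually
  clicked approximate center — each of 360 rays contributes its radial
  peak, peaks deviating more than 10% from the mean distance to the
  center are excluded, and an algebraic (Kåsa) least-squares circle is
  fitted and iteratively refined; sub-resolution "filled" organelles
  without a luminal intensity dip fall back to a segmentation-based
  estimate. The circumference is reported as 2πr in nanometres.
* **dual-channel membrane profiles** — both channels sampled along the
  fitted contour as a function of arc position, the lower-resolution
  companion channel with a two-times-wider radial band;
* a **moving-average Pearson correlation** R between the smoothed
  profiles, one value per organelle;
* a **Between / Outside classification** of every membrane sample:
  *Between* when the point lies within a gap (default 30 nm) of another
  fitted ring's boundary, *Outside* when exposed to the cytosol — with
  per-cell predominant localisation and cohort percentages;
* **condition-level statistics**: per-condition means ± SD, a one-way
  ANOVA across conditions, and a one-tailed paired t-test on
  replicate-level outside percentages.

A seeded synthetic scene generator (patchy von Mises membrane emission,
a coupled companion channel, tangent ring clusters, Gaussian PSFs at two
scales, Poisson noise, exported ground truth) makes every stage testable
without microscope data. See the methods vignette
(`vignettes/stedrings-methods.Rmd`) for the model, parameter defaults,
and known limitations.

## Worked example

Simulate a small two-condition study (two coupling levels between the
channels), run the full pipeline, and look at the tables:

```r
library(stedrings)

dir <- tempfile("demo")
study <- simulate_study(
  file.path(dir, "scenes"),
  conditions = list(meoh_16h      = list(coupling_alpha = 0.8),
                    glucose_30min = list(coupling_alpha = 0.3)),
  n_replicates = 3, images_per_replicate = 1, base_seed = 42,
  image_size_px = c(260L, 260L), n_cells = 4L,
  rings_per_cell_range = c(1L, 3L), cluster_probability = 0.6)
study$paired_conditions <- c("meoh_16h", "glucose_30min")
res <- run_pipeline(study)

head(res$per_peroxisome[, c("image_id", "ring_id", "radius_nm",
                            "circumference_nm", "R",
                            "n_between", "n_outside")], 4)
#>         image_id ring_id radius_nm circumference_nm      R n_between n_outside
#> 1 meoh_16h_r1_i1       1    188.13           1182.0 0.8652        81       279
#> 2 meoh_16h_r1_i1       2     89.58            562.8 0.7958       164       196
#> 3 meoh_16h_r1_i1       3     99.63            626.0 0.7153       133       227
#> 4 meoh_16h_r1_i1       4    183.61           1153.7 0.4145        53       307

res$summary[, c("condition", "n_rings", "mean_circumference_nm",
                "sd_circumference_nm", "mean_R", "sd_R")]
#>       condition n_rings mean_circumference_nm sd_circumference_nm mean_R  sd_R
#> 1 glucose_30min      25                  1325                 397  0.472 0.393
#> 2      meoh_16h      27                  1183                 389  0.832 0.130

res$tests[, c("test", "metric", "statistic", "df1", "df2", "p_value")]
#>                  test             metric statistic df1 df2  p_value
#> 1       one_way_anova   circumference_nm     1.699   1  50 1.98e-01
#> 2       one_way_anova           mean_ch2     0.386   1  50 5.37e-01
#> 3       one_way_anova                  R    20.255   1  50 4.06e-05
#> 4 paired_t_one_tailed outside_percentage    -1.000   2  NA 7.89e-01
```

Each per-peroxisome row is one fitted ring: its radius and circumference
in nanometres, its moving-average correlation R between the two
channels, and how many of its 360 membrane samples lie at contacts with
other rings (`n_between`) versus exposed to the cytosol (`n_outside`).
Here the condition simulated with strong channel coupling (α = 0.8)
shows a high mean R (0.83) and the weakly coupled condition a low, widely
spread one (0.47); the ANOVA on R separates them (p ≈ 4×10⁻⁵) while
circumference — drawn from the same distribution in both conditions —
does not (p ≈ 0.2).

A single organelle can be fitted directly:

```r
pair <- read_image_pair(study$manifest$ch1_path[1], study$manifest$ch2_path[1])
cen  <- read_centers(study$centers_path)
fit  <- fit_ring(pair$ch1, c(cen$row_px[1], cen$col_px[1]))
fit
#> <ring_fit_result> center (85.50, 150.19) px, r = 9.41 px (188.1 nm), C = 1182.0 nm, radial_peak [ok]
```

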