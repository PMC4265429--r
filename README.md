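# retfractal

Unsupervised measurement of retinal vascular complexity from
optic-disc-centred fundus photographs, using the **differential
(grayscale) box-counting fractal dimension** — no vessel segmentation
required — together with the cohort statistics used to relate that
dimension to diabetes status, and seeded synthetic generators that
provide ground truth for every stage.

## Who this is for

Researchers in ophthalmic image analysis who want a fully automatic,
deterministic FD measurement for disc-centred fundus photographs, and a
reference implementation of the grayscale box-counting estimator with
complete per-scale diagnostics and a validated oracle suite.

## The estimator

The image is a surface *z = g(x, y)* with *z* the gray level. For a grid
of side *s* over an analysis window with shorter side *M* and *G* gray
levels, the intensity axis is cut into boxes of height *s′ = sG/M* (a
column of cubes over each grid cell). Each cell spanning gray levels
*[g_min, g_max]* contributes

    n_cell = floor((g_max − g_min) / s′) + 1

boxes, and *N_r* is the total over all cells at grid ratio *r = s/M*.
The fractal dimension is the least-squares slope of *log N_r* versus
*log(1/r)* over dyadic scales *s = M/2, M/4, …, 2*. For any grayscale
surface the dimension lies in [2, 3]; enhanced retinal crops typically
measure 2.3–2.5.

The full pipeline is: optic-disc detection by an active contour on the
red channel → square crop of 4 disc diameters on the inverted green
channel, resampled to 729 × 485 → multiscale oriented (Gabor) vessel
enhancement → grayscale box counting. A binary box-counting comparator
(`binary_bc_fd()` on `segment_vessels()` output) is included for
reference.

## Worked example

```r
library(retfractal)

# a synthetic disc-centred scene with known ground truth
sf  <- gen_synthetic_fundus(synth_fundus_params(seed = 1))
rec <- measure_image(sf$image)
rec$od
#> <optic_disc> centre (480.0, 720.0), diameter 177.9 px, rms 0.11 px [snake]
rec$curve
#> <box_count_curve> dbc, 7 scales, fd = 2.3625 (R^2 = 0.9985)
```

The true disc is at (480, 720) with diameter 180 px: the detector is
0.03 px off centre and 1.2% off in diameter, and the enhanced ROI
measures FD 2.36 — inside the typical retinal range, with an almost
perfectly linear log–log box-count curve (R² = 0.9985).

The statistical layer on a synthetic cohort calibrated to the study
population (166 controls, 23 diabetic cases):

```r
ch  <- gen_cohort(cohort_gen_params(seed = 1), mode = "group_mean")
res <- group_anova(ch, "diabetes")
res$summaries
#>   level   n  mean_fd   ci_low  ci_high
#> 1     0 166 2.420274 2.417482 2.423066
#> 2     1  23 2.441677 2.434175 2.449179
res$p_value
#> 3.7e-07
```

Diabetic cases show a higher mean FD (2.4417 vs 2.4203) with pooled
95% intervals and a one-way ANOVA p-value well below 0.001 — the
group structure the generator was calibrated to.

`ols_regression(ch)` fits FD on BMI, age, blood pressures, gender and
diabetes; `interaction_anova(ch)` tests the diabetes × gender
interaction; `anderson_darling_normality(ch$fd)` checks normality.

A command-line front end is in `inst/cli/retfractal.R`
(`measure`, `pipeline`, `synth`, `stats` subcommands, YAML config,
exit codes 0/2/3).

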