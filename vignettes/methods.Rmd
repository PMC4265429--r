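---
title: "Measuring retinal vascular complexity with grayscale box counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vascular complexity with grayscale box counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Retinal vessels form a branching, space-filling network whose geometric
complexity changes with systemic disease. A standard summary of that
complexity is the fractal dimension (FD) of the vasculature. Most FD
estimates in the ophthalmic literature use binary box counting, which
requires segmenting the vessels first; segmentation errors and the manual
clean-up they demand make that route unattractive for automated screening.

`retfractal` implements the segmentation-free alternative: the
differential (grayscale) box-counting dimension (DBC) of an
optic-disc-centred crop of the fundus photograph. The image is treated as
a surface $z = g(x, y)$, where $z$ is intensity. For a grid of side $s$
pixels over an analysis window with shorter side $M$ and $G$ gray levels,
the intensity axis is divided into boxes of height $s' = sG/M$, so that
the boxes covering a grid column are cubes in the rescaled coordinates.
Each grid cell contributes

$$n_{cell} = \left\lfloor \frac{g_{\max} - g_{\min}}{s'} \right\rfloor + 1,$$

the number of intensity boxes spanned between the cell's minimum and
maximum gray level, and $N_r = \sum_{cells} n_{cell}$ at grid ratio
$r = s/M$. The FD is the ordinary-least-squares slope of $\log N_r$
against $\log(1/r)$ over dyadic scales. For any intensity surface the
slope lies in $[2, 3]$: a constant image gives exactly 2 (one box per
cell, $N_r = (1/r)^2$), and fully space-filling intensity variation
approaches 3.

## Pipeline

1. **Load** (`load_fundus()`): 8-bit RGB raster, any of PNG/TIFF/JPEG.
2. **Optic disc** (`detect_od()`): the disc is the brightest structure in
   the red channel. The contour is initialised from the largest connected
   component above a scale-free threshold (median plus half the
   median-to-maximum range of the smoothed red channel), then refined as a
   radial active contour on the gradient-magnitude edge map with a
   smoothness penalty and a small inward balloon pressure; it stops when
   no point moves more than 0.1 px (cap 500 iterations). A least-squares
   circle fit to the converged boundary gives centre, diameter and an RMS
   residual. An exhaustive circle search over nearby centres and radii is
   the fallback when the contour fails. Images with no sufficiently bright
   candidate region raise a detection error — the exclusion pathway for
   ungradable photographs; batches record the exclusion and continue.
3. **ROI** (`extract_roi()`): a square of four disc diameters centred on
   the disc, cropped from the *inverted green channel*
   (`extract_green_inverted()`), edge-replicated where it leaves the frame
   (rejected above 25% padding), and bilinearly resampled to 729 x 485 by
   default. The anisotropic output replicates the source protocol; a
   `square_out` switch gives a geometry-preserving 512 x 512 instead.
4. **Enhancement** (`enhance_vessels()`): a bank of complex Gabor filters
   (scales 2-5 px across the vessel, 12 orientations, envelope elongation
   4, carrier wavelength $4s$) is applied by FFT with reflective padding;
   `vessel_response()` is the per-pixel maximum response modulus over the
   bank. The enhanced image is the input plus `vessel_gain` (default 0.6)
   times the normalised response, linearly rescaled to $[0, G-1]$.
5. **FD** (`dbc_fd()`): dyadic scales from `min_s = 2` to half the shorter
   side, OLS fit in natural logs, with per-scale counts and $R^2$
   reported in a `BoxCountCurve`.

```{r}
library(retfractal)
sf <- gen_synthetic_fundus(synth_fundus_params(seed = 1))
rec <- measure_image(sf$image)
rec$curve
```

## Design choices on points the protocol leaves open

**Why the enhanced image is not the raw filter response.** A
maximum-modulus Gabor response is band-limited: it varies on the scale of
the carrier wavelength and is therefore smooth at the pixel scale. The
grayscale box-counting dimension of such an image collapses to about 2.02
regardless of the scene, while enhanced retinal crops are consistently
reported in the 2.3-2.5 range — their sensor-scale texture carries the
fractal signal. Enhancement here therefore *adds* the vessel response to
the image instead of replacing the image with it: vessel contrast
improves (the package's `contrast_ratio()` rises from about 1.5 to about
1.9 on synthetic scenes) while fine-scale content is preserved. The raw
response remains available as `vessel_response()`.

**Cell counts.** The difference-based count $\lfloor \Delta g / s'
\rfloor + 1$ is used because it makes the estimator *exactly* invariant
to constant intensity offsets, a property the test suite asserts
bit-for-bit. The fixed-partition variant
($\lfloor g_{\max}/s' \rfloor - \lfloor g_{\min}/s' \rfloor + 1$) is
available via `variant = "absolute"` for cross-checks against other
implementations.

**Smallest scale.** At $s = 1$ every cell holds one pixel, every count is
1, and the point drags the slope toward 2 while adding no intensity
information; the default starts at $s = 2$, with `include_s1 = TRUE`
available.

**Non-square, non-dyadic windows.** The 729 x 485 ROI is neither square
nor a power of two. The analysis side is $M = \min(h, w)$; grids tile the
full rectangle and partial boundary cells participate with their actual
extents, so no vasculature is discarded and no artificial flat padding
deflates the slope.

**Circle fit.** The algebraic (Kasa) least-squares circle is used: it is
closed-form, deterministic, and exact (zero residual) on noise-free
circle samples, which the tests require at $10^{-9}$ relative tolerance.

**Coordinates.** Matrices are indexed 1-based `(row, col)` as everywhere
in R; all reported geometry (centres, diameters, errors) is independent
of that convention.

**Interaction model.** The diabetes-gender interaction is a two-factor
linear model with interaction and no additional covariates, since no
covariate list is specified for that analysis; the sequential F-test of
the interaction term (entered last) is reported.

**Group confidence intervals** use the pooled one-way-ANOVA residual
variance rather than per-group SDs, which makes interval widths
reproducible from the group sizes and a single variance estimate — the
convention of the desktop statistics package used for the original
analyses. `mean_ci()` provides per-sample t intervals where needed.

**Gender coding** is female = 1, male = 0, which makes the negative
published gender coefficient consistent with the higher male group means.

## What the generators emulate — and what they do not

`gen_synthetic_fundus()` renders a flat reddish background with Gaussian
sensor noise, a bright smooth-rimmed disc, and a recursive bifurcating
vessel tree (two trunks, sinusoidal tortuosity, geometric width decay)
drawn dark on the green channel with Gaussian cross-sections. The frozen
default scene is 960 x 1440 px with a 180 px disc, so the four-diameter
crop (720 px) is *downsampled* into the 729 x 485 ROI just as the
original 4288 x 2848 photographs were — this preserves pixel-scale noise
in the ROI, which matters for the fractal stage. Tree depth 10, root
width 14 px, width decay 0.88 and noise SD 14 were chosen once so that
the enhanced ROI lands mid-range of the typical retinal FD interval and
vessel coverage (~10% of the ROI) resembles real crops. Not emulated:
illumination gradients, arteriole/venule distinction, pathology
(microaneurysms, haemorrhages), or camera optics. Passing tests
demonstrate that the pipeline recovers known geometry and known
statistical structure; they do not certify clinical performance on real
photographs.

`gen_fbm_surface()` synthesises fractional Brownian surfaces spectrally
(complex Gaussian spectrum with amplitude $\propto f^{-(H+1)}$, inverse
FFT, linear quantisation to $[0, 255]$). The theoretical surface
dimension $3 - H$ makes these the estimator's oracle;
`periodogram_slope()` independently verifies the synthesised spectrum.

`gen_cohort()` draws group-wise covariates (normal, ages truncated to the
study's 14-73 range, Bernoulli gender) around the published group
moments, and offers two FD models because the published group summaries
and the published regression are not jointly exact: `group_mean` mode
draws FD per group around the published means with SDs back-derived from
the printed 95% CIs ($SD = \text{half-width}/1.96 \times \sqrt{n}$,
giving 0.0168 and 0.0166); `regression` mode uses the published model-1
linear predictor with residual SD 0.0159, chosen once so the model
$R^2$ sits near the published 20.7%.

## Numerical behaviour and known limitations

* **Bounds.** Over a seeded 100-image suite (constants, noise, gradients,
  fractional Brownian surfaces, enhanced synthetic ROIs) every estimate
  falls in $[2, 3]$; constants give $2$ with $R^2 = 1$ to $10^{-9}$.
* **Known estimator bias.** Like all Sarkar-style DBC implementations,
  the estimator underestimates the dimension of very rough surfaces: at
  512 x 512 and 8-bit quantisation the mean estimate is near the
  theoretical $3 - H$ for smooth fields ($H = 0.8$) but falls short by
   0.2-0.3 for $H \le 0.5$. Two mechanisms cause this: at small scales the
  expected per-cell min-max range grows with the number of pixels per
  cell (an extreme-value factor on top of the $s^H$ structure function),
  flattening the low-$s$ end of the log-log curve, and at large scales
  counts saturate toward the $+1$ floor. The bias is monotone, so the
  ordering of surfaces by roughness — what the cohort comparisons rely
  on — is preserved, and the suite asserts strict monotonicity in $H$.
  Restricting the fitted scale range does not remove the bias and is not
  done by default.
* **Determinism.** Every generator is a pure function of its parameters
  including the seed, and restores the caller's RNG state. The pipeline
  is deterministic given inputs and configuration.
* **Problem sizes.** The validation suite uses 100 mixed-size images
  (128-512 px), 20 full-pipeline synthetic scenes, 10 surfaces per Hurst
  value, 200 regression replicates and 1000 null ANOVA replicates —
  sizes at which each check completes in seconds to a few minutes on one
  core while keeping Monte-Carlo error well inside the asserted bands.
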