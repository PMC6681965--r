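---
title: "Coccolith morphometry by calibrated polarised-light imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coccolith morphometry by calibrated polarised-light imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coccomorph)
```

## The scientific question

Coccolithophores are single-celled marine algae that build calcite plates
(coccoliths). Single-coccolith mass matters for carbonate budgets and carbon
export, but it is hard to measure directly, so it is commonly *estimated*
from coccolith length through the volumetric shape-factor model

$$ m = k_s \, l^3 \, d, $$

where $m$ is mass (pg), $l$ is length (µm), $d = 2.71$ pg µm⁻³ is the
density of calcite and $k_s$ is a species-specific dimensionless shape
constant. The cubic exponent assumes **isometric growth**: thickness scales
proportionally with length. If thickness is instead decoupled from length
(allometric growth), mass grows roughly with $l^2$ and the cubic model
systematically overestimates the mass of longer coccoliths.

This package implements the full chain needed to study that question with
known ground truth: a forward optical model of circular-polarised-light
(CPL) imaging of birefringent calcite, a synthetic coccolith and micrograph
generator, the inverse measurement pipeline, the $k_s$ model and its bias
audit, and the statistical layer (ANOVA, Tukey HSD, regression with global
assumption validation, and a measurement-resolvability rule).

## The optical forward model

Thin calcite between crossed circular polarizers produces an interference
grey whose brightness encodes the optical retardation
$\Gamma = 1000\,\Delta n_\mathrm{eff}\, t$ (nm, $t$ in µm). The package uses
the single-wavelength intensity law

$$ g(\Gamma) = g_0 + A \sin^2\!\left(\frac{\pi \Gamma}{\lambda}\right),
\qquad \lambda = 550\ \mathrm{nm\ (default)}, $$

restricted to the first order $\Gamma \le \lambda/2$ so the curve is
strictly increasing and invertible. Real calibrations use the full-colour
Michel-Lévy chart; in the first-order grey regime the single-wavelength
curve is an adequate monotone stand-in and has an exact closed-form inverse.
The calibration is anchored the way microscopes are calibrated in practice:
by fitting through the grey values of two reference retardation films (31 nm
and 129 nm), which recovers the dark offset $g_0$ and amplitude $A$ exactly
for the two-parameter model.

Choices worth noting:

* **Effective birefringence** $\Delta n_\mathrm{eff} = 0.172$ (the calcite
  maximum) by default, configurable. The value a given microscope implies
  depends on crystal orientation; since the same constant is used for
  synthesis and measurement, recovery tests are insensitive to it.
* **Working range** capped at $\lambda/2$; thicker pixels raise an error.
  This matches the method's validity domain (thin coccoliths).
* **Grey values are continuous during synthesis** and quantized only when an
  image is materialized. The default bit depth is 16. At 8 bits the
  E. huxleyi regime (mean thickness ≈ 0.07 µm, $\Gamma \approx 12$ nm) spans
  fewer than two grey steps of the first-order curve, so quantitative
  recovery through a single-wavelength grey calibration is not possible;
  the real method leans on colour information there. 8-bit writing is
  supported for completeness.
* **Sub-offset greys clamp to zero retardation** (background noise), with
  the clamp count logged; greys above the gain level are an error (outside
  the first order).
* Gamma encoding: the calibration is fit on the same encoding the generator
  emits, so the pipeline is self-consistent; no gamma correction is applied
  by default.

Per-pixel mass is $d \, A_\mathrm{px} \, t$ with pixel area
$A_\mathrm{px} = 0.0003$ µm², and total mass of any thickness map satisfies
the conservation identity $m = d\,A_\mathrm{px}\sum t$ exactly — this is the
anchor every downstream module is tested against.

## The synthetic coccolith

A coccolith is modelled as two concentric ellipses (outer shield, inner
central-area opening) with a smooth radial thickness profile across the
shield: a half-sine peaking mid-shield plus a linear ramp that leaves a
finite thickness step at the outer rim. The step gives the crisp outer edge
that edge-based segmentation needs; the central-area edge tapers to zero.
No published 3-D shape exists for these coccoliths, so the profile is a
modelling choice; only integrated quantities (area, mean thickness, mass,
thickness-distribution skewness) are treated as meaningful, and the
recovery tests assert exactly those.

Populations are drawn as follows:

* **Length**: truncated normal (> 0) whose mean shifts linearly with
  salinity. The default study design derives per-strain means, slopes and
  spreads from the published per-culture summaries (mean lengths 2.5-3.4 µm
  for *E. huxleyi*, 4.5-5.1 µm for *G. oceanica*; spreads back-computed
  from the printed 95% CIs, e.g. CI 0.1 µm with n = 30 implies an
  observation sd of about 0.27 µm).
* **Thickness coupling**, the scientific dial of the generator:
  `isometric` ($\bar t = cL$), `allometric` ($\bar t = cL^b$) or
  `decoupled` ($\bar t \sim N(T_0, \sigma_T)$, independent of length). The
  default design uses `decoupled` for *E. huxleyi* (the study's finding)
  and `isometric` for *G. oceanica*. Under decoupled coupling, ground-truth
  mass scales as $l^2$ — the mechanism behind the model-bias divergence.
* **Aspect ratio** (truncated ≥ 1, default mean 1.25) and **central-area
  fraction** (default mean 0.45) are mild normal variates; typical placolith
  values, not published quantities.
* **Sample size** n = 30 per culture and salinities 25/34/44, the study's
  design.

All randomness flows from a single master seed; per-cell seeds are drawn
from it, so identical seeds give identical studies.

`simulate_study()` has two modes. **Table mode** bypasses imaging: analytic
ground truth (exact for the continuous geometry) plus Gaussian measurement
noise at half the stated 95% uncertainties (length sd 0.1 µm, thickness sd
0.0035 µm, mass 8% relative). This is fast and is what the statistical
layer is exercised on. **Image mode** rasterizes every coccolith at the
calibrated pixel size and renders grey micrographs (grid layout,
non-overlapping, optional reference-film patches, Gaussian camera noise,
default sd 2×10⁻⁴ normalized grey ≈ 13 counts at 16 bit).

What the generator does **not** emulate: malformation, bridge structures,
overlapping or touching particles, illumination gradients, out-of-focus
blur, and 3-D crystal-optic effects. Passing recovery tests therefore show
the pipeline is internally consistent and correctly calibrated — not that
it handles every pathology of real micrographs.

## The inverse pipeline

* **Segmentation** is Canny-style: Gaussian smoothing (default σ = 1.5 px),
  Sobel gradient magnitude, hysteresis thresholds derived from the robust
  background (median + 2.5/6 MAD, with a floor relative to the maximum
  gradient so noise-free images segment), weak regions kept only when they
  contain strong pixels, then hole filling. A refinement step shrinks each
  region to pixels whose grey exceeds the robust background level; without
  it the smoothing halo inflates lengths by several pixels and dilutes mean
  thickness. The central-area opening is retained as interior (zero-mass)
  pixels. Particles outside 0.5-100 µm² or touching the border are removed
  with logged counts.
* **Length and width** come from the ImageJ-convention moment ellipse
  (axis ratio from the second-moment eigenvalues, axes rescaled so the
  ellipse area equals the mask area), since the original measurements were
  made with ImageJ particle analysis. The maximum Feret diameter is
  available as an optional column.
* **Mass and mean thickness** follow the conservation identity on the
  calibrated per-pixel thickness, so $m = d \cdot \mathrm{area} \cdot
  \bar t$ holds to machine precision for every particle.
* **Skewness** of the thickness distribution uses the biased Fisher-Pearson
  moment form $g_1 = m_3/m_2^{3/2}$ (what common image software reports);
  the adjusted estimator and raw-grey skewness are available via flags —
  thickness and grey skewness differ under the nonlinear calibration, and
  the calibrated-thickness version is the default because it is the
  physically meaningful shape descriptor.

Zero-noise synthetic studies are recovered to within 2 pixels in length and
2% in mean thickness and mass for ≥ 95% of particles (the residual error is
quantization plus pixelation), and mean measured $k_s$ matches the generated
value within 5%.

## Uncertainty budget

Uncertainties are propagated to 95% confidence in first-order quadrature
from six components: calibration-curve fit (5% relative), illumination
variation (4%), calibration-curve resolution (3%), pixel-size calibration
(1% linear), edge localization (4 px per boundary) and camera grey noise
(via the local slope of the inverse calibration, averaged over the
particle's pixels). The partition among sources is not published; the
defaults were chosen so that a typical *E. huxleyi*-scale particle lands at
the method's stated uncertainties — ±0.2 µm length, ±0.007 µm thickness,
and 13-20% relative mass (≈ 0.9 pg for *G. oceanica*-scale particles). On
noisy synthetic images the stated intervals cover ground truth for well
over 90% of particles; the actual errors of the pipeline are much smaller
than the stated bands, which mirrors the conservatism of the real method's
published budget.

A difference between sample means counts as **resolved** only when it is at
least twice the stated 95% uncertainty (so length differences under 0.4 µm
are unresolved). Statistical significance and resolvability are reported as
separate flags.

## The statistical layer

* **ANOVA / Tukey HSD**: classical fixed-effects decomposition via `lm`;
  Tukey intervals and adjusted p-values from the studentized range
  distribution (`ptukey`/`qtukey`), cross-checked in the tests against
  `stats::TukeyHSD`, a Monte-Carlo studentized-range oracle, and the exact
  $k=2$ reduction to the pooled t-test.
* **Global assumption validation**: four directional statistics — residual
  skewness, residual kurtosis, link misspecification (squared-fitted-values
  augmentation) and heteroscedasticity (squared residuals on fitted values)
  — each standardized to an asymptotic χ²(1) deviate; their sum is the
  global χ²(4) statistic. The moment statistics use exact small-sample null
  means/variances; the two regression-based components are mapped through
  their finite-sample t-test p-values. This standardization was validated
  by simulation (type-I error 4.9% at nominal 5% for n = 30 Gaussian data,
  2000 replicates), not by matching any particular implementation
  bit-for-bit. Independence is not testable within a single sample and is
  reported as assumed.
* **Transform policy**: if the global test rejects at 5%, the regression is
  refit on the natural-log-log scale (base only rescales the slope); if
  violations persist or the data cannot be logged, the sample is kept
  untransformed and flagged.
* **Influence diagnostics**: studentized residuals outside the pointwise
  95% normal-quantile envelope of the Q-Q plot. Points are reported, never
  removed. For regression residuals the envelope is conservative (the
  fitted constraints remove the location mode that drives Q-Q excursions),
  so clean data are flagged well below 5%; large outliers are still caught
  reliably.
* Non-finite measurements are dropped with a logged count before any test;
  zero-variance ANOVA returns F = 0, p = 1 by convention.

## Estimating $k_s$ from samples

Two estimators are always reported: the **mean of per-coccolith ratios**
$\overline{m_i/(l_i^3 d)}$ with a t-based CI, and the **ratio of means**
$\bar m / (\bar l^3 d)$. They agree exactly for identical coccoliths and
diverge with length spread — because $E[l^3] \ge E[l]^3$, the ratio-of-means
form exceeds the mean-of-ratios by roughly $3\,\mathrm{cv}^2$ under
isometry, about 2-4% at realistic length spreads. The published per-culture
$k_s$ values are reproduced by the ratio-of-means arithmetic on the printed
mean mass and length for most rows (16 of 24 at the printed precision).
Applying a literature shape constant of 0.05 to samples whose measured
constant is 0.021 overestimates mass by 138.1% (≈ 140%), independent of
length, because the model is scale-invariant in $l$.

## Problem sizes and numerical choices

The test suite runs the full 24-sample, 720-coccolith table-mode study;
image-mode checks use smaller renders (8-30 coccoliths per sample at the
real pixel size of 0.0003 µm², i.e. 150-300 px per coccolith) so the whole
suite completes in well under a minute of imaging work. The level
simulation uses 2000 replicates at n = 30; the qualitative-pattern check
uses 25 replicated two-strain studies at the published effect sizes
(+0.7 µm length from salinity 25 to 44, thickness decoupled). Tolerances:
calibration references reproduced to 0.02 grey; grey-retardation round trip
exact to one quantization step; conservation identities to machine
precision.

## Known limitations

* The geometry is a smooth idealized placolith; real coccoliths have
  crystallographic texture, slits and tube structures that affect the
  thickness histogram's fine shape (its skewness sign and trends are still
  meaningful).
* The single-wavelength grey model cannot represent the colour information
  real calibrations exploit; quantitative thickness work at 8-bit grey is
  out of reach by construction.
* The measurement pipeline assumes isolated particles; overlapping
  coccoliths are rejected rather than separated.
* Growth-rate handling is limited to the exponential-phase formula; no
  attempt is made to model growth dynamics.
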