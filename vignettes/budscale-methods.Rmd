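---
title: "Methods: the modified volumetric power model and its pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the modified volumetric power model and its pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budscale)
```

## The problem

Macroscopic engineered living materials (ELMs) grown from matrix-secreting
bacteria in shake flasks assemble through a pellicle at the air–water
interface, and the size of the final material depends non-monotonically on
shaking speed, fill volume and flask diameter. Neither the volumetric power
input nor the oxygen transfer coefficient alone predicts material size
across flask geometries; their product with a fifth-power diameter
correction does. `budscale` implements that composite model and the
quantitative pipelines around it.

## The hydrodynamic model

For an unbaffled flask of inner diameter $d$ shaken at frequency $n$ on an
orbit of diameter $d_0$ with fill volume $V_L$:

$$\mathrm{Re} = \frac{\rho\, n\, d^2}{\eta_{app}}, \qquad
Ne' = 70\,\mathrm{Re}^{-1} + 25\,\mathrm{Re}^{-0.6} + 1.5\,\mathrm{Re}^{-0.2}$$

$$\frac{P}{V_L} = \frac{Ne'\,\rho\, n^3 d^4}{V_L^{2/3}} \quad [\mathrm{W/m^3}],
\qquad
k_La = 0.5\, d^{73/36}\, n\, d_0^{1/4}\, V_L^{-8/9}\, D^{1/2}\,
\nu^{-13/54}\, g^{-7/54} \quad [\mathrm{1/s}]$$

$$P_{V,A} = d^5 \cdot k_La \cdot \frac{P}{V_L}
\quad [\mathrm{W\,m^2/s}],$$

reported in mW m²/s so that the optimal band 0.72–1.65 sits on the printed
scale. The medium constants default to water at 30 °C
($\eta_{app} = 7.97\times10^{-4}$ Pa·s, $\rho = 995.67$ kg/m³,
$\nu = 8.005\times10^{-7}$ m²/s, $D = 2.5655\times10^{-5}$ m²/s,
$g = 9.807$ m/s², $d_0 = 0.05$ m). All constants are used verbatim as the
model defines them — including $D$, which is larger than a textbook O₂
diffusivity in water; the correlation is a package of its printed
constants, and swapping one would change the predictor scale and detach the
band from it.

Modelling choices worth making explicit:

* **Static cultures.** $Ne'$ diverges as $\mathrm{Re}\to 0$, but
  $Ne'\,n^3 \propto n^2 \to 0$, and $k_La$ is linear in $n$, so every power
  quantity has a continuous zero limit at $n = 0$. The code short-circuits
  $n = 0$ rather than evaluating the correlation; `newton_mod` is reported
  `NA` there. Static growth is a meaningful input: no material forms
  without shaking.
* **Units at the interface.** Bench protocols quote rpm and mL; the
  correlations need 1/s and m³. Constructors take explicitly unit-tagged
  arguments (`shaking_rpm` vs `shaking_per_s`, `fill_volume_mL` vs
  `fill_volume_m3`) and store SI. The $d^5$ factor makes a silent cm/m slip
  a four-orders-of-magnitude error, which is why no untagged numeric is
  accepted anywhere and why flask presets (`flask_presets()`) are marked as
  assumed values.
* **Band edges.** The optimal range is a closed interval: 0.72 and 1.65
  mW m²/s both classify `optimal`. Inverse solutions that converge onto an
  edge target are labelled from the target, not from the
  $\mathcal{O}(10^{-10})$ residual.
* **Dimensional check.** Because the $k_La$ correlation is dimensional,
  `model_dimensions()` re-derives its units by exact rational exponent
  arithmetic (integer numerator/denominator pairs, no floating point):
  length exponent $\frac{73}{36}+\frac14-\frac{8}{3}+1-\frac{26}{54}-\frac{7}{54}=0$
  and time exponent $-1$, and $P/V_L$ reduces to kg m⁻¹ s⁻³ = W/m³.

## Inverse design

$P_{V,A}$ is strictly increasing in $n$ (every factor is a positive power
of $n$) and strictly decreasing in $V_L$ (exponents $-2/3$ and $-8/9$), so
designing a condition for a target $P_{V,A}$ is monotone 1-D root finding.
`solve_frequency()` / `solve_volume()` bracket the target (defaults cover
6–600 rpm and 10–500 mL — artefact defaults, configurable) and solve with
`stats::uniroot` to a relative tolerance of $10^{-9}$ on the achieved
$P_{V,A}$. A target outside the bracket's image returns
`converged = FALSE` with diagnostics rather than throwing, so a design
sweep over many targets degrades gracefully.

## Apparent size from flask-bottom photographs

Trained pixel-classification workflows (ilastik-style two-stage
autocontext) are the usual way to make this measurement, but a trained
model is not reproducible from a description. The package keeps the same
three-class semantics — background, scattered debris, bundled material —
with a deterministic, parameterised two-stage rule:

1. **Stage 1** — optional Gaussian smoothing (`smooth_sigma`, default 0 px:
   off; enable ~1 px for noisy photographs) then a global threshold on the
   blue channel (automatic Otsu by default, fixed value available). The
   blue channel is used because material contrasts best against the flask
   there.
2. **Stage 2** — 8-connected components; objects with area
   `min_bundle_area_px` (default 200 px) or more are `bundled`, smaller
   ones `scattered`; objects under `min_object_px` (default 2) are
   discarded as noise. 8-connectivity and border-object retention are
   deliberate: flask rims crop material arbitrarily.

Calibration is a pure linear scale, `cm_per_px = diameter_cm /
(2 * radius_px)`, from a manually supplied rim circle — lens distortion and
wall refraction are not modelled, and automatic circle detection is
deliberately not trusted as a default. The per-image summary is the mean of
all bundled areas at or above the 95th percentile (linear-interpolation
percentile, threshold inclusive) — the "top five percentile averaged"
measure. Two interpretations were open and are fixed here: the percentile
definition (type-7 interpolation, inclusive `>=`), and the object pool
(bundled pieces only, since areas are computed from the stage-2 mask;
pooling scattered debris would dilute the statistic with specks).

## The overlap statistic

Matrix composition is assessed as the percentage of overlapping pixels
between cell-free and stained regions. The operational definitions this
statistic needs are fixed as: per-channel automatic (Otsu) thresholds; the
material ROI is the morphological closing (disc, radius 5 px, configurable)
of the union of both masks, or an explicitly supplied ROI; the cell-free
region is ROI minus the cell mask; and the reported percentage is
$100\,|{\rm stain}\cap{\rm cellfree}|/|{\rm cellfree}|$ — the fraction of
the cell-free matrix that is stained, which is the question the comparison
asks (is the matrix proteinaceous?). Alternative denominators (`stained`,
`roi`) are selectable. An empty cell-free region yields an explicit
undefined flag, never a number. Group summaries report mean, sample SD
(n−1, `NA` for singletons), median and the 25–75% IQR — the box-plot
descriptors.

## Unimodal response and the optimal band

Optimal operating windows of this kind are often drawn by eye on grouped
data; to make the band reproducible the package fits

$$\mathrm{size} = A\,
\exp\!\left(-\frac{(\log_{10} P_{V,A} - \mu)^2}{2 w^2}\right) + b$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`, amplitude and
width bounded positive) and derives the band as the closed-form half-max
interval $10^{\mu \pm w\sqrt{2\ln 2}}$ (fraction $f$ configurable,
default 0.5 as the FWHM analogue). Replicates are averaged per condition
before fitting by default. A model-free alternative, `empirical_band()`
(range of conditions whose mean size reaches $\alpha \cdot \max$,
$\alpha = 0.5$), is provided for users who prefer an assumption-free
grouping of their conditions. Degenerate inputs — flat
response, fewer than 5 distinct predictor values, optimiser failure — give
`converged = FALSE` with a message, never a fabricated band. $R^2$ is
truncated to $[0,1]$.

`compare_parameters()` refits the same form against $P/V_L$, $k_La$ and
$P_{V,A}$ and ranks by $R^2$. The three are algebraically confounded on
single-diameter data, so such tables are flagged.

## What the generators emulate — and what they do not

The generators exist so every pipeline is testable end to end with no
external data; their defaults are the study conditions:

* `gen_condition_table()` — 30 conditions × 3 replicates across the three
  flask diameters (0.065/0.085/0.105 m), fill volumes 40–160 mL, response
  peak at 1.09 mW m²/s (geometric midpoint of the 0.72–1.65 band) with
  log-width 0.153 (so the planted half-max band is the optimal band),
  amplitude 6 cm² over a 0.5 cm² baseline, noise SD 10% of amplitude,
  truncated at 0. Conditions are placed on an even $\log_{10} P_{V,A}$
  grid spanning peak ± 2.5 widths by solving the inverse model, so the
  planted peak is exact. The `kla`/`power` modes plant the response on the
  realised alternative predictor instead, decoupling it from $P_{V,A}$ for
  the model-selection test.
* `gen_flask_image()` — 512×512 px, calibration circle radius 220 px
  (8.5 cm flask), 5 bundled disks (radius 15–30 px) + 50 scattered specks
  (1–3 px), background 0.08 with a 0.08 left-right gradient, material at
  0.85 in the blue channel, noiseless by default. The rim ring is rendered
  only in the red/green channels (a rim reflection), keeping the
  segmentation channel clean; calibration uses the circle metadata.
  Ground-truth areas are counted on the rasterised mask, not from
  $\pi r^2$, so pipeline errors are attributable to the pipeline.
* `gen_coloc_field()` — 256×256 px disk ROI (radius 100 px), 25 cell blobs,
  stain planted on exactly `round(f * n_cellfree)` cell-free pixels (exact
  pixel accounting; the sidecar reports the achieved percentage), intensity
  noise SD 0.05 by default.

Passing on these fixtures shows the pipelines are correct on their own
terms — exact bookkeeping, calibrated statistics, recoverable planted
structure. It does not show robustness to what real flask photographs
contain and the generators deliberately omit: glare and reflections,
lens/wall distortion, touching or translucent material, uneven
illumination beyond a linear gradient, and stain bleed-through. Parameters
exposed for those cases (smoothing, fixed thresholds, explicit ROI) are
provided but their defaults are tuned to the synthetic conditions.

## Numerical choices and problem sizes

Percentiles are type-7 (linear interpolation) throughout. Root finding uses
$10^{-13}$-scaled interval tolerance and verifies the $10^{-9}$ contract on
the achieved value. Connected components are 8-connected (EBImage's
4-connected labelling plus an exact diagonal-merge pass). The test-suite
problem sizes — 100-condition round-trip sweeps, 512² images, 100
Monte-Carlo fit replicates at n = 30 — were chosen so each acceptance
property exercises the estimator where its behaviour is visible (the
Monte-Carlo calibration showed the half-max band covers the true peak in
~100/100 replicates at 10% noise, so the ≥95 criterion has margin); the
whole suite runs in well under a minute.

## Known limitations

* The model is the printed correlations, nothing more: no CFD, no
  oxygen-uptake or growth coupling, no shear-damage term.
* $k_L$ and $a$ are never separated; only their product is modelled.
* The segmentation is a deterministic stand-in with the same class
  semantics as the original trained classifier, not an emulation of its
  feature set; absolute sizes from real photographs will depend on its
  parameters.
* The 0.72–1.65 mW m²/s band ships as a configuration constant; the
  fitting module recovers bands from condition–size data supplied by the
  user, it does not re-derive the default.
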