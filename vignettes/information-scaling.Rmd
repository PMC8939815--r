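---
title: "How much information does a centimetre-scale NDVI map really carry?"
author: "ndviscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How much information does a centimetre-scale NDVI map really carry?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndviscale)
```

## The question

Drone surveys of a wheat field deliver NDVI at a grain of ~10 cm — tens of
millions of pixels — while the measurements a producer acts on arrive at far
coarser grains: a combine harvester integrates yield and grain protein content
(GPC) over a 12 m header, and satellite products sit at 30 m. `ndviscale`
quantifies what is kept and what is lost when the fine map is averaged to
those working grains, using three complementary instruments:

1. **Moment scale profiles.** Block-averaging with an $f \times f$ pixel
   operator and tracking the variance, the fraction of native-grain variance
   lost, and the skewness of the aggregated image as the grain grows.
2. **Distributional information loss.** NDVI on $(0,1)$, when unimodal, is
   well described by a Beta$(\alpha,\beta)$ distribution. Fitting the native
   image (parameters $\alpha,\beta$) and each aggregated image
   ($\alpha',\beta'$) gives a closed-form Kullback–Leibler divergence
   $$D_{KL} = \ln\frac{B(\alpha',\beta')}{B(\alpha,\beta)}
     + (\alpha-\alpha')\psi(\alpha) + (\beta-\beta')\psi(\beta)
     + (\alpha'-\alpha+\beta'-\beta)\,\psi(\alpha+\beta),$$
   with $B$ the beta function and $\psi$ the digamma function. The
   orientation is fixed as KL(native ‖ averaged): the curve reports how badly
   the averaged-image distribution encodes the native one. Units are nats.
3. **Spectral scaling.** The radially-averaged power spectral density of each
   image, interpreted through the power law $Y = c\,k^{b}$. We always report
   $b$ as the *signed* log–log slope, so a red spectrum (variance
   concentrated at large scales) has $b < 0$; verbal conventions in the
   literature mix the sign.

Around these sit the linkage steps: 1 m × 12 m rectangular footprints match
each harvester record to the imagery, exhaustive all-subsets OLS with AIC and
Akaike weights selects among per-date and seasonal-sum NDVI predictors of
yield and GPC, and a multi-temporal k-means zoning splits the field into
ranked trajectory zones.

Because no real field dataset ships with the package, a seeded synthetic
generator provides inputs with *known* marginals, spectra, coherence and
regression structure; every analysis step is validated against that known
structure in the test suite.

## The synthetic field generator

`synthesize_grid()` builds a Gaussian random field by spectral synthesis:
white Gaussian noise is Fourier-filtered with amplitude $\propto k^{-b/2}$
(so the power spectrum falls as $k^{-b}$), with the DC coefficient set to
zero — the mean is injected later through the marginal, which avoids the
$k = 0$ singularity. Spectral phases are exactly uniform. The latent field is
then pushed onto the requested Beta marginal by a *rank-based* probability
integral transform: the $n$ latent values are replaced by the $n$ Beta
quantiles at probabilities $(r_i - 0.5)/n$. Two properties follow:

* **Marginal fidelity is exact by construction** — the output is the Beta
  quantile set at any spectral exponent. A pointwise normal-CDF transform
  would instead inherit the realization noise of the latent field, which for
  steep spectra (few effective degrees of freedom) visibly distorts one
  realization's histogram.
* **The spectrum is only approximately preserved** — any monotone marginal
  transform bends the spectrum slightly. Empirically the fitted exponent
  stays within ±0.15 of $-b$ for $b \in [0, 3.5]$ at $512^2$, which is the
  tolerance the tests assert.

`synthesize_season()` shares one latent noise field across dates with
variance weight `coherence` (per-date independent noise takes the
complement), so `coherence = 1` with equal exponents gives rank-identical
dates and `coherence = 0` independent ones. Note one subtlety we verified
while testing: for strongly red spectra the effective number of independent
patches is small, so even *independent* dates show inter-date Spearman
correlations of a few hundredths in a single realization; the strict
$1/\sqrt{n}$ bound only applies near the white end.

The bundled preset (`wheat_season_spec()`) emulates a four-date winter-wheat
season: ordinal days 140, 160, 183, 202; Beta marginals moment-matched to
means 0.91, 0.88, 0.44, 0.27 with standard deviations 0.014, 0.025, 0.063,
0.011; spectral exponents 2.0, 2.3, 2.4, 3.2; coherence 0.8; pixel size
0.1343 m. Moment matching alone reproduces the expected negative skew of the
early, nearly saturated dates (a Beta with mean 0.91 is strongly
left-skewed), so no separate skew adjustment is applied. The preset is a
realistic default for exercising the machinery, not a dataset to reproduce.

`synthesize_harvest()` lays serpentine north–south passes one swath width
(default 12 m) apart, one record per metre of travel, and draws yield and GPC
as linear functions of the per-date *footprint-mean* NDVI plus Gaussian
noise. The footprint means come from the same `extract_buffer_means()` the
analysis uses, so generator and analysis share a single footprint definition
and a noiseless simulation is recovered exactly by OLS. Noise can be given
directly (`noise_sd_*`) or via a true-model $R^2$ target, in which case
`sd(noise) = sd(signal)\sqrt{(1-R^2)/R^2}` for the realized signal. Yield
units are treated as opaque: the preset coefficients set plausible magnitudes
and signs (including a negative mid-June GPC term), nothing downstream
depends on the unit.

What the generator does **not** emulate: georeferencing error, radiometric
drift between flights, cloud or shadow artifacts, anisotropy (row direction
effects), harvester sensor lag, or yield-monitor cleaning. Tests passing on
synthetic fields show the estimators are correct under the stated model; they
do not certify behavior under those real-data pathologies.

## Raster model and I/O choices

Grids are square-pixel, single-band matrices with `NA` for missing cells; row
1 is the northern edge, map x grows east, y grows north, and the origin is
the outer NW corner. Dates are integer ordinal days — sub-daily flight timing
is ignored, and calendar labels are the caller's business (the package takes
no position on date bookkeeping disputes in source material).

File I/O uses the ESRI ASCII grid format: a standard georeferenced raster
interchange format that is plain text, carries an explicit nodata sentinel,
and — because it has a single `cellsize` — enforces square pixels
structurally. Values are printed with 17 significant digits, so doubles
round-trip bit-exactly.

Two 50% rules handle ragged field boundaries, chosen once and used
everywhere: an aggregated cell (or resampled cell) is valid only if at least
half its area/cells are valid, and a harvester footprint is kept only if it
captures at least half its expected pixel count. Resampling onto the
coarsest geometry is *area-weighted* averaging (not nearest-neighbour),
consistent with the aggregation semantics of the rest of the package;
partial edge blocks are dropped rather than padded, since padding would bias
block means.

## Numerical choices

* **Beta MLE** (`fit_beta_mle`): Newton iteration on the exact score and
  Hessian (digamma/trigamma), started at the method-of-moments estimate,
  with step halving to keep parameters positive and the likelihood
  non-decreasing; convergence at score norm $<10^{-8}$ (per observation) or
  step $<10^{-10}$, cap 500 iterations. Sample values are clamped to
  $[10^{-6}, 1-10^{-6}]$ first: saturated canopy pixels sit exactly at 1 and
  the log-likelihood diverges there. A zero-variance sample is an error.
* **Radial PSD** (`radial_psd`): invalid cells are filled with the valid
  mean (zero-filling would inject a spurious field-boundary edge), the mean
  is removed, an optional Hann taper applied (default on; all Parseval
  checks run untapered), and power is normalized as $|F|^2/N^2$ so the
  untapered non-DC total equals the population variance of the mean-removed
  image — that identity pins the normalization to machine precision and is
  asserted in the tests. Wavenumbers are cycles per metre (no $2\pi$). Bins
  are integer multiples of $\Delta k = 1/(L\cdot\text{pixel})$ with bin
  centre the mean radius of member lattice cells, which avoids empty low
  bins.
* **Power-law fits** (`fit_power_law`): plain OLS of $\ln Y$ on $\ln k$ over
  the requested range, as stated. **Scale-break search**
  (`find_scale_break`) is the one place weights enter: the greedy
  two-segment search weights each bin by its annulus member count, because
  the handful of low-$k$ bins average very few lattice cells and their
  enormous log-power variance otherwise hands the split a spurious 10–50%
  error improvement on perfectly single-exponent spectra. With
  count-weighting, single-exponent syntheses improve by only 1–4% (below
  the 5% flag threshold) while a genuine two-exponent field improves by
  ~90% and its break frequency is recovered within a few percent.
* **AIC** (`all_subsets_lm`): $n\ln(\mathrm{RSS}/n) + 2(p+2)$, counting the
  intercept and the error variance. AIC rather than AICc: with $n$ in the
  thousands the difference is under 0.01 and the formula stays transparent.
  RSS is floored at $10^{-24}\cdot\mathrm{TSS}$ so that exact fits rank by
  the parameter penalty instead of by rounding noise in $\ln \mathrm{RSS}$.
  Seasonal sums are offered as single candidates and never co-occur with
  their own addends (or each other) — those combinations are collinear by
  construction; the two model families are compared, not mixed. A caution
  learned from the package's own experiments: when nested supersets of the
  true model are candidates, each spurious extra predictor retains Akaike
  weight $\approx e^{(\chi^2_1-2)/2}$, so the *true* model's weight
  concentrates near 0.5 rather than 1 no matter how large $n$ is — read
  "weight of the top model" with that ceiling in mind.
* **Footprints** (`make_buffer`): the ambiguous "1 × 12 m" is resolved as
  12 m *across* the travel direction (the header's cut width) and 1 m along
  it (the per-record advance). Headings come from consecutive points of the
  same pass; the last point of a pass inherits its predecessor's heading.
  Pixel membership is by pixel centre, not area weighting: at ~0.13 m pixels
  inside a 12 m² polygon the discretization error is negligible and the
  rule is exactly reproducible.
* **Zoning** (`kmeans_stack`, `group_classes`): k-means on per-pixel
  multi-date vectors, k-means++ seeding from the given seed, 10 restarts,
  best within-SS kept; pixels missing on any date are excluded
  (complete-case, matching the stack intersection used elsewhere). The
  original workflow's expert grouping of 50 classes into 3 is replaced by a
  reproducible rule: classes are ranked by class-mean seasonal NDVI sum and
  cut into equal-rank tiers, ties broken by class index. This recovers
  "high/medium/low trajectory" semantics from the data alone.

## What the tests assert, and at what sizes

The suite validates each instrument against an independent oracle: Beta KL
against adaptive quadrature (100 random parameter pairs in $[0.5,50]^2$,
agreement to $10^{-6}$); the MLE against known shapes at $n = 10^5$ (2%
recovery) and against an independent fitting package; Parseval to $10^{-8}$;
spectral exponents by round-trip through the synthesizer at $512^2$ (±0.15);
the i.i.d. aggregation laws ($\sigma^2/f^2$ variance, CLT-rate skewness) at
$1024^2$, where the $f=16$ block count (4096) keeps the sampling error of a
variance estimate near 2%; break detection at $512^2$ with a break planted
at 6 cycles m⁻¹; selection consistency on a ~2000-point synthetic harvest;
the slope test's type-I error over 200 null replicates; and a deterministic
end-to-end pipeline run at $256^2$. These sizes are the package's chosen
study conditions and are deliberately inherited by `scripts/acceptance.R`.

## Known limitations

* The rank-PIT spectral distortion is uncharacterized beyond the empirical
  ±0.15 band; extreme marginal skew bends steep spectra the most.
* `resample_to_coarsest` assumes co-projected inputs; there is no CRS
  handling or reprojection.
* Spatial autocorrelation is ignored in all regression inference, as in the
  workflow the package reproduces; p-values on real transect data will be
  anti-conservative.
* The Beta fit is asserted, not tested: no goodness-of-fit check guards
  against multimodal NDVI (e.g. exposed soil plus canopy).
* The KL curve for marginals very close to the support boundary (late-season
  mean 0.27 with sd 0.011 is benign, but a mean of 0.99 would not be) can
  overflow `lbeta` for huge aggregated shape parameters; the function
  reports this as an error rather than returning nonsense.
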