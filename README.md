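# ndviscale

High-resolution drone surveys of crop fields produce vegetation-index (NDVI)
maps at a grain of centimetres — orders of magnitude finer than the scales at
which decisions are made: a combine harvester reports yield and grain protein
content (GPC) over a 12 m header, and satellite NDVI arrives at 30 m.
`ndviscale` is for agronomists and remote-sensing researchers who want to ask,
quantitatively: *how much of the fine-scale map survives averaging to a
working grain, and which acquisitions actually predict yield and protein?*

The package measures information content three ways as the spatial grain
`f × pixel` grows:

* **Moment profiles** — block-average the image and track variance, the
  fraction of native-grain variance lost, and skewness.
* **Distributional information loss** — NDVI on (0, 1) is fit by a
  Beta(α, β) distribution (maximum likelihood); the divergence between the
  native-grain fit and each aggregated-grain fit (α′, β′) has the closed form

  ```
  D_KL = ln[B(α′,β′)/B(α,β)] + (α−α′)ψ(α) + (β−β′)ψ(β) + (α′−α+β′−β)ψ(α+β)
  ```

  in nats, with B the beta function and ψ the digamma function, oriented as
  KL(native ‖ averaged).
* **Spectral scaling** — the radially-averaged power spectral density
  `Y = c·k^b` of each image, with `b` reported as the signed log–log slope,
  plus a two-segment search for a spectral scale break.

Linkage tools connect imagery to harvester records (1 m × 12 m oriented
footprint means, exhaustive all-subsets OLS with AIC and Akaike weights,
per-date simple regressions) and a multi-temporal k-means zoning splits the
field into ranked high/medium/low trajectory zones. A seeded synthetic
generator — power-law Gaussian random fields mapped onto Beta marginals, with
serpentine harvester transects — supplies inputs with known structure, so
every estimator is testable end to end. Rasters are read and written as ESRI
ASCII grids; tables as CSV.

## Worked example

Simulate one date of a wheat season (Beta(148, 20) marginal, spectral
exponent 2.3, 0.25 m pixels), then profile it across grains up to and beyond
the 12 m harvester scale:

```r
library(ndviscale)
fs <- wheat_season_spec(shape = c(256, 256), pixel_size = 0.25, seed = 1)
season <- synthesize_season(fs)
g <- season$grids[[2]]                       # the day-160 image

prof <- scale_profile(g, scale_factor_ladder(g, target_lengths = c(12, 30)))
prof[c(1, 6, 12), c("factor", "grain_length", "variance",
                    "variance_loss_fraction", "skewness")]
#>    factor grain_length variance variance_loss_fraction skewness
#> 1       1         0.25 0.000625                 0.0000 -0.35761
#> 6       8         2.00 0.000438                 0.2984 -0.15035
#> 12     48        12.00 0.000187                 0.7014 -0.29692
```

Variance decays smoothly with grain — on this 64 m synthetic field about 70%
of the native variance is averaged out by the time the grain reaches the
12 m harvester footprint — and the negative skew of the nearly saturated
canopy is progressively smoothed. The same ladder through the
Kullback–Leibler lens:

```r
kl <- kl_scale_curve(g, scale_factor_ladder(g, target_lengths = c(12, 30)))
kl[c(1, 6, 12), ]
#>    factor grain_length alpha_prime beta_prime    d_kl
#> 1       1         0.25         148       20.2 0.00000
#> 6       8         2.00         209       28.5 0.03396
#> 12     48        12.00         503       68.7 0.59802
```

The aggregated fits drift toward ever more concentrated Beta distributions
(α′ + β′ grows roughly as f²), and `d_kl` quantifies, in nats, how badly the
coarse-grain distribution encodes the native one. Finally the spectrum:

```r
sp <- radial_psd(g, taper = FALSE)
fit_power_law(sp, c(2 * attr(sp, "delta_k"), 1))
#> <power_law_fit> power = 2.507e-09 * k^-2.298 over k in [0.03125, 1] (R2 = 0.996, 63 bins)
```

The fitted slope −2.298 recovers the exponent (2.3) the field was synthesized
with: a red spectrum whose variance lives at large spatial scales, which is
exactly why coarse grains retain most of the field's structure.

`run_info_pipeline(out_dir, seed)` chains everything — simulate, write
rasters, co-register, interpolate daily, seasonal sums, profiles, KL curves,
spectra with break detection, a simulated harvester run with AIC model
selection for yield and GPC, and three-zone classification — into one
deterministic, all-text output directory.

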