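# pedoconverge

Does urbanization homogenize soils — not just at the managed surface, but
meter-deep? `pedoconverge` is an R package for answering that question from
paired field descriptions: urban soil cores matched to the pre-urban
reference soil series that occupied the site before development. It is
aimed at soil scientists and urban-ecosystem researchers working with
horizon-level data (USDA texture class, Munsell color value, optional
measured total carbon).

## What it computes

Starting from a horizon table (one row per described layer) and a pairing
table (urban pedon ↔ reference series), the package:

1. **Slices** each profile to 1-cm resolution over 0–150 cm
   (`slice_profiles()`): slice *i* takes the value of the horizon containing
   depth *i* + 0.5 cm; no interpolation, no extrapolation below the deepest
   horizon.
2. **Quantifies** the two properties per slice: texture class → triangle
   centroid → geometric mean particle diameter
   `exp(0.01 Σ pᵢ ln dᵢ)` (mm); Munsell value → total carbon via the
   log-linear pedotransfer `ln C = 5.07 − 0.58·value` (g C/kg, natural log).
3. **Summarizes vertical structure** with the Index of Profile Anisotropy
   (`compute_ipa()`): `IPA = Σ|xᵢ − μ| / μ`, 0 for a uniform profile, with
   per-property minimum floors (13.6 / 10.7) replacing quantization-induced
   zeros before urban:reference ratios are formed.
4. **Tests convergence** per depth slice (`fit_slice_regressions()`) by OLS
   of `ln(urban/reference)` on `ln(reference)` pooled over pairs. A negative
   slope means urbanization pulls the property toward a common level; the
   **point of convergence** is the reference value where the fitted ratio
   is 1, `exp(−intercept/slope)`. The same regression on whole-profile IPA
   values (`ipa_convergence_regression()`) tests convergence of profile
   structure itself.
5. **Fits the universal urban profile** through the 150 per-depth
   convergence points: a quartic in (orthogonalized) depth for
   `ln(particle size)` and `C(x) = C₀·exp(−kx)` for carbon.

A synthetic paired-pedon generator (`generate_dataset()`) produces datasets
with known convergence targets and pull strengths — values are round-tripped
through texture classes and integer Munsell chips so the analysis path sees
realistic quantization — giving every stage a ground truth to be tested
against.

## Worked example

```r
library(pedoconverge)

res <- run_pipeline(synthetic = synthetic_config(n_pairs = 120, seed = 2))

res$ipa_convergence$particle_size_mm
#> IPA convergence regression: ln(urban/reference IPA) ~ ln(reference IPA)
#>   property: particle_size_mm, n = 120 pairs
#>   intercept = 0.059, slope = -0.100, F(1,118) = 2.2, p = 0.141
#>   converged IPA = 1.8

res$profile_models$carbon
#> Exponential carbon profile: C(x) = 18.44 * exp(-0.00608848 * x)  [g C/kg, x in cm]

head(res$slice_fits$carbon_g_per_kg[, c("depth_cm", "n_pairs", "intercept",
                                        "slope", "p_value",
                                        "convergence_point")], 4)
#> # A tibble: 4 × 6
#>   depth_cm n_pairs intercept  slope  p_value convergence_point
#>      <int>   <int>     <dbl>  <dbl>    <dbl>             <dbl>
#> 1        0     120      1.22 -0.426 8.50e-21              17.6
#> 2        1     120      1.22 -0.426 8.50e-21              17.6
#> 3        2     120      1.22 -0.426 8.50e-21              17.6
#> 4        3     120      1.22 -0.426 8.50e-21              17.6
```

The synthetic data were generated with pull strength `b = 0.5` toward a
carbon target of `18.4·exp(−0.005868x)` g/kg: the per-slice regressions at
the surface recover a convergence point of 17.6 g/kg against a generating
target of 18.3 g/kg at that depth, and the exponential profile model fitted
through all 150 recovered points lands on `C₀ = 18.44`, `k = 0.00609` —
within quantization and noise of the generating parameters. Each slice fit
also reports its Benjamini–Hochberg adjusted p-value (`p_bh` column). The
whole-profile IPA regression is near-null here because the generator pulls
property *values*, which compresses profiles only mildly at `b = 0.5`.

`autoplot()` methods draw the converged profiles and the IPA regression;
`tidy()`/`glance()` give broom-style summaries of every fitted object.

## Layout

* `R/` — implementation (profiles, texture, carbon pedotransfer, IPA,
  convergence, synthetic generator, IO/pipeline, plots)
* `tests/testthat/` — unit, property and end-to-end suites
* `vignettes/urban-soil-convergence.Rmd` — the methods vignette: model,
  assumptions, generator design, numerical choices, limitations
* `data-raw/texture_centroids.R` — regenerates the packaged USDA
  texture-class centroid table (`inst/extdata/usda_texture_centroids.csv`)
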