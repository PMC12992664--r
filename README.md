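# numprf

Numerosity population receptive-field (pRF) modelling for
cortical-surface fMRI, in R.

Some cortical populations are tuned to *numerosity* — the number of
items in a stimulus, whether dots in an array or beeps in a sequence —
and in several association areas these preferences are laid out
topographically as *numerotopic maps*. `numprf` implements the full
analysis chain used to find and characterize such maps from per-vertex
BOLD time series, for researchers running numerosity-mapping
experiments or benchmarking tuning-model estimators:

1. **Design**: the ascending/descending block design
   (1–2–3–4–5–20–5–4–3–2–1–20, four cycles per 145-volume run at
   TR 2.1 s) and its numerosity-versus-time function.
2. **Forward model**: log-Gaussian neuronal tuning
   `z = exp(−½((ln x − ln μ)/σ_log)²)` with FWHM
   `ω = 2μ·sinh(√(2 ln 2)·σ_log)`, convolved with the canonical
   double-gamma HRF and sampled at slice-time-corrected volume times
   (`y = β·s + β₀ + ε`).
3. **Estimation**: percent-signal-change conversion, 12-regressor
   confound removal, run averaging, exhaustive grid-search maximum
   likelihood over 89 × 60 (μ, σ_log) combinations, split-half (odd/even
   runs) cross-validated R², F-test `F = (R²/(p−1))/((1−R²)/(n−p))` with
   Bonferroni correction over vertices, and selection of vertices with
   β̂ > 0, 1 ≤ μ̂ ≤ 5 and significant cvR².
4. **Topography**: connected supra-threshold clusters, triangle surface
   areas, assignment to reference map centers, binned area/width
   correlations, an order-5 cross-validated polynomial coordinate model,
   and per-map numerosity ranges.
5. **Group level**: participant count maps, linear mixed-effects models
   of area and tuning width versus preferred numerosity, and a
   categorical six-condition control GLM with a "1–5 minus 20" contrast.
6. **Synthetic subjects**: a generator planting known tuning, a
   numerotopic gradient and area/width geometry on a planar mesh, plus
   `recovery_report()` for sensitivity/specificity/RMSE scoring — so the
   whole pipeline is testable offline with known ground truth.

Everything is tidyverse-shaped: long tibbles in, tibbles out, `tidy()` /
`glance()` methods, `autoplot()` for each result type.

## Worked example

```r
library(numprf)

schedule <- build_run("visual")          # 4 cycles, 145 volumes, TR 2.1 s
subject  <- simulate_subject(schedule, nx = 40, ny = 25,
                             noise_sd = 0.5, n_runs = 8, seed = 42)
fit <- fit_prf(subject$data, schedule, n_comparisons = 1e5)
glance(fit)
#> # A tibble: 1 × 7
#>   n_vertices n_selected r2_threshold max_cv_r2 median_mu_selected n_runs space
#> 1       1000        486        0.162     0.989                2.2      8 log
```

Of 1000 vertices (500 carrying a planted tuning gradient, 500 pure
noise), 486 pass all three selection filters at the Bonferroni-corrected
variance-explained threshold of R² = 0.1625 (α = 0.05, corrected for
100,000 comparisons); the best vertex reaches cvR² = 0.99.

```r
recovery_report(fit, subject$truth)
#>   stratum n_tuned n_null sensitivity specificity  mu_bias mu_rmse omega_rmse
#> 1 all         500    500       0.972           1 -0.00177  0.0519      0.231
```

97% of truly tuned vertices are detected, no null vertex is falsely
selected, and preferred numerosity is recovered essentially without bias
(RMSE 0.05, the grid step).

```r
sel <- fit$selected
geometry_correlations(tibble::tibble(
  mu   = fit$mu_hat[sel],
  fwhm = fit$omega_hat[sel],
  area = vertex_areas(subject$mesh)[fit$vertex[sel]]))
#> <nprf_geometry> 8 occupied bins
#>   area  ~ preferred numerosity: r = -0.917
#>   FWHM  ~ preferred numerosity: r = 0.999
```

The planted cortical geometry is recovered: surface area shrinks with
preferred numerosity (r = −0.92 across the eight 0.5-wide bins) while
tuning width grows (r = 0.999). The planted spatial gradient is likewise
recovered by the coordinate model:

```r
co <- subject$mesh$coordinates[fit$vertex[sel], ]
coordinate_polynomial_model(tibble::tibble(
  x = co[, 1], y = co[, 2], z = co[, 3], mu = fit$mu_hat[sel]), seed = 1)
#> <nprf_coordfit> order-5 coordinate model, 10-fold CV
#>   cv-r = 0.999  MAE = 0.0319
```

## Documentation

The methods vignette (`vignettes/numerosity-prf.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, the numerical conventions (microtime grid, convolution edges,
tie-breaks, quartiles), what the synthetic generator does and does not
emulate, and known limitations.
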