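---
title: "Numerosity population receptive-field modelling with numprf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerosity population receptive-field modelling with numprf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numprf)
```

## The model

Cortical populations that respond to the number of items in a stimulus —
dots in an array, beeps in a sequence — behave like receptive fields over
an abstract "numerosity axis". `numprf` models the aggregate response of
the population sampled by one surface vertex as a Gaussian in
*logarithmic* numerosity space:

$$z_t = \exp\!\left[-\tfrac{1}{2}\left(\frac{\ln x_t - \ln\mu}{\sigma_{\log}}\right)^2\right]$$

where $x_t$ is the numerosity presented at time $t$, $\mu$ is the
*preferred numerosity* (the stimulus eliciting the peak response) and
$\sigma_{\log}$ the tuning width in log space. Log-Gaussian tuning
captures the Weber-like compression seen in single-unit recordings:
responses fall off symmetrically in ratio, not in difference. Tuning
width is reported on the linear axis as the full width at half maximum,

$$\omega = e^{\ln\mu + \sqrt{2\ln 2}\,\sigma_{\log}} - e^{\ln\mu - \sqrt{2\ln 2}\,\sigma_{\log}}
         = 2\mu\sinh(\sqrt{2\ln 2}\,\sigma_{\log}),$$

so that a vertex preferring 3 items with $\omega = 2$ responds at half
its peak to roughly 2 and 4 items. A linear-Gaussian variant
(`tuning_response_linear()`, $\omega = 2\sqrt{2\ln 2}\,\sigma_{lin}$) is
included as a control model only; on log-Gaussian data it systematically
loses the cross-validated model comparison (this is one of the package's
acceptance properties).

The neuronal response is linked to the measured BOLD signal through a
linear time-invariant forward model: $z_t$ is evaluated on a fine
microtime grid, convolved with the canonical double-gamma hemodynamic
response function $h$, sampled at the volume acquisition times, and
scaled,

$$s_t = z_t * h(t), \qquad y_t = \beta s_t + \beta_0 + \varepsilon_t,$$

with $\varepsilon_t$ i.i.d. Gaussian. Serial correlations are
deliberately not modelled; generalized least squares does not improve
tuning-parameter estimates in this design and the i.i.d. likelihood
keeps the grid search exact and fast. The AR(1) option of the simulator
exists precisely to probe this robustness.

## The experimental design

`build_run()` constructs the block design the analysis assumes:
numerosities 1–5 ascending, a twenty-item baseline block, 5–1
descending, and a second twenty-item block (1–2–3–4–5–20–5–4–3–2–1–20),
repeated four times per run. Small-numerosity blocks hold six stimulus
events (visual: 300 ms on / 400 ms off; auditory: 500 ms on / 200 ms
off), so every block lasts 4.2 s; baseline blocks last 16.8 s. A run is
145 volumes at TR 2.1 s (304.5 s) with 2.1 s of stimulus-free padding
after the fourth cycle, and a session of 8 runs presents each small
numerosity exactly 384 times. The twenty-item baseline enters the
stimulus function as numerosity 20 — it is a modelled condition (the
tuning curve is evaluated there, and the categorical control GLM treats
it as its sixth regressor), not an "off" state; its role is to let
responses of low-preferring populations return to baseline.

Two timing conventions are supported for the neuronal regressor.
The default is a block-level boxcar: the sub-second gaps between events
are invisible at the BOLD time scale. `event_level = TRUE` switches to
event-level boxcars (stimulus-on windows only; a 3/7 duty cycle for the
visual timing). For the auditory baseline block only the total 16.8 s
(8 events) is fixed by the design; the package fills it with 2.0 s
event windows separated by 0.1 s, and the sub-event tone micro-timing
(60 ms tones, 40 ms gaps) is not modelled at all — numerosity, not tone
onsets, is the modelled quantity.

## Numerical choices in the forward model

* **Microtime grid** `dt = 0.1` s = TR/21. It divides the TR and every
  event duration evenly; `numerosity_timecourse()` enforces the
  divisibility.
* **HRF**: double-gamma with peak delay 6 s, undershoot delay 16 s, unit
  dispersions, peak:undershoot ratio 6, 32 s support, normalized to peak
  amplitude 1 (`canonical_hrf()`). Amplitude normalization only rescales
  $\beta$; cross-validated $R^2$, F statistics and selection are
  invariant to it.
* **Convolution** is causal with a zero-padded start and is truncated to
  the run length; the convolution sum is scaled by `dt` so it
  approximates the continuous integral and is stable under grid
  refinement.
* **Sampling**: volumes are read off at $k\,\mathrm{TR} + 1.025$ s, the
  slice-timing reference of the acquisition, by linear interpolation on
  the microtime grid (1.025 s is not a multiple of `dt`).
* Internally, every predicted time course is a linear combination of six
  per-numerosity-level convolved boxcars (`condition_regressors()`), so
  the full grid of predictions is two small matrix products. This
  factorization is exact (it is tested against per-grid-point
  convolution) and is what makes exhaustive search cheap.

## Signal conditioning

`condition_timeseries()` fixes the preprocessing order: each run is
standardized to percent signal change, $100(y/\bar y - 1)$, then twelve
confound regressors are removed by OLS (six motion parameters; white
matter, CSF and global signal; three cosine drift terms). Residuals keep
zero mean — the intercept is part of the confound model and $\beta_0$
absorbs any offset downstream. The cosine basis uses the three lowest
non-constant DCT-II terms: on a 304.5 s run these capture drifts slower
than ~1.5 cycles per run. (A classical 128 s high-pass cutoff would
admit a fourth term; `cosine_drift_basis(n_terms =)` makes that choice
explicit and overridable.) Runs are averaged pointwise across runs — but
never across the four stimulation cycles — before model estimation.

## Estimation, cross-validation, selection

`fit_prf()` evaluates every combination of a parameter grid: $\mu$ from
0.8 to 5.2 in steps of 0.05 (89 values) and $\sigma_{\log}$ from 0.05 to
3.0 in steps of 0.05 (60 values), 5340 models per vertex. The grid
extends 0.2 beyond the presented range on both sides so that boundary
preferences can be detected and filtered rather than silently clipped.
The $\sigma_{\log}$ bound of 3.0 spans linear tuning widths from
$\omega = 0.12$ to $34.17$ at $\mu = 1$ and $0.59$ to $170.9$ at
$\mu = 5$ — wider than any numerosity tuning that is distinguishable
from a categorical response in this stimulus set. For each grid point,
$\beta$ and $\beta_0$ are estimated by OLS and scored by the Gaussian
log-likelihood at the ML variance; under i.i.d. errors the argmax equals
the RSS minimizer. Exact ties (possible only in degenerate data) go to
the first grid point in ($\mu$ ascending, $\sigma_{\log}$ ascending)
scan order and are reported via a message.

Model fit is assessed out of sample. Runs are split into odd
(1, 3, 5, 7) and even (2, 4, 6, 8) halves; tuning parameters estimated
on one half's average generate a predicted time course whose baseline
and scaling — the model's only two free parameters at this stage — are
re-estimated by OLS on the other half's average, giving an $R^2$;
cvR² is the mean over the two directions. Because $\beta_0, \beta$ are
refit on the test half, cvR² lies in $[0, 1]$; the F machinery
(`f_from_r2()`) nevertheless extends monotonically to negative inputs
for use with externally supplied predictions. Significance uses

$$F = \frac{R^2/(p-1)}{(1-R^2)/(n-p)}, \qquad n = 145,\; p = 2,$$

($\mu, \omega$ are not counted: they come from independent data) and a
Bonferroni-corrected level $\alpha / n_\text{vertices}$. Inverting the F
quantile gives the variance-explained threshold
`r2_threshold()` — 0.1625 at $\alpha = 0.05$ with 100,000 vertices. A
vertex is *selected* when $\hat\beta > 0$ (otherwise "preferred"
numerosity would be the response minimum), $1 \le \hat\mu \le 5$
(otherwise tuning is monotone over the presented range), and cvR²
exceeds the threshold. Reported maps use $\hat\mu, \hat\omega$ from the
all-run average fit, while significance comes from the split-half
procedure; the alternative (averaging the two half-fits) is available by
calling `split_half_cv()` directly, whose output carries both half
estimates.

## Cortical geometry

Selected vertices are clustered by direct mesh connectivity
(`connected_clusters()`; edge distance 1). Cluster area is the sum of
triangles whose three nodes all lie in the cluster
(`cluster_surface_area()`), so boundary triangles do not count and
splitting a cluster loses area — an intentional, conservative
convention. Clusters are assigned to numerotopic maps
(`assign_maps()`) when they exceed a minimum area (defaults: 50 mm²
visual, 25 mm² auditory) and come within a maximum distance (25 mm
visual, 50 mm auditory) of a user-supplied table of reference map
centers; cluster-to-center distance is the minimum over cluster
vertices, assignment goes to the nearest eligible center, and exact
ties break to the earlier table row. Reference centers are inherently a
user input (they come from prior mapping work in standard space); the
package ships none. A cluster spanning several centers is assigned
whole to its nearest one — it is not split.

For binned summaries (`geometry_correlations()`), preferred
numerosities are partitioned into eight half-open bins of width 0.5 from
1 to 5 (the last bin closed at 5). "Area devoted to a bin" uses
per-vertex area shares — each triangle contributes a third of its area
to each node (`vertex_areas()`) — because strict all-interior-triangle
areas would discard every bin-boundary triangle in a smooth gradient.
Topographic organization within a map is quantified by
`coordinate_polynomial_model()`: preferred numerosity regressed on pure
powers (no cross terms) of the mean-centered pial coordinates up to
order 5 (16 design columns), with 10-fold cross-validation over a seeded
random vertex partition; design columns are standardized internally for
conditioning, which leaves predictions unchanged and makes the model
exactly invariant to rigid translations. Per-map numerosity ranges
(`numerosity_range()`) use type-7 (linear interpolation) quartiles and
the 1.5 IQR whisker rule.

## Group-level statistics

`mixed_effects_geometry()` fits, by REML,

`area (or fwhm) ~ hemi + hemi:mu + (1 | subject)`

with hemisphere as a two-level factor (L reference): one hemisphere main
effect plus *hemisphere-specific* slopes of binned preferred numerosity,
reported with Wald z statistics and normal-approximation 95% CIs. REML
is the standard small-sample choice for variance components; with a
singular or failed random-effects fit the function falls back to pooled
OLS with a warning. The categorical control analysis
(`categorical_glm_contrast()`) asks whether responses merely distinguish
"small" (1–5) from "many" (20): six convolved condition regressors plus
confounds, contrast weights $(1/5, \ldots, 1/5, -1)$ (checked to sum to
zero), followed by a per-vertex one-sample t-test across subjects
(`group_t_test()`) reporting both one-sided tails.

## The synthetic-data generator

There is no packaged real dataset; every claim the test suite makes is
established on synthetic subjects with known ground truth.
`simulate_subject()` builds a planar grid-triangulated mesh (1000
vertices by default) — chosen over a sphere because every triangle area
is known analytically — with one contiguous tuned patch covering half
the sheet. Within the patch, true $\mu$ rises from 1 to 5 along x; with
the default convex ("shrinking") gradient, successive numerosity bins
occupy geometrically shrinking bands, planting the negative
area-versus-numerosity relationship. True FWHM follows
$\omega = 1 + \mu$, planting the positive width gradient. Vertices
outside the patch are null. Noise is i.i.d. Gaussian in PSC units;
defaults are $\beta = 1$ and `noise_sd = 0.5`, a visual-like
signal-to-noise ratio (per-condition signal change of a few percent
against sub-percent averaged noise); auditory-like subjects are
emulated with $\beta \approx 0.3$–0.75. Everything is reproducible from
one integer seed, end to end.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: physiological and scanner noise
spectra (only white or AR(1) noise), HRF variability across cortex,
spatially correlated noise between neighboring vertices, folded cortical
geometry and its distance distortions, motion artifacts, and vertex
time series that violate the linear forward model altogether.

`recovery_report()` scores a fit against truth: sensitivity (selected
among tuned), specificity (unselected among null), and bias/RMSE of
$\hat\mu$ and $\hat\omega$ over selected tuned vertices. At the default
SNR the suite requires sensitivity ≥ 0.8 and, on 10,000 null vertices
under Bonferroni correction for 100,000, a false-selection rate
≤ 0.1%.

## Problem sizes used by the test suite

The packaged checks run at desk scale by design: 500 tuned vertices for
recovery, 10,000 null vertices for specificity, 200 vertices for the
log-versus-linear comparison, 50 vertices against a brute-force
grid-search oracle on a reduced grid, 4 simulated subjects × 2
hemispheres for the mixed-model sign pattern, and 100 replicates for
mixed-model CI coverage. These sizes give comfortable margins on every
threshold tested while keeping the whole suite around a minute.

## Known limitations

* **Grid truncation aliases out-of-range preferences.** A population
  truly preferring ~6 items is estimated at the grid edge; with *sharp*
  tuning ($\sigma_{\log} \lesssim 0.5$) the argmax can land exactly at
  $\mu = 5.0$, inside the selection range. With the broad widths the
  empirical width gradient implies out there ($\omega \approx 10$),
  more than 98% of such vertices are correctly rejected, but the range
  filter is not a guarantee against sharply tuned just-out-of-range
  populations.
* The estimator is exhaustive, not gradient-based: estimates are
  quantized to the grid (0.05 in $\mu$), which bounds, but never
  eliminates, discretization error.
* Surface input is a plain ASCII mesh format; GIFTI/FreeSurfer binary
  surfaces must be converted upstream.
* Group inference for the control GLM is per vertex and uncorrected;
  whole-map correction at the group level is out of scope.

## A minimal end-to-end run

```{r example, eval = FALSE}
schedule <- build_run("visual")
subject  <- simulate_subject(schedule, seed = 42)
fit      <- fit_prf(subject$data, schedule, n_comparisons = 1e5)
glance(fit)
recovery_report(fit, subject$truth)

sel <- fit$selected
geometry_correlations(tibble::tibble(
  mu   = fit$mu_hat[sel],
  fwhm = fit$omega_hat[sel],
  area = vertex_areas(subject$mesh)[fit$vertex[sel]]))
```
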