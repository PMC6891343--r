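---
title: "Calibrating THz transmittance against gravimetric leaf water mass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating THz transmittance against gravimetric leaf water mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafthz)
```

## The physical model

Liquid water absorbs terahertz radiation very strongly (absorption
coefficient $\alpha \approx 500\ \mathrm{cm^{-1}}$ near 2.55 THz), while dry
leaf matter absorbs and scatters comparatively little at these long
wavelengths. A fresh leaf therefore attenuates a THz beam essentially in
proportion to the water column it puts in the beam path. Writing the optical
depth as the log intensity ratio

$$\tau = \ln\frac{I_0}{I_{Tr}},$$

Beer–Lambert attenuation through an effective water slab of thickness
$d_w = M_w / (\rho_w L_A)$ — the leaf's water volume spread over its
projected area $L_A$ — gives

$$\tau = \alpha\, d_w = \frac{\alpha}{\rho_w}\,\frac{M_w}{L_A} \equiv K\,\frac{M_w}{L_A}.$$

Neither $\tau$ nor $L_A$ alone tracks water mass across leaves: a large
well-hydrated leaf and a small one can have the same areal water density.
The product $\tau L_A$ removes that confound, and a per-species linear
calibration

$$\tau L_A = C_1 M_w + C_0$$

absorbs residual (non-water) absorption into the intercept $C_0$ and
species-level deviations from the pure-water slope $K = \alpha/\rho_w
\approx 0.5\ \mathrm{cm^2\,mg^{-1}}$ into $C_1$. Thick cuticular wax and
dry-matter absorption pull fitted slopes below $K$; the six species built
into this package span $C_1 = 0.31$–$0.47\ \mathrm{cm^2\,mg^{-1}}$. Once
$C_1, C_0$ are fitted on a destructively weighed calibration set, any later
$(\tau, L_A)$ pair converts to water mass nondestructively:
$\hat M_w = (\tau L_A - C_0)/C_1$.

## Measurement protocol and numerical conventions

* **Incident intensity** is read twice, before and after the leaf
  measurements; `average_incident()` takes their mean, so slow source drift
  enters as a symmetric error.
* **Transmitted intensity** is read at four points of the adaxial blade (two
  for small-leaved species, enforced via the `small_leaf` flag of
  `transmission_record()`), and `aggregate_transmission()` averages them.
* **Pooling order.** `record_optical_depth()` defaults to
  $\tau = \ln(\bar I_0/\bar I_{Tr})$ — intensities averaged *before* the
  log, matching the protocol's wording. The alternative (mean of per-point
  $\tau_i$) is exposed via `method = "per_point"`; by concavity of the log
  it is never smaller than the pooled value, and the package asserts that
  Jensen ordering as a test invariant rather than hiding it.
* **Negative optical depth** ($I_{Tr} > I_0$, possible under drift) warns
  but does not error; calibration tolerates it. Likewise a negative
  predicted water mass (when $\tau L_A < C_0$) is returned as-is with a
  warning, because truncating at zero would bias validation statistics.
* The regression direction is fixed: $\tau L_A$ is the response, $M_w$ the
  predictor; the water-mass prediction is the algebraic inverse of that fit,
  never a reverse regression.

## Uncertainty of predictions

`fit_calibration()` is ordinary least squares and reports the slope and
intercept with standard errors and covariance, plain and adjusted $R^2$
($1-(1-R^2)(n-1)/(n-2)$, one regressor), the two-sided Pearson test, and the
residual SD. `predict_water_mass()` propagates, to first order,

$$\operatorname{var}(\hat M_w) = \frac{\sigma^2_{res} + \mathrm{se}^2_{C_0}
  + \hat M_w^2\,\mathrm{se}^2_{C_1} + 2 \hat M_w
  \operatorname{cov}(C_0, C_1)}{C_1^2},$$

i.e. the scatter of a new observation plus the sampling uncertainty of both
coefficients, and forms the interval with the $t$ quantile on $n-2$ degrees
of freedom. At calibration sizes of 7–11 leaves these intervals are wide in
the tails: "within 3 standard errors" is a $t$ bound missing in 1.5–3 % of
studies even for a perfectly specified fit, which is why the package's
simulation tests check slope unbiasedness and a 90 % floor on 3-SE coverage
rather than a normal-theory 99.7 %. The measurement noise is multiplicative
in $\tau$ (so the $y$-scatter grows with $M_w$), which fattens those tails
slightly further; a weighted fit would be more efficient but the simple OLS
calibration is the method being validated.

## Leaf area from images

The manual path mirrors the classic ImageJ workflow: `calibrate_scale()`
(known length in px vs cm), then `polygon_area()` applies the shoelace
formula to the outlined perimeter, rejecting self-intersecting outlines by
an explicit segment-pair test. Pixel coordinates are 0-based, origin
top-left, $x$ = column, $y$ = row, vertices at pixel centers; areas are
orientation-independent.

The automatic path, `segment_leaf()`, thresholds a greenness index —
excess-green $2G-R-B$ by default, or the raw green channel — with Otsu's
method, decides which side of the threshold is foreground by comparing the
image border (assumed background) with the threshold, keeps the largest
8-connected component, and always fills interior holes: leaf blades are
simply connected, so specular highlights must not punch holes. Only
projected (planar) area is computed; curvature, perspective and petiole
handling are out of scope. Shoelace and pixel-counting areas agree within
2 % at 100 px/cm or better, which is the regime a handheld camera with a
ruler in frame easily reaches.

## What the simulator emulates

`simulate_study()` generates the full six-species study: leaf sampling,
instrument readings, and the measurement CSV. Its defaults are the study
conditions, not tuning knobs:

| Parameter | Default | Why |
|---|---|---|
| marginal means/SDs of $M_w$, $L_A$, LDM | six species' printed summaries | moment-matched exactly |
| marginals' form | lognormal | SDs reach half the mean (e.g. hazel $M_w$ 407 ± 221 mg); Gaussian marginals would need truncation at 0 |
| `corr_mw_la` | 0.98 (log scale) | see below |
| `slope_K` per species | 0.47, 0.45, 0.45, 0.39, 0.45, 0.31 $\mathrm{cm^2\,mg^{-1}}$ | the fitted calibration slopes being emulated |
| `C0` | 0 | intercepts were reported as zero in most cases; configurable |
| leaf counts | 11, 10, 7, 10, 11, 10 | the study design (59 leaves) |
| `I0_nominal` | 1000 counts | arbitrary detector units |
| `drift_sd` | 0.01 | relative before/after incident drift |
| `point_tau_sd` | 0.02 | within-leaf relative $\tau$ heterogeneity |
| `detector_sd` | 0.0002 · $I_0$ | additive detector noise |

Water mass and area are drawn bivariate-lognormal with the marginals
moment-matched in closed form ($\mu = \ln(m^2/\sqrt{v+m^2})$,
$\sigma^2 = \ln(1+v/m^2)$); dry mass is lognormal, correlated with area at
the same level, with water and dry mass conditionally independent given
area; fresh mass is their sum.

**Choosing the water–area correlation.** The across-leaf SD of $\tau$
observed per species on the real instrument is small — 0.08 to 0.76 around
means of 4.1–5.9 — which says that within a species the areal water density
$M_w/L_A$ is nearly constant: big leaves hold proportionally more water. In
the generator that dispersion is dominated by the log-scale correlation
between $M_w$ and $L_A$, and matching the observed band requires
$\rho \approx 0.98$; at a looser $\rho = 0.8$ the simulated $\tau$ SDs come
out 0.6–1.8, well outside anything observed. Note that the band cannot be
matched species-by-species from printed marginals alone: with fixed
marginal SDs, the log-SD of $M_w/L_A$ is bounded below by
$|\sigma_{M_w} - \sigma_{L_A}|$, so the tightest observed species (holm
oak, 0.08) is unreachable by any lognormal consistent with its printed
means and SDs — the joint raw data would be needed. The generator therefore
targets the across-species band, not each species' value.

**Choosing the instrument noise.** The instrument error is one component of
the observed per-species $\tau$ dispersion, so the smallest observed value
(0.08) is an upper bound on the per-leaf instrument error. Monte-Carlo
evaluation at each species' mean leaf shows `point_tau_sd = 0.02` with
`detector_sd = 0.2` keeps that error at 0.04–0.06 for every species —
consistent with the bound — while coarser settings (e.g. relative
heterogeneity of 8 %) produce per-leaf errors of 0.18–0.27, larger than two
species' entire observed across-leaf spread and thus physically excluded.

Transmitted intensities are clipped below at $10^{-6} I_0$ (with a warning)
so a noisy reading of an opaque leaf cannot go negative before the log;
with 4-point pooling the clip has negligible influence until $\tau$
approaches $\ln(10^6) \approx 13.8$, far beyond leaf-like values.

Seeding is a documented counter scheme: species $i$ draws its leaves under
sub-seed $f(\text{master}, i)$ and leaf $j$ its readings under
$f(\text{master}, 1000i + j)$, so any subset of the study reproduces
independently; all sub-seeds stay below $2^{31}$.

**What the simulator does not emulate** — and hence what passing tests do
not establish about real leaves: spatial water-distribution structure
within the blade (the measurement points are exchangeable draws), venation
and petiole geometry in rendered images (blades are superellipses),
systematic calibration drift between sessions, biological deviation from
the linear law (real $R^2$ values of 0.86–0.99 reflect sources of scatter —
area measurement error, non-water absorption variability — that printed
summary statistics do not constrain, so simulated fits are cleaner than
real ones), and any time dynamics of transpiration.

## Rendered image fixtures

`render_leaf_image()` draws a green superellipse of *exactly* the requested
area (the semi-axes are solved from the closed-form superellipse area
$4ab\,\Gamma(1+1/p)^2/\Gamma(1+2/p)$) on white, with 2×2 supersampled edge
anti-aliasing and optional Gaussian speckle, and returns the analytic area
as ground truth. Rendering refuses blades under 50 px across, where
discretization error would dominate what is being measured.

## Problem sizes used by the test-suite

Simulation-backed tests run the full 59-leaf study over 100 seeds for the
fit-quality sweep, 200 seeds for slope-coverage properties, $n = 10^4$
leaves for moment-recovery checks, and $10^4$ random cases for the
optical-depth identities; segmentation checks use 20 rendered blades of
4–90 cm². These sizes put Monte-Carlo error well below every asserted
tolerance while keeping the suite inside about a minute.

## Known limitations

* Calibration is per species and instrument session; slopes are not
  transferable across species (SLA and wax thickness shift them), and the
  package deliberately offers no cross-species pooled fit.
* OLS ignores the multiplicative structure of the $\tau$ noise;
  uncertainty statements are first-order delta-method approximations.
* The image path assumes a single leaf blade on a light background with a
  known scale; no lens-distortion or perspective correction.
* No frequency dependence: the single operating point near 2.55 THz is
  hard-coded in spirit — $\alpha$ is a constant, not a spectrum.
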