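---
title: "Methods: propagating geometric and analytical error through coronary simulation pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propagating geometric and analytical error through coronary simulation pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroprop)
```

## The problem

Computational indices derived from reconstructed coronary arteries — wall
shear stress maps, pressure-derived stenosis indices, plaque-growth
forecasts — inherit the error of the reconstruction itself. Validation of
contour-based lumen/wall reconstruction puts that error at about 5% of the
cross-sectional area. `coroprop` asks, quantitatively: if every contour's
area is wrong by 5% in either direction, how far do downstream quantities
move, and does a prognostic model built on top remain stable?

The package therefore implements, end to end:

1. a point-cloud vessel representation (stacks of 72-point closed contours,
   0.5 mm apart) and the per-contour area-perturbation procedure;
2. reduced-order hemodynamics (shear stress, pressure drop) on those stacks;
3. the SmartFFR flow-ramp index;
4. a shear-coupled Kedem–Katchalsky / ODE plaque-growth model;
5. the agreement-statistics layer (paired differences, Bland–Altman limits,
   relative errors, quadrature uncertainty chains); and
6. error-injected regression for prognostic-model stability.

Synthetic vessel and cohort generators make every stage runnable without
patient data.

## Geometry and the perturbation procedure

A contour is scaled about its vertex centroid by the linear factor
`sqrt(area_factor)` — the unique similarity transform achieving a prescribed
area ratio — and re-translated so the centroid is preserved. Both the lumen
and the outer wall are scaled in the same direction, producing an
overestimated (`area_factor = 1.05`) and an underestimated (`0.95`) model
per original vessel.

Two open choices were resolved as follows:

* **Centroid** means the arithmetic mean of the 72 vertices, not the
  enclosed-area centroid. For the near-regular rings of a reconstruction
  (and exactly for the synthetic regular polygons) the two coincide; the
  vertex mean is the natural quantity in a point-cloud workflow.
* The stated error is applied **to each contour's area exactly**, not to
  total volume. Under per-contour scaling the two are equivalent for the
  axial profiles used here, and per-contour application is what the stepwise
  procedure (scale → recompute centroid → translate back) describes.

Out-of-plane jitter is projected onto each ring's best-fit plane (SVD of the
centred vertices) before scaling, so the procedure is well defined for
imperfectly planar input.

## Reduced-order hemodynamics

The analysis object is error *propagation*, not the flow solver, so a 3-D
Navier–Stokes solve is replaced by a closed-form model that preserves the
monotone structure the propagation argument rests on:

* Shear stress: `tau(z) = 4 mu Q / (pi r(z)^3)`, with `r(z)` the effective
  radius `sqrt(A(z)/pi)` of the shoelace lumen area. Viscosity 0.0035 Pa s
  (Newtonian blood), rest flow 1 mL/s.
* Pressure: Poiseuille gradient `8 mu Q / (pi r^4)` integrated by the
  trapezoid rule over the 0.5 mm stations, plus a Young-type separation loss
  `K_t (rho/2) (Q/A_ref)^2 (A_ref/A_throat - 1)^2` at the throat of each
  detected stenosis (`K_t = 1.52`, density 1060 kg/m^3, both configurable;
  the separation term can be disabled). Inlet pressure 100 mmHg.

A uniform area error then has an exact algebraic consequence:
`tau_perturbed / tau_original = (1 ± 0.05)^(-3/2)`, i.e. +8.00% for
underestimation and −7.06% for overestimation at every station. These are
the model-specific analogues of the CFD-derived relative errors
(+5.84%/−6.72%), which are not recoverable without the patient meshes; the
test suite asserts the closed-form values exactly. The density default
(1060 kg/m^3) is the standard literature value; only the viscosity is fixed
by the study conditions.

## SmartFFR

Pd/Pa is computed at the five-step flow ramp 0–4 mL/s, interpolated by a
shape-preserving monotone cubic spline (Hyman-filtered), and resampled to
100 points including both endpoints. The index is the trapezoidal area under
this curve divided by that of a *healthy reference*: a constant-radius tube
of the same length. The reference radius defaults to the 95th percentile of
the station radii (alternatives: proximal mean, user value) since the
source analysis does not define its "healthy segment". Classification uses
the clinical grey zone around 0.80 with a ±0.03 band (configurable).

The spline is taken over *flow*, not time: the five simulated "timesteps"
map one-to-one onto the five flow states, and Pd/Pa is a function of flow.
A monotone spline prevents spurious oscillation of the area under the curve.

Because SmartFFR is self-normalized, a uniform ±5% area error largely
cancels (both the case and its reference scale together); the residual
shift comes from the separation term. A throat-only error of the same size
moves the index more — the suite checks this dominance property.

## Plaque growth

The source description names the mechanisms (Kedem–Katchalsky influx,
LDL oxidation damped by HDL, monocyte→macrophage differentiation, foam-cell
formation, SMC phenotype switching, collagen production) but not the
equations, which live in earlier work. The package implements the minimal
ODE system realizing every named mechanism, with every rate exposed in
`growth_params()`; this is the largest modelling gap and the reason the
published absolute concentration magnitudes are not reproduction targets
(their units are unstated).

Per station (time unit days; concentrations in arbitrary units):

* influx of LDL, HDL and monocytes: `Js = P(tau) (C_l - C_w) +
  (1 - sigma_f) Jv (C_l + C_w)/2`, `Jv = Lp (dp - sigma_d dpi)`, scaled by
  the station's endothelial surface-to-wall-volume ratio `2 r / (R^2 - r^2)`;
* `P(tau) = P0 (1 + a / (1 + b tau))`, strictly decreasing in shear;
* the ten-species cascade of `step_wall_odes()` (see its documentation for
  the exact right-hand side), integrated by classic RK4 with non-negativity
  clipping;
* plaque volume `w_F F + w_S S_s + w_G G`, whose increments shrink the lumen
  contours through `remodeling_gain`, closing the geometry–shear feedback
  loop every `coupling_interval` (5 days); simulation halts with a
  documented status if the lumen closes below 0.1 mm radius.

**Why underestimation grows more plaque.** A smaller lumen raises shear,
which *lowers* permeability — but it also raises the surface-to-volume
ratio by `(1-e)^(-1/2)` (+2.6% at 5%). With the default shear modulation
(`a = 0.5`, `b = 1` /Pa) the permeability drop over the physiological
0.5–25 Pa range is a fraction of a percent, so the geometric effect
dominates and the underestimated geometry accumulates more LDL, more
inflammation and more plaque — the causal ordering the study reports. The
defaults were fixed once on that mechanistic ground; steeper shear
dependence (larger `a·b`) can invert the ordering and is left to the user.

Numerical choices: `dt = 0.05` day, chosen so the RK4 path agrees with a
brute-force forward-Euler integration at `dt/100` to within 0.1% (the
comparison error is dominated by the first-order oracle's own step error);
initial contractile SMC concentration is doubled relative to the
physiologic value (`diseased_multiplier = 2`) reflecting a diseased wall.

## Statistics layer

* Paired differences use the **original − perturbed** sign convention and a
  **population** (divide-by-n) standard deviation by default: these are the
  conventions under which the published per-case SmartFFR difference
  summaries (−0.004 ± 0.006 over; +0.009 ± 0.008 under) reproduce exactly
  from the published 20-case table. Both are switchable.
* Bland–Altman limits are `mean ± 1.96 sd`; each limit's 95% CI uses the
  standard variance `3 sd^2 / n`. The published underestimated-shear limits
  recompute from the published mean and sd to within rounding (±0.002). The
  corresponding overestimated limits as published are not consistent with
  `mean ± 1.96 sd` and are deliberately not reproduced.
* Relative error is the percentage difference of a summary statistic
  (min, max or mean) of the perturbed model from the original's.
* Uncertainty chains combine in quadrature, `u = sqrt(sd^2 + u_prev^2)`,
  seeded with the reconstruction-level uncertainty 0.09.
* The number of shear sample points behind the published CIs is not stated;
  `n` is therefore an explicit argument of `bland_altman_moments()`.

## Prognostic stability under analytical error

Laboratory analytical error reaches 13%. Two scenarios perturb the sixteen
biohumoral columns only: `maximum` multiplies by 1.13 (direction
configurable — the source states only a magnitude), `random` multiplies
each cell by an independent `U(0.87, 1.13)` draw (per-column mode
available). Screening is one OLS regression per variable; the multivariate
model is a joint OLS fit over a fixed predictor list, with Wald 95% CIs.
The published tables are titled linear regression while the accompanying
text says binary logistic; both are first-class here (`model = "logistic"`),
with OLS the default. No multiple-testing correction is applied, matching
the published analysis; Benjamini–Hochberg is available off by default.

Under the uniform 13% scenario OLS is exactly equivariant — coefficients
and CIs divide by 1.13, t and p unchanged — so the significant set is
provably identical; the random scenario can flip borderline variables at
small n, which is reported distributionally rather than asserted.

## What the synthetic generators do and do not emulate

`generate_vessel()` builds straight or gently curved tubes whose lumen area
carries Gaussian-shaped stenoses (severity defined on area, matching
clinical % area stenosis), with a constant-thickness outer wall —
sufficient for every contract in the pipeline, but not a realistic coronary
tree: no branching, no eccentric lesions, no wall-composition variation.
`generate_cohort()` (default n = 20, the study cohort size) draws
positive-valued biohumoral variables from log-normal marginals with
plausible clinical central values and plants linear effects of age (+0.010)
and baseline plaque burden (−0.011) — the magnitudes of the published
independent predictors — on a continuous progression outcome (residual sd
0.3, chosen so the planted effects are reliably detectable at n = 500 and
borderline at study scale). Passing tests therefore demonstrate the
*procedural* contracts (calibration, equivariance, orderings, agreement
formulas) on data with the assumed statistical structure; they do not
validate the hemodynamic or biological models against measurements.

Test and acceptance runs use desk-scale problem sizes chosen for fast,
deterministic execution: 20-vessel sets at 41 stations, 30-day growth
horizons, 200-replicate calibration loops.

## Known limitations

* The reduced-order pressure model has no 3-D recirculation, curvature or
  non-Newtonian effects; its relative errors are exact scaling laws, which
  is the point of the design but also its boundary.
* The growth ODE system is a concrete instantiation of a verbally specified
  model; absolute outputs are in arbitrary units.
* One published Bland–Altman row is internally inconsistent and is excluded
  from reproduction.
* The synthetic cohort is cross-sectional with independent predictors; real
  biohumoral panels are correlated.
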