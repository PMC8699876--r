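# coroprop

Error propagation through coronary simulation pipelines.

Reconstructed coronary vessel geometries carry a known cross-sectional area
error of about 5%. `coroprop` quantifies how that geometric error — and the
analytical error of biohumoral laboratory measurements (up to 13%) —
propagates through three downstream simulation levels and into prognostic
modelling:

1. **Hemodynamics.** Per-station endothelial shear stress
   `τ(z) = 4 μ Q / (π r(z)³)` and the pressure profile from a Poiseuille +
   Young-type separation-loss model on the effective-radius profile
   `r(z) = √(A(z)/π)`.
2. **SmartFFR.** The distal/proximal pressure ratio Pd/Pa over a 0–4 mL/s
   flow ramp, splined to 100 points; SmartFFR = AUC(case) / AUC(healthy
   reference), clipped to 1, with the clinical grey zone around 0.80.
3. **Plaque growth.** A shear-coupled Kedem–Katchalsky influx
   (`P(τ) = P₀(1 + a/(1 + b τ))`, decreasing in shear) feeding a ten-species
   wall ODE cascade (LDL → oxLDL → inflammation → foam cells / synthetic
   SMCs / collagen), with geometry feedback narrowing the lumen.

The statistics layer implements the paired comparisons used to report the
propagated error: mean ± sd of paired differences, Bland–Altman limits of
agreement with their CIs, relative errors of summary statistics, and the
quadrature uncertainty chain `u = √(sd² + u_prev²)` seeded with the
reconstruction uncertainty 0.09. The prognostic layer injects maximum
(×1.13) or random (×U(0.87, 1.13)) analytical error into biohumoral
variables and compares univariate and multivariate regression reports across
scenarios.

Vessels are stacks of 72-point closed contours spaced 0.5 mm apart (lumen +
outer wall). The area perturbation scales each contour about its centroid by
`√(area factor)`. Synthetic vessel and cohort generators let the whole
pipeline run with no external data.

## Worked example

```r
library(coroprop)

vessel <- generate_vessel(
  vessel_recipe(length = 20, base_radius = 1.5,
                stenoses = list(stenosis_spec(10, 6, 0.6))),
  case_id = "demo")
trip <- vessel_triplet(vessel, error = 0.05)   # original / +5% / -5%

sapply(trip, function(m) compute_smartffr(m)$smartffr)
#>       original  overestimated underestimated
#>         0.9820         0.9837         0.9801

tau <- lapply(trip, function(m) compute_ess(axial_profile(m))$tau_Pa)
stat3 <- function(x) c(min(x), max(x), mean(x))
re <- relative_error_summary(stat3(tau$original), stat3(tau$underestimated))
round(c(re$re_min, re$re_max, re$re_mean), 2)
#> [1] 8 8 8

round(sapply(lapply(trip, run_growth), function(g) g$plaque_volume_total), 4)
#>       original  overestimated underestimated
#>         7.8937         7.7148         8.0851
```

Reading the output: the 5% underestimation shifts SmartFFR down by ~0.002
(the index is self-normalized, so a uniform error largely cancels), raises
every shear-stress statistic by exactly `0.95^(-3/2) − 1 = +8.00%` under the
reduced-order model, and grows more plaque (8.09 vs 7.89 a.u.) because the
smaller lumen's higher surface-to-volume ratio outweighs the permeability
drop from higher shear — overestimation does the opposite.

The agreement statistics work the same way on bundled published per-case
values:

```r
cases <- reference_smartffr_cases()
bland_altman(paired_comparison(cases$original, cases$underestimated))
#> Bland-Altman: mean 0.0090 +/- 0.0083; LoA [-0.0073, 0.0253] (n = 20)
propagate_uncertainty(1.9902, 0.09)   # shear level on top of reconstruction
#> [1] 1.992234
```

`run_pipeline(pipeline_config(n_vessels = 20))` executes the full study
layout — 20 synthetic vessels × 3 models, shear fields, SmartFFR reports,
growth runs and the comparison tables — into a self-describing run
directory with a manifest (config hash + seed); identical configs reproduce
outputs exactly.

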