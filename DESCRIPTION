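Package: coroprop
Title: Error Propagation in Coronary Hemodynamics and Plaque-Growth Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how a stated reconstruction error in coronary vessel
    geometry propagates through hemodynamic and plaque-growth simulations and
    into prognostic models. Vessels are represented as stacks of closed planar
    contours; a per-contour area perturbation emulates lumen over- and
    under-estimation. Reduced-order blood-flow models compute endothelial shear
    stress and pressure drop, a flow-ramp Pd/Pa curve yields the SmartFFR
    stenosis index, and a shear-coupled Kedem-Katchalsky/ODE model simulates
    plaque growth. Agreement statistics (Bland-Altman limits, relative errors,
    quadrature uncertainty chains) and error-injected regression compare the
    perturbed pipelines with the original. Synthetic vessel and cohort
    generators allow every stage to run without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
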