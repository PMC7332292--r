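Package: hbshift
Title: Dynamics and Variability of the Hunchback Boundary in Early Drosophila Embryos
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how positional information is transmitted through
    the anterior-posterior patterning cascade of the early Drosophila embryo.
    Provides a synthetic-data generator for Hunchback (Hb) boundary
    trajectories, nuclear Bicoid (Bcd) gradients and downstream Kruppel/
    Even-skipped features; profile feature extraction (logistic boundary
    fits, inflection fronts, strip widths, peaks, orientation heat maps);
    boundary-variability statistics (equal-n time binning, smoothing-spline
    de-trending, F-tests, bootstrap errors, scaling regressions, pooled
    standard deviations); Bcd gradient noise analytics with positional-error
    propagation; a synthesis-diffusion-degradation simulator with fluorophore
    maturation correction; and a reaction-diffusion model of Hb boundary
    dynamics under Bcd activation and Hb self-activation, with genotype
    transforms, weighted multi-start parameter fitting and variant
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
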