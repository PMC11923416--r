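Package: isoneedle
Title: Time-Integrated Hydrogen Isotope Signals in Conifer Needle Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and screening statistics for detecting time-integrated
    physiological and environmental signals in the hydrogen isotope
    composition (delta-2H) of needle n-alkanes, water-soluble carbohydrates
    and starch. Provides a synthetic half-hourly forcing generator with
    planted ground-truth signals, leaf gas-exchange derivations (total
    conductance from transpiration), a mass-balance rooting-zone water
    isotope reservoir, Craig-Gordon needle-water enrichment with Peclet,
    two-pool and nonsteady-state corrections, compound-level isotope algebra
    (nonexchangeable hydrogen, alpha-amylase unmixing, abundance-weighted
    alkane means, biosynthetic fractionation inversion), daytime-filtered
    multi-window time integration, and a Spearman/Holm screening stage with
    random-intercept mixed-model confirmation reporting marginal and
    conditional R-squared and intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
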