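Package: tcellflux
Title: Compartmentalized 13C Metabolic Flux Analysis for T-Cell Central
    Carbon Metabolism
Version: 0.1.0
Authors@R:
    person("MFA", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Steady-state 13C metabolic flux analysis (13C-MFA) of
    central carbon metabolism in activated T cells traced with
    [U-13C]glucose.  Provides a reaction-list model dialect with carbon
    atom-transition maps across extracellular, cytosolic and
    mitochondrial compartments; elementary metabolite unit (EMU)
    simulation of GC-MS mass isotopomer distributions with a
    full-isotopomer brute-force oracle; natural-abundance correction for
    MOX-TBDMS derivatized fragments; uptake/secretion rate estimation
    from spent-media time courses; multi-start weighted least-squares
    flux estimation with chi-square goodness-of-fit and SSR-profile 95%
    confidence intervals; and a synthetic-experiment generator with
    glycolysis-high and OxPhos-high presets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
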