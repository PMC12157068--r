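Package: lemnagrow
Title: Canopy Growth Modelling and Harvest Optimization for Floating Duckweed Cultures
Version: 0.1.0
Authors@R: person("Jonas", "Feldmann", email = "jfeldmann@posteo.net", role = c("aut", "cre"))
Description: Growth kinetics of free-floating duckweed (Lemna) mats under
    artificial light. Combines Beer-Lambert light attenuation through the
    floating plant layer with a Monod light-response of photosynthesis and a
    constant respiration loss into a single ordinary differential equation for
    areal dry-weight density. Provides trajectory simulation (embedded
    Dormand-Prince integrator), least-squares parameter estimation from
    end-of-trial densities with Hessian-based standard errors, a logistic
    comparator model, long-term validation scoring, semi-continuous harvest
    optimization (optimal residual density, maximum daily yield, light-use
    efficiency), ordinary kriging of photosynthetic photon flux density fields
    over production basins with circular-subarea averaging, and synthetic-data
    generators that emulate the factorial growth-trial design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
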