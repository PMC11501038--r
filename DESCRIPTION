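Package: shhfp
Title: Floor-Plate Formation and Shh Gradient Dynamics in a Growing Neural Tube
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-species gene-regulatory reaction-diffusion model
    of Sonic hedgehog (Shh) morphogen source formation in a uniformly growing
    one-dimensional neural tube. Provides a Heun-scheme integrator on a growing
    domain (mapped coordinates with dilution), a random-walk computational
    screen over interaction parameters with data-constrained success criteria,
    classification of networks by their sensitivity to floor-plate-derived Shh,
    sensitivity scans, growth and source sweeps, morphogen gradient
    quantification (amplitude and decay length), and processing of
    ventral-to-dorsal fluorescence intensity profiles. All analyses return
    tidy tibbles and come with ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
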