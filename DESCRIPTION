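Package: bilayerDR
Title: Crossover-Point Analysis of Diffuse Reflectance from Bilayer Turbid Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Monte Carlo simulation of spatially resolved diffuse reflectance
    from monolayer and bilayer tissue-mimicking turbid media, and analysis of
    the resulting radial profiles. Provides a weighted-photon transport kernel
    with Henyey-Greenstein scattering and Fresnel boundaries, log-profile and
    local-slope analysis of reflectance versus source-detector separation,
    extraction of the crossover point at which the bottom layer of a bilayer
    sample begins to dominate the profile, detection of the secondary breaking
    point at the far-field noise limit, and fitting of the linear relation
    between the crossover point and the square root of the bottom-to-top
    absorption-coefficient ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
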