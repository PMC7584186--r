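Package: pollidyn
Title: Pollinator-Flower Dynamics and Yield Prediction for Dioecious Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic simulator of pollination dynamics in dioecious
    crop orchards such as kiwifruit. Bloom phenology follows Gaussian
    opening-rate curves with fixed flower lifespans; pollinators are
    tracked in pollen-load compartments with Holling type II visitation
    and preference-driven movement between male and female flowers.
    Per-cohort visit accounting yields daily fruit-set probabilities and
    total predicted yield. Includes parameter-sweep experiments
    (sex ratio, bloom timing, bee density, preference, handling time)
    and global sensitivity analysis via Latin hypercube sampling with
    partial rank correlation coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
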