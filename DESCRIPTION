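Package: dropevolve
Title: Recursive Droplet Evolution: Osmotic Coarsening, Size Selection,
    and Price-Equation Metrics for Microdroplet Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates osmotically coupled water-in-oil microdroplet
    populations carrying internal polymerization chemistry, and the
    recursive evolution loop built around them: droplet generation,
    incubation with osmotic water and molecular-weight-dependent solute
    exchange, size-threshold selection (individual or sub-population),
    fusion with fresh feedstock, splitting with partition noise, and
    multi-generation recursion. Each generation is scored with a Price
    decomposition of trait change into selection and transmission terms,
    and coarsening is tracked both from simulated radii and from an
    image-analysis pipeline (synthetic micrograph rendering, circle
    detection, polydispersity time series). All results are tidy tibbles
    with tidy()/glance()/autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    EBImage,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
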