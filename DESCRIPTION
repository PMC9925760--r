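Package: redtidesim
Title: Spatiotemporal Food-Web Simulation of Harmful Algal Bloom Impacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale spatiotemporal trophic-dynamic ecosystem simulator
    for studying episodic harmful algal bloom (red tide) impacts on coastal
    food webs. Provides an Ecopath-style mass-balance solver, foraging-arena
    trophic dynamics, a gridded spatial engine with habitat-capacity-weighted
    movement and gravity-model fishing effort, lethal and sublethal logistic
    response functions to Karenia brevis concentration, a combinatorial
    scenario ensemble, a percent-bias iterative calibration routine,
    ecosystem/community/population impact indicators, and a fully synthetic
    input generator (balanced food webs, environmental driver rasters, bloom
    maps, and survey samples).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
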