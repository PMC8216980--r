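Package: limnotte
Title: Trophic Transfer Efficiency of Carbon, Nutrients and Omega-3 PUFA in Lake Plankton
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for estimating how efficiently carbon, nitrogen,
    phosphorus and omega-3 polyunsaturated fatty acids are transferred from
    phytoplankton (seston) to zooplankton in lake plankton communities.
    Computes Carlson trophic state indices and a hydrochemical dystrophy
    index from survey chemistry, converts zooplankton counts and body
    lengths to biomass through length-weight allometry, estimates
    depth-integrated gross primary production from chlorophyll, PSII
    activity and PAR profiles and crustacean secondary production from an
    allometric regression, derives per-substance production from elemental
    and fatty-acid composition, and summarises transfer efficiencies by
    trophic class with one-way ANOVA, Fisher LSD compact letter displays,
    Bray-Curtis clustering and (canonical) correspondence analysis. A
    seeded synthetic lake-survey generator reproduces the statistical
    structure of a 30-lake summer snapshot survey so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
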