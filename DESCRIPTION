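Package: popscape
Title: Spatially Explicit Forward-Time Population Genetic Simulation on
    Abstract Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Declarative construction of spatio-temporal demographic models
    (populations with polygonal ranges on planar landscapes, splits, resizes,
    gene flow, range movements and expansions), executed by a continuous-space
    forward Wright-Fisher engine that records genealogies with recombination,
    simplifies them to succinct node/edge tables, overlays neutral mutations,
    and computes population-genetic statistics (diversity, divergence,
    f4-statistics, f4-ratio admixture proportions, allele frequency spectra)
    together with spatio-temporal ancestry tables, Newick trees, and
    VCF/EIGENSTRAT exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
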