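Package: sgpnet
Title: Signal-Gene-Protein Interaction Networks, Disease Projections, and
    Boolean Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling and interrogating molecular interaction
    networks around disease genes: tidy containers for protein-protein
    interaction graphs with identifier maps and annotation sets, induced
    subnetwork and k-hop neighborhood queries, disease-disease projections
    from shared or interacting gene products, pathway crosstalk ranking over
    typed signal-protein-gene interaction classes, export of typed pathways
    to SBML with first-order rate laws, and a synchronous Boolean network
    engine (rule-file parser, exhaustive state-space enumeration, singleton
    and cyclic attractor detection with basin sizes, and clamping-based
    mutant analysis) that reproduces the mammalian cell-cycle logical model
    of Faure et al. (2006) <doi:10.1093/bioinformatics/btl210>.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
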