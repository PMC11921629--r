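Package: metabolizr
Title: Reaction Rules from Genome-Scale Metabolic Models for Metabolite
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns biotransformation reactions extracted from genome-scale
    metabolic models into graded, atom-context-trimmed reaction rules
    (chemically specific reaction rules, CSRRs), applies them to query
    small molecules to predict human and gut-microbial metabolites, and
    scores every prediction with a three-component confidence score
    (substrate similarity, product similarity, atom efficiency).
    Downstream analyses cover per-atom metabolic accessibility,
    physicochemical and bioavailability profiling, structural alerts,
    isotope patterns, benchmark statistics, and molecular similarity
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
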