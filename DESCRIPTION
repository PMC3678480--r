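Package: taxonmatch
Title: Taxonomic Name Parsing, Fuzzy Matching and Synonymy Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking biological species datasets by scientific name.
    Parses Linnaean binomial and trinomial names together with their author
    citations into structured objects, matches lists of names against a
    reference synonymy through a configurable cascade (exact match with
    authority, name-only match with authority checking, promotion of
    infraspecific names to the parent species, and front-padded q-gram fuzzy
    matching with first-three-character blocking), merges matched datasets
    under accepted names, and standardizes free-text distribution region
    lists to a canonical region scheme such as the TDWG World Geographical
    Scheme. Includes a synthetic-synonymy benchmark generator with known
    ground truth for evaluating matcher precision and recall, and a
    command-line interface for reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    stringi,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
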