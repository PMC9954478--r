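Package: phonet
Title: Resilience of Phonological Networks Under Edge Damage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the resilience of the mental lexicon viewed
    as a phonological network. Builds networks in which words are linked when
    they differ by a single phoneme (addition, deletion, or substitution),
    applies a cumulative random edge-removal damage protocol, computes a
    structural metric panel (giant component, isolates, islands, modularity,
    clustering, average shortest path length) with a resilience heuristic,
    simulates lexical retrieval by spreading activation with retention,
    decay, and suppression parameters, and relates simulated activation to
    behavioural naming data via correlation and location-based chi-square
    analyses. Includes calibrated synthetic generators for lexicons,
    accuracy tables, and error records so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
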