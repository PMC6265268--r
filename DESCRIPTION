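Package: lowhic
Title: Hi-C Contact Map Processing, Structure Calling and Rearrangement
    Detection for Low-Input Libraries
Version: 0.1.0
Authors@R:
    person("lowhic", "developers", email = "lowhic@example.org",
           role = c("aut", "cre"))
Description: A toolkit for processing Hi-C sequencing libraries from
    aligned read pairs to balanced contact matrices and downstream
    chromatin-structure calls. Implements in-silico restriction digestion,
    valid-pair filtering (ligation-bias, same-fragment, restriction-site
    distance and PCR-duplicate filters), binning, low-coverage masking and
    Knight-Ruiz matrix balancing; observed/expected transforms, insulation
    scores with TAD boundary calling, A/B compartment eigenvectors,
    aggregate TAD/loop statistics, HICCUPS-style de-novo loop calling, and
    case-versus-control detection of structural rearrangements by
    whole-genome virtual 4C. Ships a deterministic contact-map and
    read-pair simulator with planted ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
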