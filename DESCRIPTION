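Package: colocnet
Title: Co-Location Social Networks and Bedroom Privacy in Long-Term Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds resident social networks from indoor positioning
    co-location streams in long-term-care facilities. Cleans second-level
    device-zone records, detects meaningful dyadic interaction events with a
    five-minute co-presence rule, constructs two-mode (resident-location) and
    one-mode (resident-resident) networks, derives per-resident network
    features stratified by roommate relation and location class, classifies
    residents into a k-means social-cluster typology with elbow-based model
    selection, scores bedroom privacy with a five-factor built-environment
    instrument, and quantifies privacy-network associations. Includes an
    agent-based simulator of facility movement and sensor noise with planted
    social structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
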