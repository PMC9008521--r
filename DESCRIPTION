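Package: discourselens
Title: Anchored N-Gram Analysis of Topical Discourse in Social Media Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for decade-scale analysis of topical discourse in
    timestamped message streams: anchored n-gram corpus construction with
    organic/retweet count ledgers, tied-rank time series, lexicon-based
    ambient happiness with word-shift decompositions, rank-turbulence
    divergence between ranked vocabularies (allotaxonometry), and
    contagiogram amplification statistics. Includes a seeded synthetic
    stream generator that plants topic growth, awareness and tragedy
    event spikes, sentiment regimes, and retweet dynamics, so the whole
    pipeline is testable without access to a proprietary platform feed.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    ggplot2,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
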