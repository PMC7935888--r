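Package: circadetox
Title: Circadian Analysis of Detoxification Gene Expression and Promoter
    E-Box Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis chain from circadian expression time courses and
    genome annotation to rhythmicity calls, phase classes and promoter
    E-box statistics in insect detoxification gene families. Implements a
    nonparametric rank-correlation rhythm test against cosine references
    over a 12-24 h period window with exact tied-reference null
    distributions, fuzzy c-means soft clustering of standardized
    time-course profiles, day/night/arrhythmic phase classification,
    strand-aware promoter extraction with canonical (CACGTG) and
    non-canonical (CANNTG) E-box scanning, TSS-distance histograms and
    permutation enrichment, behavioral actogram summaries with chi-square
    periodogram period estimation, and a synthetic-data module with
    planted rhythms and motifs so every stage is verifiable by parameter
    recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
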