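Package: lphist
Title: Alignment-Free DNA Sequence Comparison with Local Pattern
    Histograms of Binary Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Alignment-free estimation of similarity between DNA sequences.
    Each sequence is drawn as a two-dimensional trajectory by assigning a
    diagonal unit vector to every base and accumulating the vectors, with
    optional self-information weighting factors derived from a second-order
    Markov model of trinucleotide frequencies.  The trajectory is rasterized
    to a binary image, summarized as an occurrence-frequency histogram of
    3x3 local bitmap patterns, and pairs of histograms are compared under
    five distance measures (histogram intersection, Manhattan distance,
    Bhattacharyya distance, Jensen-Shannon divergence, and Kendall's
    rank-correlation distance).  Distance matrices feed UPGMA tree
    construction and Robinson-Foulds evaluation against a reference tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    png
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
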