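Package: pirnakit
Title: Characterization of piRNA Clusters from Small-RNA and Repeat Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing piRNA clusters such as the Drosophila
    flamenco locus: merging RepeatMasker fragments into transposable-element
    copies and classifying them as full-length, solo-LTR or fragment;
    multimapper-weighted small-RNA counting; proTRAC-style piRNA cluster
    calling with density, 1U/10A, read-concentration and main-strand
    criteria; ping-pong signature scoring from 10-nt 5'-end overlaps;
    synteny-based alignment of TE annotations across genotype panels with
    shared/private insertion spectra; horizontal-transfer calling from
    percent identity; restriction-digest and assembly-QC utilities; and
    seeded synthetic-data generators with recorded ground truth for all of
    the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
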