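Package: gameconv
Title: Detection, Dating and Orientation of Gene Conversion Between X-Y
    Gametologs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects, delimits, dates and orients ectopic gene-conversion
    events between X- and Y-linked homologous (gametologous) regions from
    multi-species nucleotide alignments. Implements sliding-window
    p-distance profiles, deterministic neighbor-joining with column
    bootstrap, topology classification (reciprocal monophyly versus
    species pairing), segmentation of a region into topology-homogeneous
    sub-regions, parsimonious mapping of conversion events onto a
    time-calibrated species tree, direction inference from outgroup-
    polarized diagnostic sites, molecular dating against fossil-calibrated
    chromosome-specific substitution rates, and detection of short
    recent conversion tracts as anomalously long identical runs between
    alleles. A forward simulator of gametolog evolution (Jukes-Cantor
    substitution, stratum formation, conversion tracts, lineage-specific
    deletions) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Genetics, Phylogenetics, SequenceMatching, Alignment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
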