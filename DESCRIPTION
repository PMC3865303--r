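Package: erucaseq
Title: Coding-Region Diversity and Trait Association for Brassicaceae FAE1-Style Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of in-frame coding alignments, built
    around the fatty-acid elongase (FAE1) erucic-acid system in Brassicaceae.
    Classifies alignment columns (variable, parsimony-informative, silent vs
    replacement), estimates nucleotide diversity and Jukes-Cantor-corrected
    divergence within and between groups, computes Nei-Gojobori Ka/Ks with
    equal-weight pathway averaging, profiles silent-site diversity in sliding
    windows, detects group-diagnostic states and frequency-threshold fixed
    differences, categorizes seed erucic-acid contents by gap boundaries, and
    tests genotype-phenotype association with a diversity-based Fst and a
    label-permutation null. A seedable codon-level simulator generates
    alignments, trees, and clade-correlated phenotypes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
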