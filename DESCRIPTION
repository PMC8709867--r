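Package: pseudochron
Title: Forensics and Dating of Gene Loss on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the history of gene loss from
    exon-structured coding sequences. Detects open-reading-frame
    disrupting mutations (frameshifts, premature stop codons, start
    loss) by alignment against an intact reference, clusters shared
    inactivating mutations into independent loss events under Dollo
    parsimony on a time-calibrated tree, estimates branch-category
    dN/dS under an MG94xHKY codon substitution model with a
    Felsenstein-pruning likelihood, dates gene inactivation on mixed
    (part functional, part pseudogenic) branches with the 1ds/2ds
    mixed-branch decomposition, tests gene retention against a
    continuous trait with phylogenetic logistic regression, and
    simulates codon alignments with known inactivation times for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
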