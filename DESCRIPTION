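Package: leaptools
Title: Classification and Physico-Chemical Profiling of Late Embryogenesis
    Abundant Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the sequence-based analysis of Late Embryogenesis
    Abundant Proteins (LEAPs). Classifies protein sequences into the twelve
    motif-defined LEAP classes using a compact motif dialect, computes a suite
    of per-sequence physico-chemical descriptors (molecular weight, isoelectric
    point, net charge, GRAVY, mean Eisenberg hydrophobicity, FoldIndex,
    bulkiness, flexibility, solvent accessibility fractions, transmembrane
    tendency, amino-acid composition), profiles amino-acid usage against a
    background proteome composition, places sequences on charge-hydropathy
    order/disorder planes, and runs a nonparametric statistical battery
    (normality screening, Kruskal-Wallis with Nemenyi post-hoc comparisons,
    Spearman correlation grouping, principal component analysis, Ward
    clustering). A synthetic corpus generator emulating the LEAPdb class
    structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
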